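test_that("the packaged journal matrix has the published margins", {
  tab <- biomed_journal_matrix()
  expect_equal(sum(tab$counts), 400L)
  expect_equal(unname(rowSums(tab$counts)), rep(40L, 10))
  expect_equal(unname(colSums(tab$counts)),
               c(53L, 31L, 16L, 25L, 70L, 53L, 44L, 51L, 43L, 14L))
  expect_equal(tab$counts["J Cardiovas Magn R", "8"], 38L)
  expect_equal(tab$counts["BMC Bioinformatics", "1"], 34L)
})

test_that("dominant classes follow the column maxima with deterministic ties", {
  tab <- biomed_journal_matrix()
  dom <- dominant_class_per_cluster(tab)
  expect_equal(unname(dom["5"]), "BMC Cancer")
  expect_equal(unname(dom), tab$classes)  # diagonal dominance in the fixture

  diag_tab <- contingency_table(diag(3L) + 0L,
                                classes = c("a", "b", "c"),
                                clusters = c("1", "2", "3"))
  expect_equal(unname(dominant_class_per_cluster(diag_tab)), c("a", "b", "c"))

  tie_tab <- contingency_table(matrix(c(3L, 3L), 2, 1),
                               classes = c("a", "b"), clusters = "1")
  expect_warning(tie <- dominant_class_per_cluster(tie_tab), "tie")
  expect_equal(unname(tie), "a")

  zero_col <- contingency_table(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(dominant_class_per_cluster(zero_col), "no members")
})

test_that("homologous-text accounting matches the published totals", {
  tab <- biomed_journal_matrix()
  hom <- homologous_counts(tab)
  expect_equal(unname(hom$per_cluster["1"]), 19L)
  expect_equal(unname(hom$per_cluster),
               c(19L, 15L, 9L, 10L, 49L, 22L, 19L, 13L, 13L, 0L))
  expect_equal(hom$total, 169L)

  diag_tab <- contingency_table(diag(4L) * 5L)
  expect_equal(homologous_counts(diag_tab)$total, 0L)
})

test_that("the relationship network reproduces the published degree structure", {
  tab <- biomed_journal_matrix()
  net <- build_relationship_network(tab, threshold = 2)
  expect_equal(nrow(net$edges), 27L)
  deg <- degree_stats(net)
  out <- deg$degrees$out
  names(out) <- deg$degrees$node
  expect_equal(unname(out["BMC Cancer"]), 8)
  expect_equal(unname(out["J Med Case Rep"]), 0)
  expect_equal(deg$median_out_degree, 3)
  expect_equal(deg$avg_neighbors, 4.4)
  expect_false(any(net$edges$from == net$edges$to))
  expect_true(all(net$edges$weight >= 2L))
})

test_that("the literal direction convention transposes edges but keeps the count", {
  tab <- biomed_journal_matrix()
  a <- build_relationship_network(tab, convention = "degree_consistent")
  b <- build_relationship_network(tab, convention = "literal")
  expect_equal(nrow(b$edges), nrow(a$edges))
  key_a <- sort(paste(a$edges$from, a$edges$to))
  key_b <- sort(paste(b$edges$to, b$edges$from))
  expect_equal(key_a, key_b)
  da <- degree_stats(a)$degrees
  db <- degree_stats(b)$degrees
  expect_equal(da$out, db$in_)
})

test_that("clustering coefficient and path statistics match the published network", {
  tab <- biomed_journal_matrix()
  net <- build_relationship_network(tab)
  cc <- directed_clustering_coefficient(net)
  expect_equal(round(cc$mean, 2), 0.36)
  ps <- path_stats(net)
  expect_equal(ps$n_shortest_paths, 73L)
  expect_equal(round(ps$characteristic_path_length, 2), 1.89)
  expect_equal(ps$diameter, 5)
  expect_equal(weak_components(net), 1L)
})

test_that("clustering coefficient handles canonical small graphs", {
  tri <- manual_network(c("a", "b", "c"),
                        from = c("a", "b", "b", "c", "a", "c"),
                        to   = c("b", "a", "c", "b", "c", "a"))
  expect_equal(unname(directed_clustering_coefficient(tri)$per_node), rep(1, 3))

  star <- manual_network(c("hub", "l1", "l2", "l3"),
                         from = rep("hub", 3), to = c("l1", "l2", "l3"))
  expect_equal(directed_clustering_coefficient(star)$mean, 0)
})

test_that("path statistics handle chains, pairs and empty networks", {
  chain <- manual_network(c("a", "b", "c"), from = c("a", "b"), to = c("b", "c"))
  ps <- path_stats(chain)
  expect_equal(ps$n_shortest_paths, 3L)   # a->b, b->c, a->c
  expect_equal(ps$diameter, 2)
  expect_equal(ps$characteristic_path_length, (1 + 1 + 2) / 3)

  pair <- manual_network(c("a", "b"), from = c("a", "b"), to = c("b", "a"))
  expect_equal(path_stats(pair)$characteristic_path_length, 1)
  expect_equal(path_stats(pair)$diameter, 1)

  lonely <- manual_network(c("a", "b", "c"), character(0), character(0))
  expect_true(is.na(path_stats(lonely)$characteristic_path_length))
  expect_equal(path_stats(lonely)$n_shortest_paths, 0L)
  expect_equal(weak_components(lonely), 3L)

  two_pairs <- manual_network(c("a", "b", "c", "d"),
                              from = c("a", "c"), to = c("b", "d"))
  expect_equal(weak_components(two_pairs), 2L)
})

test_that("network statistics agree with igraph on the published network", {
  skip_if_not_installed("igraph")
  tab <- biomed_journal_matrix()
  net <- build_relationship_network(tab)
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  D <- igraph::distances(g, mode = "out", weights = NA)  # hop counts, not weights
  finite <- D[row(D) != col(D) & is.finite(D)]
  ps <- path_stats(net)
  expect_equal(ps$n_shortest_paths, length(finite))
  expect_equal(ps$characteristic_path_length, mean(finite))
  expect_equal(ps$diameter, max(finite))
  expect_equal(weak_components(net),
               igraph::components(g, mode = "weak")$no)
  deg <- degree_stats(net)
  expect_equal(deg$degrees$out,
               unname(igraph::degree(g, mode = "out")))
})

test_that("edge threshold dominates edge creation", {
  tab <- biomed_journal_matrix()
  expect_equal(nrow(build_relationship_network(tab, threshold = 1000)$edges), 0L)
  diag_tab <- contingency_table(diag(4L) * 5L)
  dnet <- build_relationship_network(diag_tab)
  expect_equal(nrow(dnet$edges), 0L)
  expect_equal(weak_components(dnet), 4L)
})

test_that("edge-list and GraphML exports carry every edge", {
  tab <- biomed_journal_matrix()
  net <- build_relationship_network(tab)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  edges <- utils::read.delim(tsv)
  expect_equal(nrow(edges), 27L)
  expect_equal(sort(edges$weight), sort(net$edges$weight))

  skip_if_not_installed("xml2")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  doc <- xml2::read_xml(gml)
  expect_length(xml2::xml_find_all(doc, ".//*[local-name() = 'node']"), 10L)
  expect_length(xml2::xml_find_all(doc, ".//*[local-name() = 'edge']"), 27L)
})
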