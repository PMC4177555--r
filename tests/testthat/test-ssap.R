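make_labeled_pool <- function(n_classes = 3, per = 6, seed = 99) {
  spec <- synthetic_corpus_spec(n_topics = n_classes, docs_per_topic = per,
                                rng_seed = seed)
  generate_corpus(spec)
}

test_that("construct_seed_set draws the requested number per class, reproducibly", {
  pool <- make_labeled_pool(3, 6)
  seeds <- construct_seed_set(pool, per_class = 2, rng_seed = 1)
  expect_length(seeds$entries, 6L)
  expect_equal(unname(table(seeds$entries)), rep(2L, 3), ignore_attr = TRUE)
  expect_true(all(names(seeds$entries) %in% corpus_ids(pool)))

  again <- construct_seed_set(pool, per_class = 2, rng_seed = 1)
  expect_identical(seeds$entries, again$entries)
  other <- construct_seed_set(pool, per_class = 2, rng_seed = 2)
  expect_false(identical(seeds$entries, other$entries))

  empty <- construct_seed_set(pool, per_class = 0)
  expect_length(empty$entries, 0L)

  expect_error(construct_seed_set(pool, per_class = 7), "topic01")
})

test_that("inject_seeds flags in-corpus seeds and appends external ones", {
  pool <- make_labeled_pool(2, 4)
  x <- pool
  attr(x, "truth") <- NULL
  seeds <- construct_seed_set(pool, per_class = 2, rng_seed = 3)

  flagged <- inject_seeds(x, seeds)
  expect_length(flagged$documents, length(x$documents))  # N' = N, flags set
  flags <- vapply(flagged$documents, `[[`, logical(1), "is_seed")
  expect_equal(sum(flags), 4L)

  # external seeds: corpus without those documents, pool supplies them
  rest <- corpus(unname(x$documents[setdiff(corpus_ids(x), names(seeds$entries))]))
  aug <- inject_seeds(rest, seeds, pool = pool)
  expect_length(aug$documents, length(rest$documents) + 4L)
  expect_error(inject_seeds(rest, seeds), "neither in the corpus")

  expect_identical(inject_seeds(x, seed_set(character(0))), x)
})

test_that("merge_labeled_clusters unions same-label clusters and keeps a partition", {
  # clusters {1,2} seeds X, {3,4} seeds X, {5,6} seeds Y, {7} seedless
  res <- clustering_result(c(1L, 1L, 3L, 3L, 5L, 5L, 7L),
                           ids = paste0("d", 1:7))
  seeds <- seed_set(c(d1 = "X", d3 = "X", d5 = "Y"))
  merged <- merge_labeled_clusters(res, seeds)
  expect_length(merged$clusters, 3L)
  expect_equal(merged$cluster[1], merged$cluster[3])
  expect_false(merged$cluster[1] == merged$cluster[5])
  expect_setequal(unlist(merged$clusters), 1:7)
  lab <- merged$cluster_labels[merged$cluster]
  expect_equal(lab[1], "X")
  expect_equal(lab[5], "Y")
  expect_true(is.na(lab[7]))
})

test_that("a cluster with mixed-label seeds joins the majority label", {
  res <- clustering_result(c(1L, 1L, 1L, 4L, 4L), ids = paste0("d", 1:5))
  seeds <- seed_set(c(d1 = "X", d2 = "X", d3 = "Y", d4 = "X"))
  expect_message(merged <- merge_labeled_clusters(res, seeds), "majority")
  expect_length(merged$clusters, 1L)  # both clusters adopt X and merge
  expect_equal(merged$cluster_labels[1], "X")
})

test_that("merging never splits clusters and leaves seedless results unchanged", {
  res <- clustering_result(c(1L, 1L, 3L, 3L), ids = paste0("d", 1:4))
  untouched <- merge_labeled_clusters(res, seed_set(c(zz = "X")))
  expect_equal(untouched$cluster, res$cluster)

  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    ex <- sample(n, n, replace = TRUE)
    ex <- stats::ave(seq_len(n), ex, FUN = min)  # valid exemplar map
    ex[unique(ex)] <- unique(ex)
    res <- clustering_result(as.integer(ex), ids = paste0("d", seq_len(n)))
    labs <- sample(c("A", "B"), 3, replace = TRUE)
    names(labs) <- paste0("d", sample(n, 3))
    merged <- merge_labeled_clusters(res, seed_set(labs))
    expect_setequal(unlist(merged$clusters), seq_len(n))
    expect_lte(length(merged$clusters), length(res$clusters))
    # documents in one input cluster are never separated
    for (cl in res$clusters) {
      expect_length(unique(merged$cluster[cl]), 1L)
    }
  }
})

test_that("run_ssap with an empty seed set equals plain affinity propagation", {
  pool <- make_labeled_pool(2, 5, seed = 13)
  x <- pool
  S <- set_preferences(build_similarity_matrix(x), phi = 1)
  plain <- run_ap(S)
  ssap <- run_ssap(x, seed_set(character(0)), phi = 1)
  expect_identical(ssap$cluster, plain$cluster)
  expect_identical(ssap$exemplar, plain$exemplar)
})

test_that("run_ssap recovers planted topics with few seeds at high separation", {
  spec <- synthetic_corpus_spec(n_topics = 5, docs_per_topic = 10,
                                background_mixing = 0.05, rng_seed = 41)
  x <- generate_corpus(spec)
  truth <- attr(x, "truth")
  seeds <- construct_seed_set(x, per_class = 2, rng_seed = 51)
  res <- run_ssap(x, seeds, phi = 3)
  expect_length(res$clusters, 5L)
  tab <- build_contingency(truth, res, exclude_seeds = TRUE)
  expect_gte(f_measure(tab), 0.95)
  # merged clusters carry their seed label
  expect_setequal(stats::na.omit(res$cluster_labels), sort(unique(truth)))
})

test_that("seed-guided merging improves over same-preference affinity propagation", {
  spec <- synthetic_corpus_spec(n_topics = 6, docs_per_topic = 12, rng_seed = 61)
  x <- generate_corpus(spec)
  truth <- attr(x, "truth")
  S <- set_preferences(build_similarity_matrix(x), phi = 3)
  f_ap <- f_measure(build_contingency(truth, run_ap(S)))
  seeds <- construct_seed_set(x, per_class = 4, rng_seed = 62)
  f_ssap <- f_measure(build_contingency(truth, run_ssap(x, seeds, phi = 3)))
  expect_gte(f_ssap, f_ap)
})

test_that("run_ssap is deterministic and flags seeds for evaluation", {
  pool <- make_labeled_pool(2, 5, seed = 17)
  seeds <- construct_seed_set(pool, per_class = 2, rng_seed = 18)
  r1 <- run_ssap(pool, seeds, phi = 2)
  r2 <- run_ssap(pool, seeds, phi = 2)
  expect_identical(r1$cluster, r2$cluster)
  expect_equal(sum(r1$is_seed), 4L)
  tab <- build_contingency(attr(pool, "truth"), r1, exclude_seeds = TRUE)
  expect_equal(sum(tab$counts), length(pool$documents) - 4L)
})

test_that("seed file TSV round-trips", {
  seeds <- seed_set(c(d1 = "alpha", d2 = "beta"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_seed_file(seeds, path)
  back <- read_seed_file(path)
  expect_identical(back$entries, seeds$entries)
})
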