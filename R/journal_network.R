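# Directed journal relationship network derived from a class-by-cluster
# contingency table, with the small-world statistics used to characterise it.
#
# Each cluster is identified with its dominant journal (the class contributing
# the most articles). A directed edge A -> B with weight w is drawn when
# journal B contributes w >= threshold articles to the cluster dominated by A:
# B's authors publish work that lands in A's topical territory. (The transpose
# convention — the contributor points at the dominant journal — is available
# via `convention = "literal"`; the two yield the same edge count.)

#' Dominant class of every cluster
#'
#' @param table A `contingency_table`.
#' @return Named character vector: cluster id -> class label with the maximum
#'   count in that column. Ties go to the lowest class order with a warning.
#' @export
dominant_class_per_cluster <- function(table) {
  counts <- table$counts
  if (any(colSums(counts) == 0L)) {
    stop("cluster with no members: ",
         table$clusters[which(colSums(counts) == 0L)[1L]], call. = FALSE)
  }
  out <- character(ncol(counts))
  for (g in seq_len(ncol(counts))) {
    col <- counts[, g]
    top <- which(col == max(col))
    if (length(top) > 1L) {
      warning(sprintf("cluster %s: dominant class tie between {%s}; taking '%s'",
                      table$clusters[g], paste(table$classes[top], collapse = ", "),
                      table$classes[top[1L]]), call. = FALSE)
    }
    out[g] <- table$classes[top[1L]]
  }
  names(out) <- table$clusters
  out
}

#' Homologous-text counts per cluster
#'
#' Homologous texts of a cluster are its members whose class differs from the
#' cluster's dominant class: `N_g - N_{dominant(g), g}`.
#'
#' @param table A `contingency_table`.
#' @param dominant Optional mapping from [dominant_class_per_cluster()].
#' @return List with `per_cluster` (named integer vector) and `total`.
#' @export
homologous_counts <- function(table, dominant = NULL) {
  dominant <- dominant %||% dominant_class_per_cluster(table)
  counts <- table$counts
  per <- vapply(seq_len(ncol(counts)), function(g) {
    sum(counts[, g]) - counts[dominant[g], g]
  }, numeric(1))
  per <- as.integer(per)
  names(per) <- table$clusters
  list(per_cluster = per, total = sum(per))
}

#' Build the directed relationship network
#'
#' @param table A `contingency_table` (classes = journals).
#' @param threshold Minimum article count for an edge (default 2, the
#'   "at least two articles" rule).
#' @param convention `"degree_consistent"` (default): edge A -> B when journal
#'   B has >= threshold articles in the cluster dominated by A — the
#'   orientation consistent with the reported per-journal out-degrees.
#'   `"literal"`: the transposed reading (the contributing journal points at
#'   the dominant journal). Both conventions give the same number of edges.
#' @return An object of class `relationship_network`: `nodes` (all classes),
#'   `edges` (data.frame `from`, `to`, `weight`), `dominant_of`, `threshold`,
#'   `convention`. Self-loops are never created.
#' @export
build_relationship_network <- function(table, threshold = 2L,
                                       convention = c("degree_consistent", "literal")) {
  convention <- match.arg(convention)
  threshold <- as.integer(threshold)
  if (threshold < 1L) stop("`threshold` must be >= 1", call. = FALSE)
  dominant <- dominant_class_per_cluster(table)
  counts <- table$counts
  from <- to <- character(0)
  weight <- integer(0)
  for (g in seq_len(ncol(counts))) {
    a <- dominant[g]
    contributors <- which(counts[, g] >= threshold & table$classes != a)
    for (h in contributors) {
      b <- table$classes[h]
      if (convention == "degree_consistent") {
        from <- c(from, a); to <- c(to, b)
      } else {
        from <- c(from, b); to <- c(to, a)
      }
      weight <- c(weight, counts[h, g])
    }
  }
  edges <- data.frame(from = from, to = to, weight = weight,
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {  # two clusters dominated by the same journal
      weight <- tapply(edges$weight, key, sum)
      parts <- strsplit(names(weight), "\r", fixed = TRUE)
      edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                          to = vapply(parts, `[`, "", 2L),
                          weight = as.integer(weight), stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = table$classes, edges = edges, dominant_of = dominant,
                 threshold = threshold, convention = convention),
            class = "relationship_network")
}

#' @export
print.relationship_network <- function(x, ...) {
  cat(sprintf("<relationship_network> %d nodes, %d directed edges (threshold %d, %s)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$convention))
  invisible(x)
}

# 0/1 adjacency matrix in node order
adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))] <- 1L
  }
  A
}

#' Degree statistics of the relationship network
#'
#' @param net A `relationship_network`.
#' @return List with `degrees` (data.frame `node`, `out`, `in_`),
#'   `median_out_degree`, and `avg_neighbors` (mean number of distinct
#'   neighbors per node, edge direction ignored: 2 x adjacent unordered pairs
#'   / number of nodes).
#' @export
degree_stats <- function(net) {
  A <- adjacency(net)
  U <- (A + t(A)) > 0
  degrees <- data.frame(node = net$nodes, out = rowSums(A), in_ = colSums(A),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(degrees = degrees,
       median_out_degree = stats::median(degrees$out),
       avg_neighbors = sum(U) / nrow(A))
}

#' Directed clustering coefficient
#'
#' Per node: with undirected neighbor set of size k and e directed edges among
#' those neighbors, `C = e / (k (k - 1))`; 0 when k < 2. This is the directed
#' convention of the common desktop network-analysis tools, which counts each
#' direction among neighbors separately.
#'
#' @param net A `relationship_network`.
#' @return List with `per_node` (named numeric) and `mean`.
#' @export
directed_clustering_coefficient <- function(net) {
  A <- adjacency(net)
  U <- (A + t(A)) > 0
  per <- vapply(seq_len(nrow(A)), function(i) {
    nb <- which(U[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  names(per) <- net$nodes
  list(per_node = per, mean = mean(per))
}

#' Directed shortest-path statistics
#'
#' Breadth-first search from every node along edge directions (all edges count
#' as length 1). Only ordered pairs with a finite directed path enter the
#' statistics.
#'
#' @param net A `relationship_network`.
#' @return List with `characteristic_path_length` (mean finite distance),
#'   `diameter` (max finite distance), `radius` (minimum out-eccentricity over
#'   nodes that reach at least one other node), and `n_shortest_paths` (number
#'   of ordered pairs with a finite path). All `NA` for an edgeless network.
#' @export
path_stats <- function(net) {
  A <- adjacency(net)
  n <- nrow(A)
  if (sum(A) == 0L) {
    return(list(characteristic_path_length = NA_real_, diameter = NA_real_,
                radius = NA_real_, n_shortest_paths = 0L))
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & is.infinite(dist))
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  off <- D[row(D) != col(D)]
  finite <- off[is.finite(off)]
  ecc <- apply(D, 1L, function(dr) {
    dr <- dr[is.finite(dr) & dr > 0]
    if (length(dr)) max(dr) else NA_real_
  })
  list(characteristic_path_length = mean(finite),
       diameter = max(finite),
       radius = min(ecc, na.rm = TRUE),
       n_shortest_paths = length(finite))
}

#' Number of weakly connected components
#'
#' Connected components of the network with edge directions ignored.
#'
#' @param net A `relationship_network`.
#' @return Integer count (isolated nodes each form a component).
#' @export
weak_components <- function(net) {
  U <- (adjacency(net) + t(adjacency(net))) > 0
  n <- nrow(U)
  comp <- rep(0L, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nxt <- which(colSums(U[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  k
}

#' Summary statistics of a relationship network
#'
#' @param net A `relationship_network`.
#' @return List with `n_nodes`, `n_edges`, `clustering_coefficient`,
#'   `characteristic_path_length`, `radius`, `diameter`, `n_shortest_paths`,
#'   `density` (directed, E / (n (n - 1))), `avg_neighbors`,
#'   `median_out_degree`, `n_components`.
#' @export
network_stats <- function(net) {
  n <- length(net$nodes)
  deg <- degree_stats(net)
  cc <- directed_clustering_coefficient(net)
  ps <- path_stats(net)
  list(n_nodes = n,
       n_edges = nrow(net$edges),
       clustering_coefficient = cc$mean,
       characteristic_path_length = ps$characteristic_path_length,
       radius = ps$radius,
       diameter = ps$diameter,
       n_shortest_paths = ps$n_shortest_paths,
       density = if (n > 1L) nrow(net$edges) / (n * (n - 1)) else NA_real_,
       avg_neighbors = deg$avg_neighbors,
       median_out_degree = deg$median_out_degree,
       n_components = weak_components(net))
}

#' Write a relationship network as edge-list TSV or GraphML
#'
#' @param net A `relationship_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(
    rbind(c("source", "target", "weight"), as.matrix(net$edges)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="int"/>',
    '  <graph id="G" edgedefault="directed">',
    sprintf('    <node id="%s"/>', esc(net$nodes)),
    if (nrow(net$edges)) {
      sprintf('    <edge source="%s" target="%s"><data key="w">%d</data></edge>',
              esc(net$edges$from), esc(net$edges$to), net$edges$weight)
    },
    '  </graph>',
    '</graphml>')
  writeLines(lines, path)
  invisible(path)
}
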