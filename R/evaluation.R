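# Clustering evaluation against known class labels: the class-by-cluster
# contingency table, the class-weighted global F-measure, and the
# cluster-weighted entropy (Steinbach-style definitions, the standard ones in
# document clustering).

#' Contingency table of classes by clusters
#'
#' @param counts Nonnegative integer matrix, rows = classes, columns =
#'   clusters; dimnames supply the labels.
#' @param classes,clusters Optional label vectors overriding the dimnames.
#' @return An object of class `contingency_table` with `classes`, `clusters`
#'   and the `counts` matrix.
#' @export
contingency_table <- function(counts, classes = rownames(counts),
                              clusters = colnames(counts)) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty contingency table", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be nonnegative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  classes <- as.character(classes %||% seq_len(nrow(counts)))
  clusters <- as.character(clusters %||% seq_len(ncol(counts)))
  dimnames(counts) <- list(classes, clusters)
  structure(list(classes = classes, clusters = clusters, counts = counts),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d classes x %d clusters, %d objects\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Cross-tabulate true classes against a clustering
#'
#' @param truth Named character vector mapping document id to class label.
#' @param result A `clustering_result`.
#' @param exclude_seeds Drop seed documents before counting (default `TRUE`),
#'   so the metrics describe the unlabeled data only.
#' @return A `contingency_table`; every counted document must have a label.
#' @export
build_contingency <- function(truth, result, exclude_seeds = TRUE) {
  keep <- rep(TRUE, length(result$ids))
  if (exclude_seeds && !is.null(result$is_seed)) keep <- !result$is_seed
  ids <- result$ids[keep]
  cl <- result$cluster[keep]
  lab <- unname(truth[ids])
  if (anyNA(lab)) {
    stop("no truth label for document(s): ",
         paste(utils::head(ids[is.na(lab)], 5L), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(lab, levels = sort(unique(lab), method = "radix")),
                  factor(cl, levels = sort(unique(cl))))
  contingency_table(unclass(counts))
}

#' Global F-measure of a clustering
#'
#' `F = sum_h (N_h / N) * max_g F(h, g)` with
#' `F(h, g) = 2 P R / (P + R)`, `P = N_hg / N_g`, `R = N_hg / N_h`, and
#' `F(h, g) = 0` whenever `N_hg = 0`. Ranges over \[0, 1\]; 1 iff the clusters
#' reproduce the classes exactly.
#'
#' @param table A `contingency_table`.
#' @return A real number in \[0, 1\].
#' @export
f_measure <- function(table) {
  counts <- table$counts
  N <- sum(counts)
  if (N == 0L) stop("empty contingency table", call. = FALSE)
  Nh <- rowSums(counts)
  Ng <- colSums(counts)
  P <- sweep(counts, 2L, pmax(Ng, 1L), "/")
  R <- sweep(counts, 1L, pmax(Nh, 1L), "/")
  Fhg <- matrix(0, nrow(counts), ncol(counts))
  nz <- counts > 0L
  Fhg[nz] <- 2 * P[nz] * R[nz] / (P[nz] + R[nz])
  sum(Nh / N * apply(Fhg, 1L, max))
}

#' Entropy of a clustering
#'
#' Cluster-size-weighted impurity: `E = sum_g (N_g / N) * E_g` with
#' `E_g = -sum_h p_hg log(p_hg)`, `p_hg = N_hg / N_g`, and `0 log 0 = 0`.
#' With `normalized = TRUE` (default) logarithms are taken base H (the number
#' of classes) so a uniformly mixed cluster scores 1 and pure clusters 0.
#'
#' @param table A `contingency_table`.
#' @param normalized Use base-H logs (default) or natural logs.
#' @return A nonnegative real; in \[0, 1\] when normalized.
#' @export
cluster_entropy <- function(table, normalized = TRUE) {
  counts <- table$counts
  N <- sum(counts)
  if (N == 0L) stop("empty contingency table", call. = FALSE)
  H <- nrow(counts)
  if (normalized && H == 1L) return(0)
  base <- if (normalized) H else exp(1)
  Ng <- colSums(counts)
  Eg <- vapply(seq_len(ncol(counts)), function(g) {
    if (Ng[g] == 0L) return(0)
    p <- counts[, g] / Ng[g]
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }, numeric(1))
  sum(Ng / N * Eg)
}

#' Read / write a contingency table as CSV
#'
#' First column holds the class labels (header `class`), remaining columns one
#' per cluster.
#'
#' @param path File path.
#' @return A `contingency_table` (read) or `path` (write).
#' @export
read_contingency_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("malformed contingency CSV (no counts): ", path, call. = FALSE)
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("malformed contingency CSV (non-numeric counts): ", path,
                           call. = FALSE)
  contingency_table(m)
}

#' @rdname read_contingency_csv
#' @param table A `contingency_table`.
#' @export
write_contingency_csv <- function(table, path) {
  out <- as.data.frame(table$counts)
  out <- cbind(class = table$classes, out)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
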