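# Vector-space-model k-means baseline.
#
# The comparison method: every document becomes a dense vector of normalized
# term frequencies over the *global* vocabulary and Lloyd's algorithm runs
# with Euclidean distance — precisely the high-dimensional sparse computation
# the sub-space cosine approach avoids. Implemented here (rather than via
# stats::kmeans) because the contract requires deterministic per-restart
# random centroid initialization and empty-cluster repair by reseeding from
# the farthest point; stats::kmeans aborts on empty clusters under Lloyd.

#' Dense document-term matrix of a corpus
#'
#' Rows are documents (corpus order), columns the sorted global vocabulary,
#' entries the normalized term frequencies (zero where a term is absent).
#'
#' @param x A `corpus`.
#' @return A numeric matrix with dimnames (document ids, terms).
#' @export
corpus_matrix <- function(x) {
  docs <- x$documents
  vocab <- sort(unique(unlist(lapply(docs, `[[`, "terms"), use.names = FALSE)),
                method = "radix")
  X <- matrix(0, length(docs), length(vocab),
              dimnames = list(names(docs), vocab))
  for (i in seq_along(docs)) {
    X[i, match(docs[[i]]$terms, vocab)] <- docs[[i]]$n
  }
  X
}

#' k-means clustering on the global vector space model
#'
#' Lloyd's algorithm with Euclidean distance on the dense normalized-frequency
#' matrix. Each restart draws k distinct documents as initial centroids; an
#' empty cluster is repaired by reseeding its centroid from the point farthest
#' from its current centroid. The restart with the lowest inertia (within-
#' cluster sum of squared distances) wins.
#'
#' @param x A `corpus`.
#' @param k Number of clusters (typically the number of known classes).
#' @param restarts Number of random restarts (default 10).
#' @param rng_seed Seed controlling all centroid draws.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A `clustering_result` (the representative of each cluster is its
#'   medoid, the member closest to the centroid) with attribute `inertia`.
#' @export
kmeans_vsm <- function(x, k, restarts = 10L, rng_seed = 1L, max_iter = 100L) {
  X <- corpus_matrix(x)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " exceeds the number of documents (", n, ")", call. = FALSE)
  if (restarts < 1L) stop("`restarts` must be >= 1", call. = FALSE)
  best <- NULL
  with_seed(rng_seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(X, as.integer(k), as.integer(max_iter))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  # medoid representative per cluster, so the result satisfies the
  # exemplar-maps-to-itself invariant shared with affinity propagation
  exemplar <- integer(n)
  for (c in seq_len(k)) {
    members <- which(best$assignment == c)
    d2 <- rowSums((X[members, , drop = FALSE] -
                     matrix(best$centers[c, ], length(members), ncol(X), byrow = TRUE))^2)
    exemplar[members] <- members[which.min(d2)]
  }
  res <- clustering_result(exemplar, ids = rownames(X), converged = best$converged,
                           iterations = best$iterations)
  attr(res, "inertia") <- best$inertia
  res
}

lloyd_once <- function(X, k, max_iter) {
  n <- nrow(X)
  centers <- X[sample.int(n, k), , drop = FALSE]
  asg_prev <- integer(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- euclid2(X, centers)
    asg <- max.col(-d2, ties.method = "first")
    for (empty in which(tabulate(asg, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), asg)])
      centers[empty, ] <- X[far, ]
      asg[far] <- empty
      d2[, empty] <- rowSums(sweep(X, 2L, centers[empty, ])^2)
    }
    if (identical(asg, asg_prev)) {
      converged <- TRUE
      break
    }
    asg_prev <- asg
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(X[asg == c, , drop = FALSE])
    }
  }
  d2 <- euclid2(X, centers)
  list(assignment = asg, centers = centers,
       inertia = sum(d2[cbind(seq_len(n), asg)]),
       converged = converged, iterations = it)
}

# squared Euclidean distances between rows of X and rows of C
euclid2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  pmax(d2, 0)
}
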