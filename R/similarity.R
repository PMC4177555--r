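# Pairwise cosine similarity computed in the sub-space of each document pair.
#
# A corpus of full texts has a huge global vocabulary, but any single pair of
# documents only shares a handful of terms. Each pairwise similarity is
# therefore computed over the terms of the two documents alone; this is an
# exact shortcut (terms outside the pair contribute zero to the dot product),
# not an approximation.

#' Cosine similarity of two documents
#'
#' Computed in the sub-space spanned by the two documents' own terms. The
#' default weighted variant uses normalized term frequencies:
#' sum over shared terms of n_i * n_j, divided by the L2 norms. The `"set"`
#' variant ignores frequencies and scores |intersection| / sqrt(|d_i| * |d_j|)
#' where |d| is the number of unique terms.
#'
#' @param d_i,d_j `document` objects.
#' @param variant `"weighted"` (default) or `"set"`.
#' @return Similarity in \[0, 1\]; 1 iff the normalized vectors coincide
#'   (weighted) or the term sets coincide (set).
#' @export
cosine_similarity <- function(d_i, d_j, variant = c("weighted", "set")) {
  variant <- match.arg(variant)
  if (length(d_i$terms) == 0L || length(d_j$terms) == 0L) {
    stop("cosine similarity of an empty document is undefined", call. = FALSE)
  }
  m <- match(d_i$terms, d_j$terms)
  shared <- which(!is.na(m))
  if (variant == "set") {
    return(length(shared) / sqrt(length(d_i$terms) * length(d_j$terms)))
  }
  if (length(shared) == 0L) return(0)
  dot <- sum(d_i$n[shared] * d_j$n[m[shared]])
  dot / (sqrt(sum(d_i$n^2)) * sqrt(sum(d_j$n^2)))
}

#' Build the pairwise similarity matrix of a corpus
#'
#' Fills all off-diagonal entries with pairwise cosine similarities (each pair
#' evaluated in its own term sub-space); the diagonal is left `NA` until
#' [set_preferences()] fills the self-similarities. Internally terms are
#' recoded to integers purely to speed up per-pair matching; every pair is
#' still processed over its own terms only.
#'
#' @param x A `corpus` with at least 2 documents.
#' @param variant Passed to [cosine_similarity()].
#' @return A symmetric N x N matrix with `NA` diagonal, dimnames = document
#'   ids, and attribute `variant`.
#' @export
build_similarity_matrix <- function(x, variant = c("weighted", "set")) {
  variant <- match.arg(variant)
  docs <- x$documents
  n <- length(docs)
  if (n < 2L) stop("similarity matrix needs at least 2 documents", call. = FALSE)
  nterms <- vapply(docs, function(d) length(d$terms), integer(1))
  if (any(nterms == 0L)) {
    stop("empty document: ", names(docs)[which(nterms == 0L)[1L]], call. = FALSE)
  }
  dict <- unique(unlist(lapply(docs, `[[`, "terms"), use.names = FALSE))
  term_ids <- lapply(docs, function(d) match(d$terms, dict))
  weights <- lapply(docs, `[[`, "n")
  norms <- vapply(weights, function(w) sqrt(sum(w^2)), numeric(1))
  S <- matrix(0, n, n, dimnames = list(names(docs), names(docs)))
  for (i in seq_len(n - 1L)) {
    ti <- term_ids[[i]]
    wi <- weights[[i]]
    for (j in (i + 1L):n) {
      m <- match(ti, term_ids[[j]])
      shared <- which(!is.na(m))
      if (length(shared)) {
        S[i, j] <- S[j, i] <- if (variant == "set") {
          length(shared) / sqrt(nterms[i] * nterms[j])
        } else {
          sum(wi[shared] * weights[[j]][m[shared]]) / (norms[i] * norms[j])
        }
      }
    }
  }
  diag(S) <- NA_real_
  attr(S, "variant") <- variant
  S
}

#' Set the diagonal preferences of a similarity matrix
#'
#' Every diagonal entry (self-similarity s(l,l), the affinity-propagation
#' preference) is set to `phi` times an aggregate of the off-diagonal
#' similarities. Larger preferences make more documents become exemplars,
#' i.e. more clusters; `phi` is the adjustable factor.
#'
#' @param S Similarity matrix from [build_similarity_matrix()].
#' @param phi Positive scale factor (typical settings: around 0.5-1 for plain
#'   affinity propagation, 3 when seed-guided merging follows).
#' @param mode Aggregate of the off-diagonal entries: `"mean"` (default),
#'   `"median"`, or `"min"`.
#' @return `S` with all diagonal entries equal to the preference; attribute
#'   `preference` records the value.
#' @export
set_preferences <- function(S, phi = 1, mode = c("mean", "median", "min")) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(phi, "phi", min = .Machine$double.xmin)
  if (!is.matrix(S) || nrow(S) < 2L) {
    stop("preferences need a similarity matrix over at least 2 documents", call. = FALSE)
  }
  off <- S[upper.tri(S) | lower.tri(S)]
  if (any(!is.finite(off))) stop("off-diagonal similarities must be computed first",
                                 call. = FALSE)
  agg <- switch(mode, mean = mean(off), median = stats::median(off), min = min(off))
  pref <- phi * agg
  diag(S) <- pref
  attr(S, "preference") <- pref
  attr(S, "phi") <- phi
  attr(S, "preference_mode") <- mode
  S
}

#' Write / read a similarity matrix as CSV
#'
#' Row/column order is corpus order; intended for debugging and fixtures.
#'
#' @param S Similarity matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_csv <- function(S, path) {
  utils::write.csv(S, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}
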