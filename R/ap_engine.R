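# Affinity propagation message passing.
#
# Exemplar-based clustering by exchanging two kinds of real-valued messages on
# the similarity matrix: responsibilities r(i,k) (how well suited candidate k
# is to serve as i's exemplar, relative to other candidates) and
# availabilities a(i,k) (accumulated evidence that k should be an exemplar).
# The updates are the canonical ones of Frey & Dueck (2007, Science), damped
# to prevent oscillation; the implementation is fully deterministic (ties go
# to the lowest index, no random jitter).

#' Affinity propagation configuration
#'
#' @param damping Message damping in \[0, 1): new message =
#'   `damping * old + (1 - damping) * raw`. Default 0.5.
#' @param max_iterations Hard iteration cap (default 1000).
#' @param convergence_window Stop once the exemplar set has been unchanged for
#'   this many consecutive iterations (default 100).
#' @param rng_seed Accepted for interface symmetry with the other engines and
#'   recorded in run manifests; the message passing itself is deterministic,
#'   so the value is never consumed.
#' @return An object of class `ap_config`.
#' @export
ap_config <- function(damping = 0.5, max_iterations = 1000L,
                      convergence_window = 100L, rng_seed = NA_integer_) {
  if (damping < 0 || damping >= 1) stop("`damping` must be in [0, 1)", call. = FALSE)
  max_iterations <- as.integer(max_iterations)
  convergence_window <- as.integer(convergence_window)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (convergence_window < 1L || convergence_window > max_iterations) {
    stop("`convergence_window` must be in [1, max_iterations]", call. = FALSE)
  }
  structure(list(damping = damping, max_iterations = max_iterations,
                 convergence_window = convergence_window, rng_seed = rng_seed),
            class = "ap_config")
}

#' Responsibility update
#'
#' Raw update `r(i,k) = s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]`, then
#' damped against `R_prev`.
#'
#' @param S Similarity matrix with preferences on the diagonal.
#' @param A Current availability matrix.
#' @param R_prev Previous responsibility matrix.
#' @param damping Damping factor in \[0, 1).
#' @return Updated responsibility matrix.
#' @export
update_responsibilities <- function(S, A, R_prev, damping = 0.5) {
  if (!all(is.finite(S)) || !all(is.finite(A))) {
    stop("non-finite values in message-passing input", call. = FALSE)
  }
  n <- nrow(S)
  AS <- A + S
  top <- row_top2(AS)
  R_raw <- S - top$max             # competitor max includes column k itself...
  idx <- cbind(seq_len(n), top$which)
  R_raw[idx] <- S[idx] - top$second  # ...so the argmax column uses the runner-up
  damping * R_prev + (1 - damping) * R_raw
}

#' Availability update
#'
#' Raw update, for i != k: `a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}}
#' max(0, r(i',k)))`; self-availability `a(k,k) = sum_{i' != k} max(0,
#' r(i',k))`. Damped against `A_prev`. Off-diagonal availabilities are never
#' positive.
#'
#' @param R Current responsibility matrix.
#' @param A_prev Previous availability matrix.
#' @param damping Damping factor in \[0, 1).
#' @return Updated availability matrix.
#' @export
update_availabilities <- function(R, A_prev, damping = 0.5) {
  if (!all(is.finite(R))) stop("non-finite values in message-passing input", call. = FALSE)
  n <- nrow(R)
  Rp <- pmax(R, 0)
  diag(Rp) <- diag(R)  # self-responsibility enters the sum un-thresholded
  colsum <- colSums(Rp)
  A_raw <- matrix(colsum, n, n, byrow = TRUE) - Rp
  self <- diag(A_raw)
  A_raw <- pmin(A_raw, 0)
  diag(A_raw) <- self
  damping * A_prev + (1 - damping) * A_raw
}

#' Select exemplars and form clusters from the messages
#'
#' Each document's exemplar is the maximizer of `r(i,j) + a(i,j)` (ties to the
#' lowest index). A consistency pass then fixes the exemplar set to the
#' self-electing documents and reassigns every other document to its most
#' similar exemplar under `S`, so the result is always a valid partition.
#'
#' @param R,A Message matrices.
#' @param S Similarity matrix (used for the reassignment pass).
#' @return A `clustering_result`; see [clustering_result()].
#' @export
select_exemplars <- function(R, A, S) {
  n <- nrow(R)
  if (is.null(n) || n == 0L) stop("empty message matrices", call. = FALSE)
  E <- R + A
  pref <- max.col(E, ties.method = "first")
  K <- which(pref == seq_len(n))
  if (length(K) == 0L) K <- which.max(diag(E))  # degenerate: force one exemplar
  exemplar <- integer(n)
  exemplar[K] <- K
  others <- setdiff(seq_len(n), K)
  if (length(others)) {
    SK <- S[others, K, drop = FALSE]
    exemplar[others] <- K[max.col(SK, ties.method = "first")]
  }
  clustering_result(exemplar, ids = rownames(S))
}

#' Clustering result container
#'
#' @param exemplar Integer vector: `exemplar[i]` is the index of document i's
#'   exemplar; exemplars map to themselves.
#' @param ids Optional character vector of document ids.
#' @param converged,iterations Run diagnostics.
#' @param is_seed Optional logical vector flagging seed documents.
#' @return An object of class `clustering_result` with fields `exemplar`,
#'   `cluster` (contiguous 1..G ids), `clusters` (list of member indices per
#'   cluster), `cluster_labels` (`NA` until label merging), `ids`, `is_seed`,
#'   `converged`, `iterations`.
#' @export
clustering_result <- function(exemplar, ids = NULL, converged = NA,
                              iterations = NA_integer_, is_seed = NULL) {
  exemplar <- as.integer(exemplar)
  n <- length(exemplar)
  K <- sort(unique(exemplar))
  if (!all(exemplar[K] == K)) stop("exemplars must map to themselves", call. = FALSE)
  cluster <- match(exemplar, K)
  clusters <- split(seq_len(n), cluster)
  names(clusters) <- NULL
  structure(
    list(exemplar = exemplar, cluster = cluster, clusters = clusters,
         cluster_labels = rep(NA_character_, length(K)),
         ids = ids %||% as.character(seq_len(n)),
         is_seed = is_seed %||% rep(FALSE, n),
         converged = converged, iterations = iterations),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d documents in %d clusters%s\n",
              length(x$cluster), length(x$clusters),
              if (isTRUE(x$converged)) sprintf(" (converged, %d iterations)", x$iterations)
              else if (identical(x$converged, FALSE)) " (not converged)" else ""))
  invisible(x)
}

#' Run affinity propagation
#'
#' Alternates responsibility and availability updates on `S` (preferences must
#' already be on the diagonal), monitoring the set of self-electing exemplars;
#' stops when that set is unchanged for `convergence_window` consecutive
#' iterations, or at `max_iterations`. Deterministic for fixed inputs.
#'
#' @param S Similarity matrix with finite diagonal preferences.
#' @param config An [ap_config()].
#' @return A `clustering_result`.
#' @export
run_ap <- function(S, config = ap_config()) {
  if (!is.matrix(S)) S <- as.matrix(S)
  if (!all(is.finite(S))) {
    stop("similarity matrix must be finite with preferences set on the diagonal",
         call. = FALSE)
  }
  n <- nrow(S)
  if (n == 1L) {
    return(clustering_result(1L, ids = rownames(S), converged = TRUE, iterations = 0L))
  }
  # Exactly tied similarities (common when documents share no terms) make the
  # message dynamics oscillate between symmetric solutions; like the canonical
  # implementations, break degeneracies with an eps-scale perturbation. Seeded
  # from the config (fixed default), so runs stay bitwise reproducible.
  S_in <- S
  jitter_seed <- if (is.na(config$rng_seed)) 0L else config$rng_seed
  scale <- .Machine$double.eps * diff(range(S))
  if (scale > 0) {
    S <- S + with_seed(jitter_seed, matrix(stats::rnorm(n * n), n, n)) * scale
  }
  R <- A <- matrix(0, n, n)
  stable <- 0L
  last_K <- NULL
  it <- 0L
  for (it in seq_len(config$max_iterations)) {
    R <- update_responsibilities(S, A, R, config$damping)
    A <- update_availabilities(R, A, config$damping)
    E <- R + A
    K <- which(max.col(E, ties.method = "first") == seq_len(n))
    if (identical(K, last_K)) stable <- stable + 1L else stable <- 0L
    last_K <- K
    if (stable >= config$convergence_window) break
  }
  res <- select_exemplars(R, A, S)
  res$converged <- stable >= config$convergence_window
  res$iterations <- it
  # Oscillation fallback: when the messages fail to settle, heavier damping is
  # the standard remedy. Retry once at 0.9 and keep whichever solution scores
  # better under the method's own objective; still deterministic.
  if (!res$converged && config$damping < 0.9) {
    config$damping <- 0.9
    alt <- run_ap(S_in, config)
    if (net_similarity(S_in, alt) > net_similarity(S_in, res)) return(alt)
  }
  res
}

#' Net similarity of a clustering
#'
#' The affinity-propagation objective: `sum_i s(i, exemplar(i))`, with the
#' diagonal preference counted for exemplars themselves.
#'
#' @param S Similarity matrix with preferences on the diagonal.
#' @param result A `clustering_result` over the same documents.
#' @return A finite real number.
#' @export
net_similarity <- function(S, result) {
  n <- nrow(S)
  if (length(result$exemplar) != n) {
    stop("clustering result does not match the similarity matrix size", call. = FALSE)
  }
  sum(S[cbind(seq_len(n), result$exemplar)])
}
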