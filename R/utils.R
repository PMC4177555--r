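# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state, so
#' that seeded operations (seed sampling, corpus generation, k-means restarts)
#' are reproducible without clobbering the global random stream.
#'
#' @param seed Integer seed, or `NULL`/`NA` to evaluate without reseeding.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(code)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# row-wise largest and second-largest values of a matrix, ties to lowest column
row_top2 <- function(M) {
  n <- nrow(M)
  j1 <- max.col(M, ties.method = "first")
  idx <- cbind(seq_len(n), j1)
  m1 <- M[idx]
  M[idx] <- -Inf
  m2 <- M[cbind(seq_len(n), max.col(M, ties.method = "first"))]
  list(max = m1, which = j1, second = m2)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, min), call. = FALSE)
  }
  invisible(x)
}
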