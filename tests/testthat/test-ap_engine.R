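test_that("responsibility update matches the hand-worked two-document case", {
  # s(1,2)=s(2,1)=0.5, preferences 0.2, availabilities zero, no damping
  S <- matrix(c(0.2, 0.5, 0.5, 0.2), 2, 2)
  R <- update_responsibilities(S, matrix(0, 2, 2), matrix(0, 2, 2), damping = 0)
  expect_equal(R[1, 1], -0.3)
  expect_equal(R[1, 2], 0.3)
  expect_equal(R[2, 2], -0.3)
  expect_equal(R[2, 1], 0.3)
})

test_that("first responsibility update equals the closed form on random input", {
  set.seed(14)
  n <- 6
  S <- matrix(runif(n * n), n, n)
  R <- update_responsibilities(S, matrix(0, n, n), matrix(0, n, n), damping = 0)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      expect_equal(R[i, k], S[i, k] - max(S[i, -k]), tolerance = 1e-14)
    }
  }
})

test_that("availability update matches the hand-worked case and stays nonpositive", {
  # two documents, r(2,2) = -0.3, no third parties: a(1,2) = min(0, -0.3)
  R <- matrix(c(-0.3, 0.3, 0.3, -0.3), 2, 2)
  A <- update_availabilities(R, matrix(0, 2, 2), damping = 0)
  expect_equal(A[1, 2], -0.3)
  expect_equal(A[2, 1], -0.3)
  # self-availability = sum of positive incoming responsibilities
  expect_equal(A[1, 1], 0.3)

  set.seed(15)
  for (rep in 1:5) {
    Rr <- matrix(rnorm(49), 7, 7)
    Ar <- update_availabilities(Rr, matrix(0, 7, 7), damping = 0)
    expect_true(all(Ar[row(Ar) != col(Ar)] <= 0))
  }
  # all-negative responsibilities give zero self-availability
  Rneg <- -matrix(runif(16, 0.1, 1), 4, 4)
  expect_equal(unname(diag(update_availabilities(Rneg, matrix(0, 4, 4), 0))),
               rep(0, 4))
})

test_that("damped updates are fixed points when old equals raw", {
  set.seed(16)
  S <- matrix(runif(25), 5, 5)
  A <- matrix(0, 5, 5)
  R0 <- update_responsibilities(S, A, matrix(0, 5, 5), damping = 0)
  expect_equal(update_responsibilities(S, A, R0, damping = 0.5), R0,
               tolerance = 1e-14)
  A0 <- update_availabilities(R0, matrix(0, 5, 5), damping = 0)
  expect_equal(update_availabilities(R0, A0, damping = 0.5), A0, tolerance = 1e-14)
})

test_that("select_exemplars breaks ties toward the lowest index and partitions", {
  # document 3 prefers column 1; columns 1 and 2 self-elect
  E_half <- diag(c(1, 1, 0))
  R <- E_half
  A <- matrix(0, 3, 3)
  S <- matrix(c(1, 0, 0.9, 0, 1, 0.1, 0.9, 0.1, 0), 3, 3, byrow = TRUE)
  res <- select_exemplars(R, A, S)
  expect_equal(res$exemplar, c(1L, 2L, 1L))
  expect_length(res$clusters, 2L)
  expect_setequal(unlist(res$clusters), 1:3)

  # exact tie between two self-electing columns for a third document
  S2 <- matrix(0.5, 3, 3); diag(S2) <- 1
  R2 <- diag(c(1, 1, 0)); A2 <- matrix(0, 3, 3)
  res2 <- select_exemplars(R2, A2, S2)
  expect_equal(res2$exemplar[3], 1L)
})

test_that("run_ap recovers two well-separated groups", {
  x <- two_group_corpus(3)
  S <- set_preferences(build_similarity_matrix(x), phi = 1)
  res <- run_ap(S)
  expect_length(res$clusters, 2L)
  expect_true(res$converged)
  expect_setequal(res$ids[res$clusters[[1]]], c("g1d1", "g1d2", "g1d3"))
  expect_setequal(res$ids[res$clusters[[2]]], c("g2d1", "g2d2", "g2d3"))
  # and the solution attains the brute-force optimum on 6 documents
  expect_equal(net_similarity(S, res), oracle_best_net_similarity(S),
               tolerance = 1e-6)
})

test_that("run_ap on a single document returns one converged cluster", {
  S <- matrix(0.5, 1, 1, dimnames = list("d", "d"))
  res <- run_ap(S)
  expect_equal(res$exemplar, 1L)
  expect_true(res$converged)
  expect_length(res$clusters, 1L)
})

test_that("run_ap is near-optimal on a random 8-document corpus", {
  set.seed(77)
  x <- random_mini_corpus(8)
  S <- set_preferences(build_similarity_matrix(x), phi = 1)
  res <- run_ap(S)
  expect_gte(net_similarity(S, res), 0.95 * oracle_best_net_similarity(S))
})

test_that("run_ap is deterministic for fixed inputs and config", {
  set.seed(31)
  x <- random_mini_corpus(7)
  S <- set_preferences(build_similarity_matrix(x), phi = 1.5)
  r1 <- run_ap(S)
  r2 <- run_ap(S)
  expect_identical(r1$exemplar, r2$exemplar)
  expect_identical(r1$iterations, r2$iterations)
})

test_that("cluster count does not decrease from small to large preference", {
  set.seed(19)
  for (rep in 1:2) {
    x <- random_mini_corpus(10)
    S <- build_similarity_matrix(x)
    k_lo <- length(run_ap(set_preferences(S, phi = 0.5))$clusters)
    k_hi <- length(run_ap(set_preferences(S, phi = 5))$clusters)
    expect_lte(k_lo, k_hi)
  }
})

test_that("net_similarity sums similarities to exemplars including preferences", {
  S <- matrix(c(0.4, 0.9, 0.9, 0.4), 2, 2)
  all_self <- clustering_result(c(1L, 2L))
  expect_equal(net_similarity(S, all_self), 0.8)
  one <- clustering_result(c(1L, 1L))
  expect_equal(net_similarity(S, one), 0.4 + 0.9)
})

test_that("message updates reject non-finite input and invalid config is caught", {
  S <- matrix(c(0.1, NA, 0.3, 0.1), 2, 2)
  expect_error(update_responsibilities(S, matrix(0, 2, 2), matrix(0, 2, 2), 0),
               "non-finite")
  expect_error(run_ap(S), "finite")
  expect_error(ap_config(damping = 1), "damping")
  expect_error(ap_config(convergence_window = 50, max_iterations = 10),
               "convergence_window")
})
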