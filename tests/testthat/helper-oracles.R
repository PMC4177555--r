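# Independent brute-force oracles. These deliberately share no code with the
# package internals: dense global-vocabulary vectors, literal triple loops,
# exhaustive subset enumeration.

# dense global-vocabulary cosine matrix, built with plain loops
oracle_cosine_matrix <- function(x) {
  docs <- x$documents
  vocab <- sort(unique(unlist(lapply(docs, function(d) d$terms))))
  n <- length(docs)
  X <- matrix(0, n, length(vocab))
  for (i in seq_len(n)) {
    for (j in seq_along(docs[[i]]$terms)) {
      X[i, which(vocab == docs[[i]]$terms[j])] <- docs[[i]]$n[j]
    }
  }
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        S[i, j] <- sum(X[i, ] * X[j, ]) / (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
      }
    }
  }
  S
}

# best achievable net similarity over every non-empty exemplar subset
oracle_best_net_similarity <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    K <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- sum(diag(S)[K])
    for (i in setdiff(seq_len(n), K)) val <- val + max(S[i, K])
    if (val > best) best <- val
  }
  best
}

# literal triple-loop global F-measure
oracle_f_measure <- function(counts) {
  N <- sum(counts)
  total <- 0
  for (h in seq_len(nrow(counts))) {
    Nh <- sum(counts[h, ])
    best <- 0
    for (g in seq_len(ncol(counts))) {
      Nhg <- counts[h, g]
      if (Nhg > 0) {
        P <- Nhg / sum(counts[, g])
        R <- Nhg / Nh
        f <- 2 * P * R / (P + R)
        if (f > best) best <- f
      }
    }
    total <- total + Nh / N * best
  }
  total
}

# literal double-loop clustering entropy
oracle_entropy <- function(counts, normalized = TRUE) {
  N <- sum(counts)
  H <- nrow(counts)
  base <- if (normalized) H else exp(1)
  if (normalized && H == 1) return(0)
  total <- 0
  for (g in seq_len(ncol(counts))) {
    Ng <- sum(counts[, g])
    if (Ng == 0) next
    Eg <- 0
    for (h in seq_len(H)) {
      p <- counts[h, g] / Ng
      if (p > 0) Eg <- Eg - p * log(p) / log(base)
    }
    total <- total + Ng / N * Eg
  }
  total
}

# random contingency table with a positive grand total
random_table <- function(H, G) {
  repeat {
    counts <- matrix(stats::rpois(H * G, lambda = 3), H, G)
    if (sum(counts) > 0) return(counts)
  }
}

# small random corpus over a limited vocabulary (every doc non-empty)
random_mini_corpus <- function(n_docs, vocab_size = 12L, max_count = 5L) {
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  docs <- lapply(seq_len(n_docs), function(i) {
    k <- sample(2:min(6L, vocab_size), 1L)
    document_from_counts(sprintf("d%02d", i), sample(vocab, k),
                         sample(max_count, k, replace = TRUE))
  })
  corpus(docs)
}

# tiny two-group corpus: near-identical documents within groups, disjoint terms
# across groups
two_group_corpus <- function(per_group = 3L) {
  docs <- list()
  for (g in 1:2) {
    base <- sprintf("g%dw%d", g, 1:4)
    for (i in seq_len(per_group)) {
      counts <- c(5L, 5L, 5L, i)  # slight within-group variation
      docs[[length(docs) + 1L]] <-
        document_from_counts(sprintf("g%dd%d", g, i), base, counts)
    }
  }
  corpus(docs)
}

# network fixture helpers: small hand graphs as contingency-free edge objects
manual_network <- function(nodes, from, to) {
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    weight = rep(2L, length(from)),
                                    stringsAsFactors = FALSE),
                 dominant_of = NULL, threshold = 2L,
                 convention = "degree_consistent"),
            class = "relationship_network")
}
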