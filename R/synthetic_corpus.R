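# Synthetic topic-structured corpora with known labels, so every clustering
# stage is testable without an external full-text download. Topics are
# discrete-uniform in size (equal document counts per topic, mirroring the
# balanced benchmark subsets the method targets); each topic owns a disjoint
# vocabulary, and a shared Zipf-weighted background vocabulary supplies
# natural-language-like noise.

#' Specification of a synthetic topic corpus
#'
#' Defaults describe the benchmark condition the package validates against:
#' 10 equally sized topics of 40 documents, 20% background token mixing.
#'
#' @param n_topics Number of topics (classes), >= 1.
#' @param docs_per_topic Documents per topic, >= 1.
#' @param topic_vocab_size Words in each topic's private vocabulary.
#' @param background_vocab_size Words in the shared background vocabulary.
#' @param background_mixing Probability a token is drawn from the background
#'   distribution instead of the topic vocabulary; must be < 1 so every
#'   document keeps topic signal.
#' @param doc_length_mean,doc_length_dispersion Mean and dispersion (negative
#'   binomial `size`) of the token-count distribution per document; lengths
#'   are clamped to at least 10 tokens so no document is empty.
#' @param zipf_exponent Zipf exponent of the background word distribution.
#' @param rng_seed Seed; identical spec + seed gives an identical corpus.
#' @return An object of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_topics = 10L, docs_per_topic = 40L,
                                  topic_vocab_size = 60L,
                                  background_vocab_size = 500L,
                                  background_mixing = 0.2,
                                  doc_length_mean = 150,
                                  doc_length_dispersion = 10,
                                  zipf_exponent = 1.1,
                                  rng_seed = 1L) {
  spec <- list(n_topics = as.integer(n_topics),
               docs_per_topic = as.integer(docs_per_topic),
               topic_vocab_size = as.integer(topic_vocab_size),
               background_vocab_size = as.integer(background_vocab_size),
               background_mixing = background_mixing,
               doc_length_mean = doc_length_mean,
               doc_length_dispersion = doc_length_dispersion,
               zipf_exponent = zipf_exponent,
               rng_seed = as.integer(rng_seed))
  if (spec$n_topics < 1L || spec$docs_per_topic < 1L || spec$topic_vocab_size < 1L) {
    stop("n_topics, docs_per_topic and topic_vocab_size must all be >= 1", call. = FALSE)
  }
  if (spec$background_vocab_size < 0L) {
    stop("background_vocab_size must be >= 0", call. = FALSE)
  }
  if (background_mixing < 0 || background_mixing >= 1) {
    stop("background_mixing must be in [0, 1)", call. = FALSE)
  }
  if (spec$background_vocab_size == 0L && background_mixing > 0) {
    stop("background_mixing > 0 requires a background vocabulary", call. = FALSE)
  }
  if (doc_length_mean <= 0 || doc_length_dispersion <= 0) {
    stop("doc_length_mean and doc_length_dispersion must be positive", call. = FALSE)
  }
  structure(spec, class = "synthetic_corpus_spec")
}

#' Generate a labeled synthetic corpus
#'
#' Every token is drawn independently: with probability `background_mixing`
#' from the shared Zipf-weighted background vocabulary, otherwise uniformly
#' from the document's topic vocabulary. Truth labels are the topic names.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return A `corpus` of `n_topics * docs_per_topic` labeled documents, with
#'   attribute `truth` (named character vector id -> topic label).
#' @export
generate_corpus <- function(spec = synthetic_corpus_spec()) {
  if (!inherits(spec, "synthetic_corpus_spec")) {
    stop("`spec` must be a synthetic_corpus_spec", call. = FALSE)
  }
  bg_vocab <- if (spec$background_vocab_size > 0L) {
    sprintf("bg%04d", seq_len(spec$background_vocab_size))
  } else character(0)
  bg_prob <- if (length(bg_vocab)) {
    w <- seq_along(bg_vocab)^(-spec$zipf_exponent)
    w / sum(w)
  }
  docs <- with_seed(spec$rng_seed, {
    out <- vector("list", spec$n_topics * spec$docs_per_topic)
    i <- 0L
    for (t in seq_len(spec$n_topics)) {
      topic_vocab <- sprintf("t%02dw%03d", t, seq_len(spec$topic_vocab_size))
      label <- sprintf("topic%02d", t)
      for (d in seq_len(spec$docs_per_topic)) {
        len <- max(10L, stats::rnbinom(1L, size = spec$doc_length_dispersion,
                                       mu = spec$doc_length_mean))
        n_bg <- stats::rbinom(1L, len, spec$background_mixing)
        tokens <- c(sample(topic_vocab, len - n_bg, replace = TRUE),
                    if (n_bg > 0L) sample(bg_vocab, n_bg, replace = TRUE, prob = bg_prob))
        i <- i + 1L
        out[[i]] <- build_document(sprintf("t%02dd%03d", t, d), tokens, label = label)
      }
    }
    out
  })
  x <- corpus(docs)
  truth <- corpus_labels(x)
  names(truth) <- corpus_ids(x)
  attr(x, "truth") <- truth
  x
}

#' Packaged journal cluster distribution matrix
#'
#' The bundled 10 x 10 class-by-cluster contingency matrix from a published
#' semi-supervised clustering of 400 BioMed Central open-access articles (40
#' per journal, 10 journals). It is the input for the relationship-network
#' statistics and the homologous-text accounting.
#'
#' @return A `contingency_table` with journal names as classes and clusters
#'   `1`..`10`; grand total 400.
#' @export
biomed_journal_matrix <- function() {
  path <- system.file("extdata", "biomed_cluster_distribution.csv",
                      package = "ssapcluster")
  if (!nzchar(path)) stop("packaged fixture missing", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  tab <- read_contingency_csv(path)
  ok <- sum(tab$counts) == 400L &&
    all(rowSums(tab$counts) == 40L) &&
    nrow(tab$counts) == 10L && ncol(tab$counts) == 10L
  if (!ok) {
    stop("packaged cluster distribution fixture is corrupted (md5 ", md5, ")",
         call. = FALSE)
  }
  tab
}
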