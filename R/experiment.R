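# Reproducible experiment driver tying the stages together: preprocess ->
# cluster -> evaluate, with every setting, seed and input checksum recorded in
# a manifest so a run can be repeated bit for bit. A thin command-line
# wrapper over these functions ships in inst/scripts/ssap_tool.R.

#' Experiment configuration
#'
#' @param algorithm `"ap"`, `"ssap"` or `"kmeans"`.
#' @param phi Preference scale factor for the affinity-propagation engines.
#' @param preference_mode Aggregate for [set_preferences()].
#' @param seeds_file Optional seed TSV path (`doc_id<TAB>label`); required for
#'   `"ssap"` unless `per_class` sampling from corpus labels is requested.
#' @param per_class Seeds sampled per class from the corpus's own labels when
#'   no `seeds_file` is given (default 4).
#' @param k Cluster count for the k-means baseline (default 10).
#' @param damping,max_iterations,convergence_window Message-passing settings,
#'   see [ap_config()].
#' @param rng_seed Master seed for every random draw in the run.
#' @param input Corpus source: a path accepted by [read_corpus()], a `corpus`,
#'   or a [synthetic_corpus_spec()].
#' @param output_dir Optional directory for run artifacts (assignments TSV,
#'   metrics JSON, manifest JSON); nothing is written when `NULL`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(algorithm = c("ap", "ssap", "kmeans"),
                              phi = 1, preference_mode = "mean",
                              seeds_file = NULL, per_class = 4L, k = 10L,
                              damping = 0.5, max_iterations = 1000L,
                              convergence_window = 100L, rng_seed = 1L,
                              input = NULL, output_dir = NULL) {
  config <- list(algorithm = match.arg(algorithm), phi = phi,
                 preference_mode = preference_mode, seeds_file = seeds_file,
                 per_class = as.integer(per_class), k = as.integer(k),
                 damping = damping, max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 rng_seed = as.integer(rng_seed), input = input,
                 output_dir = output_dir)
  class(config) <- "experiment_config"
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid experiment configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  config
}

validate_config <- function(config) {
  problems <- character(0)
  if (!is.numeric(config$phi) || config$phi <= 0) {
    problems <- c(problems, "`phi` must be positive")
  }
  if (!config$preference_mode %in% c("mean", "median", "min")) {
    problems <- c(problems, "`preference_mode` must be mean, median or min")
  }
  if (config$damping < 0 || config$damping >= 1) {
    problems <- c(problems, "`damping` must be in [0, 1)")
  }
  if (config$max_iterations < 1L) problems <- c(problems, "`max_iterations` must be >= 1")
  if (config$convergence_window < 1L ||
      config$convergence_window > config$max_iterations) {
    problems <- c(problems, "`convergence_window` must be in [1, max_iterations]")
  }
  if (config$algorithm == "kmeans" && config$k < 1L) {
    problems <- c(problems, "k-means requires `k` >= 1")
  }
  if (config$algorithm == "ssap" && is.null(config$seeds_file) &&
      config$per_class < 0L) {
    problems <- c(problems, "ssap requires `seeds_file` or `per_class` >= 0")
  }
  if (!is.null(config$seeds_file) && !file.exists(config$seeds_file)) {
    problems <- c(problems, paste0("seeds file not found: ", config$seeds_file))
  }
  if (is.null(config$input)) {
    problems <- c(problems, "`input` (corpus path, corpus, or synthetic spec) is required")
  } else if (is.character(config$input) && !file.exists(config$input)) {
    problems <- c(problems, paste0("input not found: ", config$input))
  }
  problems
}

#' Read a YAML experiment configuration
#'
#' Keys mirror the arguments of [experiment_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' Run a clustering experiment
#'
#' Loads or generates the corpus, runs the configured algorithm, evaluates
#' against truth labels when available (seed documents excluded), and — when
#' `output_dir` is set — writes `assignments.tsv` (doc_id, cluster_id,
#' exemplar_doc_id, label), `metrics.json` and a reproducibility
#' `manifest.json`.
#'
#' @param config An [experiment_config()].
#' @return List with `result` (a `clustering_result`), `metrics` (list with
#'   `f_measure`, `entropy`, `n_clusters`, or `NULL` without truth labels),
#'   `seeds` and `manifest`, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  x <- load_input(config$input)
  truth <- attr(x, "truth")
  if (is.null(truth)) {
    truth <- corpus_labels(x)
    names(truth) <- corpus_ids(x)
    if (all(is.na(truth))) truth <- NULL
  }
  seeds <- NULL
  ap_cfg <- ap_config(damping = config$damping,
                      max_iterations = config$max_iterations,
                      convergence_window = config$convergence_window,
                      rng_seed = config$rng_seed)
  result <- switch(config$algorithm,
    ap = {
      S <- set_preferences(build_similarity_matrix(x), phi = config$phi,
                           mode = config$preference_mode)
      run_ap(S, ap_cfg)
    },
    ssap = {
      seeds <- if (!is.null(config$seeds_file)) {
        read_seed_file(config$seeds_file)
      } else {
        construct_seed_set(x, per_class = config$per_class,
                           rng_seed = config$rng_seed)
      }
      run_ssap(x, seeds, phi = config$phi, config = ap_cfg,
               preference_mode = config$preference_mode)
    },
    kmeans = kmeans_vsm(x, k = config$k, rng_seed = config$rng_seed)
  )
  metrics <- NULL
  if (!is.null(truth)) {
    tab <- build_contingency(truth, result, exclude_seeds = TRUE)
    metrics <- list(f_measure = f_measure(tab),
                    entropy = cluster_entropy(tab),
                    n_clusters = length(result$clusters),
                    n_evaluated = sum(tab$counts))
  }
  manifest <- build_manifest(config, seeds)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_assignments(result,
                      file.path(config$output_dir, "assignments.tsv"))
    jsonlite::write_json(metrics %||% list(),
                         file.path(config$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(result = result, metrics = metrics, seeds = seeds,
                 manifest = manifest))
}

load_input <- function(input) {
  if (inherits(input, "corpus")) return(input)
  if (inherits(input, "synthetic_corpus_spec")) return(generate_corpus(input))
  read_corpus(input)
}

build_manifest <- function(config, seeds) {
  settings <- unclass(config)
  settings$input <- if (is.character(config$input)) config$input
    else class(config$input)[1L]
  settings$output_dir <- NULL
  list(package = "ssapcluster",
       version = as.character(utils::packageVersion("ssapcluster")),
       settings = settings,
       input_md5 = if (is.character(config$input) && file.exists(config$input) &&
                       !dir.exists(config$input)) {
         unname(tools::md5sum(config$input))
       } else NA_character_,
       seeds = if (!is.null(seeds)) as.list(seeds$entries),
       r_version = as.character(getRversion()))
}

#' Write cluster assignments as TSV
#'
#' Columns: `doc_id`, `cluster_id`, `exemplar_doc_id`, `label` (empty for
#' unlabeled clusters).
#'
#' @param result A `clustering_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(result, path) {
  lab <- result$cluster_labels[result$cluster]
  lab[is.na(lab)] <- ""
  tab <- cbind(doc_id = result$ids,
               cluster_id = as.character(result$cluster),
               exemplar_doc_id = result$ids[result$exemplar],
               label = lab)
  utils::write.table(rbind(colnames(tab), tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the relationship-network analysis on a contingency CSV
#'
#' Reads the class-by-cluster matrix, builds the directed journal network and
#' its statistics, and — when `output_dir` is set — writes `edges.tsv`,
#' `network.graphml` and `network_stats.json`.
#'
#' @param table_path Contingency CSV path (same dialect as
#'   [read_contingency_csv()]).
#' @param threshold Minimum article count for an edge (default 2).
#' @param convention Edge orientation, see [build_relationship_network()].
#' @param output_dir Optional artifact directory.
#' @return List with `network`, `stats`, `dominant`, `homologous`, invisibly.
#' @export
run_network_analysis <- function(table_path, threshold = 2L,
                                 convention = "degree_consistent",
                                 output_dir = NULL) {
  table <- read_contingency_csv(table_path)
  net <- build_relationship_network(table, threshold = threshold,
                                    convention = convention)
  stats <- network_stats(net)
  hom <- homologous_counts(table, net$dominant_of)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_list(net, file.path(output_dir, "edges.tsv"))
    write_graphml(net, file.path(output_dir, "network.graphml"))
    jsonlite::write_json(stats, file.path(output_dir, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(network = net, stats = stats, dominant = net$dominant_of,
                 homologous = hom))
}
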