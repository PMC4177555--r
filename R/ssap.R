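# Semi-supervision: labeled seed documents guide a post-hoc merge of the
# affinity-propagation clusters. Labels never alter the message passing by
# default; clusters that contain seeds with the same label are unioned, which
# repairs the over-segmentation a large preference produces.

#' Construct a seed set by per-class sampling
#'
#' Samples `per_class` labeled documents uniformly without replacement from
#' each class of a labeled pool.
#'
#' @param labeled_pool A `corpus` whose documents carry class labels.
#' @param per_class Number of seeds per class (0 gives an empty seed set and
#'   degenerates semi-supervised runs to plain affinity propagation).
#' @param rng_seed Seed making the draw reproducible.
#' @return An object of class `seed_set` with `entries` (named character
#'   vector: document id -> label) and `per_class`.
#' @export
construct_seed_set <- function(labeled_pool, per_class, rng_seed = NULL) {
  per_class <- as.integer(per_class)
  if (per_class < 0L) stop("`per_class` must be >= 0", call. = FALSE)
  labels <- corpus_labels(labeled_pool)
  ids <- corpus_ids(labeled_pool)
  keep <- !is.na(labels)
  if (per_class == 0L) return(seed_set(character(0), per_class = 0L))
  if (!any(keep)) stop("the pool has no labeled documents", call. = FALSE)
  classes <- sort(unique(labels[keep]), method = "radix")
  entries <- character(0)
  with_seed(rng_seed, {
    for (cl in classes) {
      pool_ids <- ids[keep & labels == cl]
      if (length(pool_ids) < per_class) {
        stop(sprintf("class '%s' has only %d documents, need %d seeds",
                     cl, length(pool_ids), per_class), call. = FALSE)
      }
      chosen <- sample(pool_ids, per_class)
      entries[chosen] <- cl
    }
  })
  seed_set(entries, per_class = per_class)
}

#' @rdname construct_seed_set
#' @param entries Named character vector (document id -> label).
#' @export
seed_set <- function(entries, per_class = NA_integer_) {
  entries <- vapply(entries, as.character, character(1))
  structure(list(entries = entries, per_class = per_class), class = "seed_set")
}

#' Read / write a seed file (TSV: doc_id, label)
#' @param path File path.
#' @return A `seed_set` (read) or `path` (write).
#' @export
read_seed_file <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (identical(unname(tolower(unlist(tab[1L, 1:2]))), c("doc_id", "label"))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  entries <- tab[[2L]]
  names(entries) <- tab[[1L]]
  seed_set(entries)
}

#' @rdname read_seed_file
#' @param seeds A `seed_set`.
#' @export
write_seed_file <- function(seeds, path) {
  utils::write.table(
    cbind(c("doc_id", names(seeds$entries)), c("label", unname(seeds$entries))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Inject seed documents into a corpus
#'
#' Seeds whose ids already exist in the corpus are flagged in place (their
#' label set from the seed set); seeds absent from the corpus are copied in
#' from `pool`. The augmented corpus has N' >= N documents.
#'
#' @param x A `corpus`.
#' @param seeds A `seed_set`.
#' @param pool Optional labeled `corpus` supplying external seed documents.
#' @return The augmented corpus; seed documents have `is_seed = TRUE`.
#' @export
inject_seeds <- function(x, seeds, pool = NULL) {
  if (length(seeds$entries) == 0L) return(x)
  ids <- corpus_ids(x)
  added <- list()
  for (sid in names(seeds$entries)) {
    if (sid %in% ids) {
      x$documents[[sid]]$label <- seeds$entries[[sid]]
      x$documents[[sid]]$is_seed <- TRUE
    } else {
      if (is.null(pool) || !(sid %in% corpus_ids(pool))) {
        stop("seed document '", sid, "' is neither in the corpus nor in `pool`",
             call. = FALSE)
      }
      doc <- pool$documents[[sid]]
      if (length(doc$terms) == 0L) stop("seed document '", sid, "' is empty", call. = FALSE)
      doc$label <- seeds$entries[[sid]]
      doc$is_seed <- TRUE
      added[[sid]] <- doc
    }
  }
  if (length(added)) x <- corpus(c(unname(x$documents), unname(added)))
  x
}

#' Merge clusters that share seed labels
#'
#' All clusters containing at least one seed of label L are unioned into one
#' cluster carrying L. A cluster holding seeds of several labels joins the
#' label with the majority seed count (ties to the lowest-sorted label; the
#' conflict is recorded in the merge log and messaged). Clusters without
#' seeds are untouched. Clusters are only ever unioned, never split, so the
#' output remains a partition with at most as many clusters as the input.
#'
#' @param result A `clustering_result` over the augmented corpus.
#' @param seeds A `seed_set`.
#' @return A `clustering_result` with `cluster_labels` set for merged clusters
#'   and a `merge_log` attribute describing each union and conflict.
#' @export
merge_labeled_clusters <- function(result, seeds) {
  if (length(seeds$entries) == 0L) return(result)
  n <- length(result$cluster)
  seed_label <- seeds$entries[match(result$ids, names(seeds$entries))]
  log <- list()
  # label adopted by each cluster (majority of its seeds), NA if seedless
  adopted <- rep(NA_character_, length(result$clusters))
  for (g in seq_along(result$clusters)) {
    labs <- seed_label[result$clusters[[g]]]
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0L) next
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    adopted[g] <- sort(winners, method = "radix")[1L]
    if (length(unique(labs)) > 1L) {
      log[[length(log) + 1L]] <- sprintf(
        "cluster %d holds seeds of labels {%s}; majority label '%s' adopted",
        g, paste(names(tab), collapse = ", "), adopted[g])
      message(log[[length(log)]])
    }
  }
  exemplar <- result$exemplar
  for (lab in unique(adopted[!is.na(adopted)])) {
    group <- which(adopted == lab)
    if (length(group) < 2L) next
    members_per <- lengths(result$clusters[group])
    keep <- group[which.max(members_per)]  # representative: largest constituent
    target <- result$exemplar[result$clusters[[keep]][1L]]
    moved <- unlist(result$clusters[setdiff(group, keep)], use.names = FALSE)
    exemplar[moved] <- target
    exemplar[target] <- target
    log[[length(log) + 1L]] <- sprintf(
      "label '%s': merged clusters {%s} (%d documents)",
      lab, paste(group, collapse = ", "), sum(members_per))
  }
  merged <- clustering_result(exemplar, ids = result$ids,
                              converged = result$converged,
                              iterations = result$iterations,
                              is_seed = result$is_seed)
  # carry the adopted label onto each surviving cluster
  for (g in seq_along(merged$clusters)) {
    labs <- adopted[unique(result$cluster[merged$clusters[[g]]])]
    labs <- labs[!is.na(labs)]
    merged$cluster_labels[g] <- if (length(labs)) labs[1L] else NA_character_
  }
  attr(merged, "merge_log") <- unlist(log) %||% character(0)
  merged
}

#' Run semi-supervised affinity propagation
#'
#' Pipeline: inject seeds into the corpus, build the pairwise sub-space
#' similarity matrix, set diagonal preferences to `phi` times the aggregate
#' off-diagonal similarity, run affinity propagation, then union clusters
#' sharing seed labels. With an empty seed set the result equals plain
#' affinity propagation on the same corpus and `phi`.
#'
#' @param x A `corpus`.
#' @param seeds A `seed_set` (possibly empty).
#' @param phi Preference scale factor (default 3, the setting that pairs with
#'   seed-guided merging; around 0.5-1 suits unsupervised runs).
#' @param config An [ap_config()].
#' @param preference_mode Aggregate for [set_preferences()].
#' @param variant Cosine variant for [build_similarity_matrix()].
#' @param must_link If `TRUE`, the similarity between every pair of same-label
#'   seeds is raised to the maximum off-diagonal similarity before message
#'   passing (a soft must-link constraint). Off by default: the baseline
#'   method lets labels act only through merging.
#' @param pool Optional labeled corpus supplying external seed documents.
#' @return A `clustering_result` over the augmented corpus; seed documents are
#'   flagged via `is_seed` so evaluation can exclude them.
#' @export
run_ssap <- function(x, seeds = seed_set(character(0)), phi = 3,
                     config = ap_config(), preference_mode = "mean",
                     variant = "weighted", must_link = FALSE, pool = NULL) {
  aug <- inject_seeds(x, seeds, pool = pool)
  S <- build_similarity_matrix(aug, variant = variant)
  if (must_link && length(seeds$entries) > 0L) {
    ids <- corpus_ids(aug)
    lab <- seeds$entries[match(ids, names(seeds$entries))]
    hi <- max(S[upper.tri(S)])
    for (l in unique(lab[!is.na(lab)])) {
      members <- which(!is.na(lab) & lab == l)
      for (a in members) for (b in members) if (a != b) S[a, b] <- max(S[a, b], hi)
    }
  }
  S <- set_preferences(S, phi = phi, mode = preference_mode)
  res <- run_ap(S, config)
  res$is_seed <- vapply(aug$documents, function(d) isTRUE(d$is_seed), logical(1))
  merge_labeled_clusters(res, seeds)
}
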