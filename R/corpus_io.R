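# Corpus ingestion: documents as sparse term/count/normalized-frequency tuples.
#
# A document is never materialised as a dense vector over a global vocabulary;
# it carries only its own terms, so a corpus of full texts stays small in
# memory and pairwise similarity can work in the sub-space of each pair.

#' Load a stop-word list
#'
#' Reads one word per line, lowercased. With no `path` the bundled standard
#' English stop-word list is used.
#'
#' @param path Path to a stop-word file, one word per line, or `NULL` for the
#'   bundled list.
#' @return An object of class `stopword_list` with element `words`.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "ssapcluster")
  }
  if (!file.exists(path)) stop("stop-word file not found: ", path, call. = FALSE)
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- unique(tolower(trimws(words)))
  words <- words[nzchar(words)]
  structure(list(words = words), class = "stopword_list")
}

#' Tokenize text into terms
#'
#' Lowercases, splits on any non-alphanumeric character, and drops tokens
#' shorter than `min_token_len` as well as stop words. Order of occurrence is
#' preserved (duplicates kept) so that term counts can be aggregated later.
#'
#' @param text Character scalar (or vector, concatenated with spaces).
#' @param stopwords A `stopword_list` or `NULL` to keep all tokens.
#' @param min_token_len Minimum token length kept (default 2).
#' @return Character vector of tokens; empty text yields `character(0)`.
#' @export
tokenize <- function(text, stopwords = NULL, min_token_len = 2L) {
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = " ")
  tokens <- strsplit(tolower(text), "[^[:alnum:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens) & nchar(tokens) >= min_token_len]
  if (!is.null(stopwords)) {
    if (!inherits(stopwords, "stopword_list")) {
      stopwords <- structure(list(words = tolower(as.character(stopwords))),
                             class = "stopword_list")
    }
    tokens <- tokens[!(tokens %in% stopwords$words)]
  }
  tokens
}

#' Build a document from a token stream
#'
#' Aggregates counts per unique term (first-occurrence order) and attaches
#' normalized frequencies n_k = count_k / sum(counts), which sum to 1. Cosine
#' similarity is invariant to any positive per-document scaling, so the choice
#' of denominator cannot affect clustering.
#'
#' @param id Document identifier (string).
#' @param tokens Character vector of terms, duplicates meaning repeated use.
#' @param label Optional class label (e.g. journal name).
#' @return An object of class `document` with fields `id`, `label`, `terms`,
#'   `counts`, `n` and `is_seed`.
#' @export
build_document <- function(id, tokens, label = NA_character_) {
  if (length(tokens) == 0L) {
    stop("empty document: '", id, "' has no admissible terms", call. = FALSE)
  }
  u <- unique(tokens)
  counts <- as.integer(table(factor(tokens, levels = u)))
  document_from_counts(id, u, counts, label = label)
}

#' @rdname build_document
#' @param terms Unique term strings.
#' @param counts Positive integer counts aligned with `terms`.
#' @export
document_from_counts <- function(id, terms, counts, label = NA_character_) {
  if (length(terms) == 0L) stop("empty document: '", id, "'", call. = FALSE)
  if (anyDuplicated(terms)) {
    stop("duplicate terms in document '", id, "'", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (length(counts) != length(terms) || any(is.na(counts)) || any(counts < 1L)) {
    stop("counts for document '", id, "' must be positive integers aligned with terms",
         call. = FALSE)
  }
  structure(
    list(id = as.character(id), label = as.character(label),
         terms = as.character(terms), counts = counts,
         n = counts / sum(counts), is_seed = FALSE),
    class = "document"
  )
}

#' Construct a corpus from documents
#'
#' Documents are ordered lexicographically by id; ids must be unique.
#'
#' @param documents List of `document` objects.
#' @return An object of class `corpus` with element `documents` (named list).
#' @export
corpus <- function(documents) {
  if (length(documents) < 1L) stop("a corpus needs at least one document", call. = FALSE)
  ids <- vapply(documents, function(d) d$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate document ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  documents <- documents[order(ids, method = "radix")]
  names(documents) <- sort(ids, method = "radix")
  structure(list(documents = documents), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  nt <- vapply(x$documents, function(d) length(d$terms), integer(1))
  labs <- corpus_labels(x)
  cat(sprintf("<corpus> %d documents, %d-%d unique terms each, %d labeled\n",
              length(x$documents), min(nt), max(nt), sum(!is.na(labs))))
  invisible(x)
}

#' Document ids of a corpus
#' @param x A `corpus`.
#' @return Character vector of ids, in corpus order.
#' @export
corpus_ids <- function(x) names(x$documents)

#' Class labels of a corpus
#' @param x A `corpus`.
#' @return Character vector of labels (`NA` where unlabeled), in corpus order.
#' @export
corpus_labels <- function(x) {
  vapply(x$documents, function(d) d$label %||% NA_character_, character(1))
}

#' Filter file paths by minimum byte size
#'
#' Very small files of a full-text dump are typically stubs (markup plus an
#' abstract at best) and are removed before clustering; the conventional
#' threshold is 4 KB.
#'
#' @param paths Character vector of file paths.
#' @param min_bytes Minimum size in bytes (default 4096); 0 disables the filter.
#' @return The subset of `paths` with size >= `min_bytes`, order preserved.
#' @export
filter_small_files <- function(paths, min_bytes = 4096L) {
  if (length(paths) == 0L) return(paths)
  if (min_bytes < 0) stop("`min_bytes` must be >= 0", call. = FALSE)
  sizes <- file.size(paths)
  if (anyNA(sizes)) {
    stop("cannot read file: ", paths[which(is.na(sizes))[1L]], call. = FALSE)
  }
  paths[sizes >= min_bytes]
}

#' Read a corpus from disk
#'
#' Supported sources:
#' * a directory of `.txt` files (one document per file, id = file name without
#'   extension), tokenized with `stopwords`/`min_token_len`; `.xml` files are
#'   accepted as a convenience when the xml2 package is available, extracting
#'   text from `title`, abstract-like and `bdy` elements;
#' * a term-tuple TSV with columns `doc_id`, `term`, `count`;
#' * JSON-lines, one object per line with fields `id`, optional `label`, and
#'   either `text` (tokenized) or `terms` (object of term:count).
#'
#' @param source Directory or file path.
#' @param format One of `"auto"`, `"dir"`, `"tsv"`, `"jsonl"`.
#' @param stopwords `stopword_list` applied when tokenizing raw text (default:
#'   bundled English list; `NULL` keeps everything).
#' @param min_token_len Minimum token length for raw-text tokenization.
#' @param min_bytes Byte-size filter applied to raw text/XML files (default 0 =
#'   off; the 4 KB rule is for raw full-text dumps, not tuple files).
#' @param labels Optional named character vector or label TSV path
#'   (`doc_id<TAB>label`) attaching class labels.
#' @return A `corpus`.
#' @export
read_corpus <- function(source, format = c("auto", "dir", "tsv", "jsonl"),
                        stopwords = load_stopwords(), min_token_len = 2L,
                        min_bytes = 0L, labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("source not found: ", source, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(source)) "dir"
    else if (grepl("\\.jsonl$", source, ignore.case = TRUE)) "jsonl"
    else "tsv"
  }
  docs <- switch(format,
    dir = read_corpus_dir(source, stopwords, min_token_len, min_bytes),
    tsv = read_corpus_tsv(source),
    jsonl = read_corpus_jsonl(source, stopwords, min_token_len)
  )
  if (length(docs) == 0L) stop("no admissible documents in ", source, call. = FALSE)
  out <- corpus(docs)
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      labels <- read_seed_file(labels)$entries
    }
    out <- apply_labels(out, labels)
  }
  out
}

read_corpus_dir <- function(source, stopwords, min_token_len, min_bytes) {
  paths <- list.files(source, pattern = "\\.(txt|xml)$", full.names = TRUE,
                      ignore.case = TRUE)
  paths <- filter_small_files(paths, min_bytes)
  docs <- list()
  for (p in paths) {
    text <- if (grepl("\\.xml$", p, ignore.case = TRUE)) {
      xml_body_text(p)
    } else {
      paste(readLines(p, warn = FALSE, encoding = "UTF-8"), collapse = " ")
    }
    tokens <- tokenize(text, stopwords, min_token_len)
    if (length(tokens) == 0L) next  # stub file, nothing admissible
    id <- sub("\\.[^.]+$", "", basename(p))
    doc <- build_document(id, tokens)
    doc$raw_size_bytes <- file.size(p)
    docs[[length(docs) + 1L]] <- doc
  }
  docs
}

# minimal XML convenience: title/abstract/body text only
xml_body_text <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading XML documents requires the 'xml2' package", call. = FALSE)
  }
  x <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(
    x, ".//*[self::title or starts-with(local-name(), 'abs') or local-name() = 'bdy' or local-name() = 'body']")
  if (length(nodes) == 0L) nodes <- x
  paste(xml2::xml_text(nodes), collapse = " ")
}

read_corpus_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) != 3L) stop("term-tuple TSV must have 3 columns (doc_id, term, count)",
                            call. = FALSE)
  if (identical(unname(tolower(unlist(tab[1L, ]))), c("doc_id", "term", "count"))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  names(tab) <- c("doc_id", "term", "count")
  if (anyDuplicated(tab[c("doc_id", "term")])) {
    d <- tab[duplicated(tab[c("doc_id", "term")]), ]
    stop(sprintf("duplicate (doc_id, term) row: (%s, %s)", d$doc_id[1L], d$term[1L]),
         call. = FALSE)
  }
  lapply(split(tab, tab$doc_id), function(g) {
    document_from_counts(g$doc_id[1L], g$term, as.integer(g$count))
  })
}

read_corpus_jsonl <- function(path, stopwords, min_token_len) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line)
    if (is.null(obj$id)) stop("JSON-lines record without 'id' field", call. = FALSE)
    label <- obj$label %||% NA_character_
    if (!is.null(obj$terms)) {
      document_from_counts(obj$id, names(obj$terms), as.integer(unlist(obj$terms)),
                           label = label)
    } else {
      build_document(obj$id, tokenize(obj$text %||% "", stopwords, min_token_len),
                     label = label)
    }
  })
}

#' Write a corpus as canonical term-tuple TSV
#'
#' Columns `doc_id`, `term`, `count`; same schema [read_corpus()] accepts, so a
#' round trip reproduces the corpus term for term.
#'
#' @param x A `corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(x, path) {
  rows <- lapply(x$documents, function(d) {
    data.frame(doc_id = d$id, term = d$terms, count = d$counts,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(rbind(c("doc_id", "term", "count"), as.matrix(tab)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach class labels to corpus documents
#'
#' @param x A `corpus`.
#' @param labels Named character vector: names are document ids, values labels.
#' @return The corpus with `label` fields set.
#' @export
apply_labels <- function(x, labels) {
  unknown <- setdiff(names(labels), corpus_ids(x))
  if (length(unknown)) {
    stop("labels refer to unknown document ids: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  for (id in names(labels)) x$documents[[id]]$label <- as.character(labels[[id]])
  x
}
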