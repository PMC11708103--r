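#' Generic policy-text mining
#'
#' A documented, deterministic replacement for the proprietary content-mining
#' step used in PMC-index studies: tokenization with a pluggable segmenter,
#' high-frequency keyword extraction, and a weighted undirected term
#' co-occurrence network. Terms are normalized to Unicode NFC and
#' lower-cased; no stemming is applied.
#'
#' @name pmc-textmining
NULL

segmenters <- list(
  # split on runs of whitespace after stripping punctuation to spaces
  whitespace = function(text) {
    text <- gsub("[[:punct:]]+", " ", text)
    toks <- strsplit(trimws(text), "\\s+")[[1]]
    toks[nzchar(toks)]
  },
  # every character its own token; crude fallback for unsegmented CJK text
  character = function(text) {
    toks <- strsplit(gsub("\\s+", "", text), "")[[1]]
    toks[nzchar(toks)]
  }
)

#' Tokenize a text
#'
#' @param text a single non-empty string (UTF-8).
#' @param segmenter `"whitespace"` (default), `"character"`, or a function
#'   `character(1) -> character()` supplying a custom word segmenter (e.g. a
#'   Chinese segmentation backend).
#' @param stopwords character vector of terms to drop (compared after
#'   normalization).
#' @param min_chars drop tokens shorter than this many characters (default 2,
#'   removing single-character noise); set to 1 to keep everything.
#' @return character vector of normalized terms in text order.
#' @examples
#' tokenize("Emergency response; emergency TEAM")
#' @export
tokenize <- function(text, segmenter = "whitespace",
                     stopwords = character(0), min_chars = 2) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) stop("empty text", call. = FALSE)
  seg <- if (is.function(segmenter)) {
    segmenter
  } else if (is.character(segmenter) && segmenter %in% names(segmenters)) {
    segmenters[[segmenter]]
  } else {
    stop("unknown segmenter '", segmenter, "'; available: ",
         paste(names(segmenters), collapse = ", "), call. = FALSE)
  }
  toks <- seg(text)
  toks <- tolower(stringi::stri_trans_nfc(toks))
  stopwords <- tolower(stringi::stri_trans_nfc(stopwords))
  toks <- toks[nchar(toks) >= min_chars & !(toks %in% stopwords)]
  toks
}

#' Read a corpus from a directory of plain-text files
#'
#' Each `<pid>.txt` file becomes one document; the file stem is the policy
#' id.
#'
#' @param dir directory containing UTF-8 `.txt` files.
#' @return tibble with columns `pid`, `text`.
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt files in ", dir, call. = FALSE)
  tibble::tibble(
    pid = sub("\\.txt$", "", basename(files)),
    text = vapply(files, function(f)
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
      character(1), USE.NAMES = FALSE))
}

check_corpus <- function(corpus) {
  if (!is.data.frame(corpus) || !all(c("pid", "text") %in% names(corpus)))
    stop("corpus must be a data frame with columns 'pid' and 'text'",
         call. = FALSE)
  if (anyDuplicated(corpus$pid))
    stop("duplicate document id(s): ",
         paste(unique(corpus$pid[duplicated(corpus$pid)]), collapse = ", "),
         call. = FALSE)
  invisible(corpus)
}

corpus_tokens <- function(corpus, ...) {
  check_corpus(corpus)
  lapply(stats::setNames(corpus$text, corpus$pid), tokenize, ...)
}

#' High-frequency terms of a corpus
#'
#' Counts every term's total occurrences and document frequency, sorts by
#' count descending with ties broken lexicographically, and keeps the top
#' `n`. `top_terms(corpus, n)` is always a prefix of
#' `top_terms(corpus, n + 1)`.
#'
#' @param corpus tibble with columns `pid`, `text`.
#' @param n maximum number of terms to return (positive).
#' @param ... passed to [tokenize()] (`segmenter`, `stopwords`, `min_chars`).
#' @return tibble with columns `term`, `count`, `doc_freq`, at most `n` rows.
#' @export
top_terms <- function(corpus, n = 50, ...) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("n must be a positive integer", call. = FALSE)
  toks <- corpus_tokens(corpus, ...)
  counts <- table(unlist(toks, use.names = FALSE))
  dfreq <- table(unlist(lapply(toks, unique), use.names = FALSE))
  out <- tibble::tibble(
    term = names(counts),
    count = as.integer(counts),
    doc_freq = as.integer(dfreq[names(counts)]))
  out <- out[order(-out$count, out$term), ]
  utils::head(out, n)
}

#' Term co-occurrence network
#'
#' Builds a weighted undirected graph over the corpus vocabulary. With
#' `window = "document"` (the default, matching coarse policy-text networks)
#' an edge's weight is the number of documents in which both terms appear;
#' with an integer `window` it is the number of sliding token windows of that
#' length containing both. No self-loops; symmetric by construction.
#'
#' @param corpus tibble with columns `pid`, `text`.
#' @param window `"document"` or a positive integer window length.
#' @param vocabulary optional character vector restricting the graph to these
#'   terms (e.g. the output of [top_terms()]).
#' @param ... passed to [tokenize()].
#' @return tibble of class `pmc_cooccurrence` with columns `term_a`,
#'   `term_b`, `weight` (`term_a < term_b` lexicographically), ordered by
#'   weight descending.
#' @export
cooccurrence <- function(corpus, window = "document", vocabulary = NULL, ...) {
  if (is.numeric(window)) {
    if (length(window) != 1 || window < 1)
      stop("window must be a positive integer or \"document\"", call. = FALSE)
    window <- as.integer(window)
  } else if (!identical(window, "document")) {
    stop("window must be a positive integer or \"document\"", call. = FALSE)
  }
  toks <- corpus_tokens(corpus, ...)
  if (!is.null(vocabulary))
    toks <- lapply(toks, function(t) t[t %in% vocabulary])
  units <- if (identical(window, "document")) {
    lapply(toks, unique)
  } else {
    unlist(lapply(toks, function(t) {
      if (length(t) <= window) return(list(unique(t)))
      lapply(seq_len(length(t) - window + 1L),
             function(i) unique(t[i:(i + window - 1L)]))
    }), recursive = FALSE)
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (u in units) {
    u <- sort(u)
    k <- length(u)
    if (k < 2) next
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      key <- paste(u[i], u[j], sep = "\r")
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  keys <- ls(env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble::tibble(
    term_a = vapply(parts, `[`, character(1), 1),
    term_b = vapply(parts, `[`, character(1), 2),
    weight = vapply(keys, function(k) env[[k]], integer(1), USE.NAMES = FALSE))
  out <- out[order(-out$weight, out$term_a, out$term_b), ]
  class(out) <- c("pmc_cooccurrence", class(out))
  out
}

#' Export a co-occurrence network
#'
#' Writes the edge list as CSV (`source,target,weight`) and, optionally, the
#' graph as GraphML for network tools.
#'
#' @param graph a `pmc_cooccurrence` edge table.
#' @param csv path for the edge-list CSV, or `NULL` to skip.
#' @param graphml path for a GraphML export, or `NULL` to skip.
#' @return invisible character vector of the paths written.
#' @export
write_cooccurrence <- function(graph, csv = NULL, graphml = NULL) {
  stopifnot(inherits(graph, "pmc_cooccurrence") || is.data.frame(graph))
  written <- character(0)
  edges <- data.frame(source = graph$term_a, target = graph$term_b,
                      weight = graph$weight)
  if (!is.null(csv)) {
    utils::write.csv(edges, csv, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE)
    written <- c(written, csv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
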