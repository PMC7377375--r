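#' Tokenized dream report
#'
#' A tokenized report couples an ordered, lowercased token sequence with the
#' positions of its paragraph breaks and the report metadata.  A break at
#' position `i` means "no word-to-word transition between token `i` and token
#' `i + 1`" (1-based), so graphs built from the report never connect words
#' across a paragraph boundary.
#'
#' @param tokens character vector of lowercase word tokens.
#' @param break_positions integer vector of break positions in
#'   `1..length(tokens) - 1`.
#' @param meta named list of report metadata (see [load_corpus()] for the
#'   expected fields).
#' @return An object of class `tokenized_report` with elements `meta`,
#'   `tokens`, `break_positions` and `n_paragraphs`.
#' @export
tokenized_report <- function(tokens, break_positions = integer(0), meta = list()) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) {
    stop("empty report: no tokens", call. = FALSE)
  }
  break_positions <- sort(unique(as.integer(break_positions)))
  if (length(break_positions) &&
      (min(break_positions) < 1L || max(break_positions) >= length(tokens))) {
    stop("break_positions must lie in 1..(n_tokens - 1)", call. = FALSE)
  }
  structure(
    list(meta = meta, tokens = tokens, break_positions = break_positions,
         n_paragraphs = length(break_positions) + 1L),
    class = "tokenized_report"
  )
}

#' @export
print.tokenized_report <- function(x, ...) {
  id <- x$meta$report_id %||% "<unnamed>"
  cat(sprintf("<tokenized_report %s: %d tokens, %d paragraph(s)%s>\n",
              id, length(x$tokens), x$n_paragraphs,
              if (!is.null(x$meta$stage)) paste0(", stage ", x$meta$stage) else ""))
  invisible(x)
}

#' Tokenize a raw transcript
#'
#' Lowercases, strips punctuation (keeping intra-word apostrophes and
#' hyphens), splits on whitespace, and records a paragraph break wherever the
#' transcript contains one or more blank lines.
#'
#' @param raw_text a single string; the full text of one transcript.
#' @return A list with `tokens` (character) and `break_positions` (integer,
#'   1-based positions after which no transition exists).
#' @examples
#' tokenize("The dog. The dog ran.")
#' tokenize("a b\n\nc d")
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1)
  lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  blank <- grepl("^\\s*$", lines)
  # paragraph id per line: increments after each run of blank lines
  para_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  if (length(lines) == 0) stop("empty report: no alphabetic tokens", call. = FALSE)
  paras <- vapply(split(lines[!blank], para_id[!blank]),
                  paste, character(1), collapse = " ")
  tok_list <- lapply(paras, tokenize_words)
  tok_list <- tok_list[vapply(tok_list, length, 1L) > 0]
  if (length(tok_list) == 0) {
    stop("empty report: no alphabetic tokens", call. = FALSE)
  }
  lens <- vapply(tok_list, length, 1L)
  breaks <- cumsum(lens)
  breaks <- breaks[-length(breaks)]
  list(tokens = unname(unlist(tok_list)), break_positions = as.integer(breaks))
}

# Lowercase and split one paragraph into word tokens.  All characters other
# than alphanumerics, apostrophes and hyphens become separators; leading and
# trailing apostrophes/hyphens are trimmed so only intra-word ones survive.
tokenize_words <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]'-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- gsub("^['-]+|['-]+$", "", toks)
  toks[nzchar(toks)]
}

#' Load a transcript corpus
#'
#' Reads a delimited metadata table (comma or tab, autodetected; header
#' required) and one UTF-8 transcript file per row, named
#' `<report_id>.txt`, and returns one [tokenized_report()] per metadata row,
#' in row order.
#'
#' Metadata columns: `report_id`, `participant_id`, `night_id`, `stage`
#' (REM/N2/N3), `minutes_since_lights_off`, `pirs` (integer 0-9, empty when
#' missing), `trc` (non-negative integer, empty when missing).
#'
#' @param metadata_path path to the metadata table.
#' @param text_dir directory containing the transcript files.
#' @return A list of `tokenized_report` objects.
#' @export
load_corpus <- function(metadata_path, text_dir) {
  meta <- read_report_metadata(metadata_path)
  missing_files <- character(0)
  corpus <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    f <- file.path(text_dir, paste0(meta$report_id[i], ".txt"))
    if (!file.exists(f)) {
      missing_files <- c(missing_files, meta$report_id[i])
      next
    }
    txt <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    tk <- tokenize(txt)
    corpus[[i]] <- tokenized_report(tk$tokens, tk$break_positions,
                                    meta = as.list(meta[i, , drop = FALSE]))
  }
  if (length(missing_files)) {
    stop("missing transcript file(s) for report_id: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  corpus
}

#' Read and validate a report metadata table
#'
#' @inheritParams load_corpus
#' @return A data.frame with one validated row per report.
#' @export
read_report_metadata <- function(metadata_path) {
  header <- readLines(metadata_path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  meta <- read.delim(metadata_path, sep = sep, stringsAsFactors = FALSE,
                     na.strings = c("", "NA"))
  required <- c("report_id", "participant_id", "night_id", "stage",
                "minutes_since_lights_off")
  absent <- setdiff(required, names(meta))
  if (length(absent)) {
    stop("metadata is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!"pirs" %in% names(meta)) meta$pirs <- NA_integer_
  if (!"trc" %in% names(meta)) meta$trc <- NA_integer_
  meta$report_id <- as.character(meta$report_id)
  dup <- meta$report_id[duplicated(meta$report_id)]
  if (length(dup)) {
    stop("duplicate report_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(meta))) {
    err <- validate_report_meta(as.list(meta[i, , drop = FALSE]))
    if (!is.null(err)) {
      stop(sprintf("metadata row %d (report_id %s): %s", i,
                   meta$report_id[i], err), call. = FALSE)
    }
  }
  meta
}

# Returns NULL when valid, else a message naming the offending field.
validate_report_meta <- function(m) {
  if (!m$stage %in% c("REM", "N2", "N3")) {
    return(sprintf("field 'stage' must be REM, N2 or N3 (got '%s')", m$stage))
  }
  t_off <- suppressWarnings(as.numeric(m$minutes_since_lights_off))
  if (is.na(t_off) || t_off < 0) {
    return("field 'minutes_since_lights_off' must be a non-negative number")
  }
  if (!is.null(m$pirs) && !is.na(m$pirs)) {
    p <- suppressWarnings(as.numeric(m$pirs))
    if (is.na(p) || p != round(p) || p < 0 || p > 9) {
      return(sprintf("field 'pirs' must be an integer in 0..9 (got '%s')", m$pirs))
    }
  }
  if (!is.null(m$trc) && !is.na(m$trc)) {
    tr <- suppressWarnings(as.numeric(m$trc))
    if (is.na(tr) || tr < 0) {
      return("field 'trc' must be a non-negative integer")
    }
  }
  NULL
}

#' Remove stop-words from a report
#'
#' Drops every token found in a stop-word list while preserving the
#' surviving paragraph structure: a paragraph boundary remains wherever two
#' consecutive surviving tokens belonged to different paragraphs; paragraphs
#' emptied by the filter disappear.
#'
#' @param report a [tokenized_report()].
#' @param stopwords either a character vector of lowercase words or the path
#'   to a plain-text file with one word per line.
#' @return The filtered `tokenized_report`.  If every token is removed an
#'   error is raised; downstream length filtering handles reports that fall
#'   below the minimum word count.
#' @export
apply_stopword_filter <- function(report, stopwords) {
  stopifnot(inherits(report, "tokenized_report"))
  if (length(stopwords) == 1 && file.exists(stopwords)) {
    stopwords <- readLines(stopwords, warn = FALSE)
  }
  stopwords <- tolower(trimws(stopwords))
  stopwords <- stopwords[nzchar(stopwords)]
  if (length(stopwords) == 0) {
    warning("empty stop-word list: report returned unchanged")
    return(report)
  }
  para <- token_paragraph_ids(report)
  keep <- !(report$tokens %in% stopwords)
  if (!any(keep)) {
    stop("stop-word filter removed every token of report ",
         report$meta$report_id %||% "<unnamed>", call. = FALSE)
  }
  kept_para <- para[keep]
  new_breaks <- which(diff(kept_para) != 0)
  tokenized_report(report$tokens[keep], new_breaks, meta = report$meta)
}

# Paragraph index (1-based) of every token.
token_paragraph_ids <- function(report) {
  n <- length(report$tokens)
  ids <- integer(n)
  ids[] <- 1L
  if (length(report$break_positions)) {
    ids <- 1L + findInterval(seq_len(n) - 1L, report$break_positions)
  }
  ids
}

#' Enforce the minimum word count
#'
#' Partitions a corpus into reports meeting a minimum token count and
#' excluded reports, with an exclusion log giving counts by sleep stage.
#'
#' @param corpus list of [tokenized_report()] objects.
#' @param min_tokens minimum number of tokens for inclusion (default 30).
#' @return A list with `kept`, `excluded` (both lists of reports) and `log`,
#'   a one-line summary such as `"excluded 13 report(s): REM = 3; N2 = 10"`.
#' @export
filter_min_length <- function(corpus, min_tokens = 30L) {
  stopifnot(min_tokens >= 1)
  lens <- vapply(corpus, function(r) length(r$tokens), 1L)
  keep <- lens >= min_tokens
  excluded <- corpus[!keep]
  if (length(excluded)) {
    stages <- vapply(excluded, function(r) r$meta$stage %||% "unknown", "")
    tab <- table(factor(stages, levels = unique(stages)))
    log <- sprintf("excluded %d report(s): %s", length(excluded),
                   paste(sprintf("%s = %d", names(tab), as.integer(tab)),
                         collapse = "; "))
  } else {
    log <- "excluded 0 report(s)"
  }
  list(kept = corpus[keep], excluded = excluded, log = log)
}

#' Token count excluding filler words
#'
#' Counts the tokens of a report after removing hesitation fillers
#' ("um", "uh", ...).  Used as a proxy for the human-rated total recall
#' count (TRC) when none is supplied; a supplied `trc` in the metadata
#' always takes precedence downstream (see [effective_trc()]).
#'
#' @param report a [tokenized_report()].
#' @param fillers character vector of filler tokens to discount, or the
#'   path to a plain-text file with one filler per line (an editable
#'   default list ships in `inst/extdata/fillers.txt`).
#' @return Integer token count.
#' @export
word_count <- function(report, fillers = default_fillers()) {
  if (length(fillers) == 1 && file.exists(fillers)) {
    fillers <- readLines(fillers, warn = FALSE)
  }
  sum(!(report$tokens %in% fillers))
}

#' Default hesitation-filler list
#' @return Character vector of fillers discounted by [word_count()].
#' @export
default_fillers <- function() {
  c("um", "uh", "ah", "er", "erm", "uhm", "hm", "hmm", "mm", "mhm")
}

#' Report length measure with human-rated precedence
#'
#' Returns the metadata `trc` when present, otherwise the filler-free token
#' count from [word_count()].
#'
#' @inheritParams word_count
#' @return A number.
#' @export
effective_trc <- function(report, fillers = default_fillers()) {
  trc <- report$meta$trc
  if (!is.null(trc) && length(trc) == 1 && !is.na(trc)) {
    return(as.numeric(trc))
  }
  word_count(report, fillers)
}
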