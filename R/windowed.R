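#' Sliding-window spans
#'
#' Start/end indices (1-based, inclusive) of every fixed-length window over
#' a token sequence.  The default 30-word window moved one word at a time
#' corresponds to a 29-word overlap; trailing tokens that cannot fill a
#' final window are already covered by the overlapping windows emitted.
#'
#' @param n_tokens number of tokens in the report.
#' @param window_length window size in words (default 30).
#' @param step how far the window advances each move (step = window_length -
#'   overlap; default 1).
#' @return A data.frame with columns `start` and `end`.
#' @export
window_spans <- function(n_tokens, window_length = 30L, step = 1L) {
  stopifnot(window_length >= 1, step >= 1)
  if (n_tokens < window_length) {
    stop(sprintf("report of %d tokens is shorter than the %d-word window",
                 n_tokens, window_length), call. = FALSE)
  }
  starts <- seq.int(1L, n_tokens - window_length + 1L, by = step)
  data.frame(start = starts, end = starts + window_length - 1L)
}

#' Window-averaged graph measures of a report
#'
#' Slides a fixed-length window over the token sequence, builds the word
#' graph of every window (paragraph breaks falling inside a window still
#' suppress that transition) and averages the connectedness measures across
#' windows with equal weight.  This controls for report length: every
#' window contributes a graph over exactly `window_length` words.
#'
#' @param report a [tokenized_report()] that passed [filter_min_length()].
#' @param window_length window size in words (default 30).
#' @param step window advance per move (default 1).
#' @param per_window if `TRUE`, also return the per-window measures matrix.
#' @return A list with `report_id`, `n_windows`, `mean_edges`, `mean_lcc`,
#'   `mean_lsc` (and `per_window` when requested).
#' @export
windowed_measures <- function(report, window_length = 30L, step = 1L,
                              per_window = FALSE) {
  stopifnot(inherits(report, "tokenized_report"))
  codes <- match(report$tokens, unique(report$tokens))
  res <- cpp_windowed_measures(codes, report$break_positions,
                               as.integer(window_length), as.integer(step),
                               per_window)
  res$report_id <- report$meta$report_id %||% NA_character_
  res[c("report_id", setdiff(names(res), "report_id"))]
}

#' Per-report measures table for a corpus
#'
#' Applies [windowed_measures()] to every report and assembles the
#' analysis-ready table: report metadata, length bookkeeping, the TRC (the
#' human-rated value when present, else the filler-free token count) and
#' the window-averaged connectedness measures.
#'
#' @param corpus list of [tokenized_report()] objects (already
#'   length-filtered).
#' @param window_length,step see [windowed_measures()].
#' @return A data.frame with one row per report: `report_id`,
#'   `participant_id`, `night_id`, `stage`, `minutes_since_lights_off`,
#'   `pirs`, `trc`, `n_tokens`, `n_paragraphs`, `n_windows`, `mean_edges`,
#'   `mean_lcc`, `mean_lsc`.
#' @export
corpus_measures <- function(corpus, window_length = 30L, step = 1L) {
  rows <- lapply(corpus, function(r) {
    wm <- windowed_measures(r, window_length, step)
    data.frame(
      report_id = r$meta$report_id %||% NA_character_,
      participant_id = r$meta$participant_id %||% NA_character_,
      night_id = r$meta$night_id %||% NA_character_,
      stage = r$meta$stage %||% NA_character_,
      minutes_since_lights_off = as.numeric(r$meta$minutes_since_lights_off %||% NA),
      pirs = as.numeric(r$meta$pirs %||% NA),
      trc = effective_trc(r),
      n_tokens = length(r$tokens),
      n_paragraphs = r$n_paragraphs,
      n_windows = wm$n_windows,
      mean_edges = wm$mean_edges,
      mean_lcc = wm$mean_lcc,
      mean_lsc = wm$mean_lsc,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
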