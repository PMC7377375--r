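#' Shuffle the word order of a report
#'
#' Draws a uniform random permutation of the token sequence while keeping
#' the paragraph-break positions (and therefore paragraph lengths and the
#' paragraph count) fixed.  Metadata is unchanged.
#'
#' @param report a [tokenized_report()].
#' @return A `tokenized_report` with permuted tokens.
#' @export
shuffle_tokens <- function(report) {
  stopifnot(inherits(report, "tokenized_report"))
  report$tokens <- sample(report$tokens)
  report
}

#' Shuffle-null z-scores for one report
#'
#' Compares a report's window-averaged LCC and LSC to the distribution
#' obtained by shuffling its word order `n_shuffles` times (paragraph
#' breaks held fixed) and recomputing the windowed measures for each
#' shuffle.  The null mean (`mr_lcc`, `mr_lsc`) and standard deviation
#' (`sdr_lcc`, `sdr_lsc`; population form, denominator n) convert the
#' observed values to z-scores: `lcc_z = (mean_lcc - mr_lcc) / sdr_lcc`,
#' and likewise for LSC.  Reports that approximate a random word sequence
#' have z-scores near 0.
#'
#' Randomness is drawn from a per-report substream derived from
#' `(seed, report_id)`, so corpus-level results do not depend on report
#' order and a fixed `(report, seed)` pair is exactly reproducible.
#'
#' @param report a [tokenized_report()] that passed [filter_min_length()].
#' @param n_shuffles number of word-order shuffles (default 1000).
#' @param window_length,step see [windowed_measures()].
#' @param seed master seed for the shuffle RNG.
#' @return An object of class `null_result`: a list with `report_id`,
#'   `n_shuffles`, `seed`, `mr_lcc`, `sdr_lcc`, `lcc_z`, `mr_lsc`,
#'   `sdr_lsc`, `lsc_z` and `degenerate`.  When a null SD is zero (e.g. a
#'   report whose tokens are all identical) the corresponding z is `NA`
#'   and `degenerate` names the measure.
#' @export
null_zscores <- function(report, n_shuffles = 1000L, window_length = 30L,
                         step = 1L, seed = 1L) {
  stopifnot(inherits(report, "tokenized_report"), n_shuffles >= 2)
  obs <- windowed_measures(report, window_length, step)
  codes <- match(report$tokens, unique(report$tokens))
  sub_seed <- seed_for_report(seed, report$meta$report_id %||% "")
  draws <- with_local_seed(sub_seed, {
    cpp_null_windowed(codes, report$break_positions,
                      as.integer(window_length), as.integer(step),
                      as.integer(n_shuffles))
  })
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mr_lcc <- mean(draws[, "mean_lcc"]); sdr_lcc <- pop_sd(draws[, "mean_lcc"])
  mr_lsc <- mean(draws[, "mean_lsc"]); sdr_lsc <- pop_sd(draws[, "mean_lsc"])
  degenerate <- character(0)
  if (sdr_lcc == 0) degenerate <- c(degenerate, "lcc")
  if (sdr_lsc == 0) degenerate <- c(degenerate, "lsc")
  structure(
    list(
      report_id = obs$report_id,
      n_shuffles = as.integer(n_shuffles),
      seed = as.integer(seed),
      mean_lcc = obs$mean_lcc, mean_lsc = obs$mean_lsc,
      mr_lcc = mr_lcc, sdr_lcc = sdr_lcc,
      lcc_z = if (sdr_lcc > 0) (obs$mean_lcc - mr_lcc) / sdr_lcc else NA_real_,
      mr_lsc = mr_lsc, sdr_lsc = sdr_lsc,
      lsc_z = if (sdr_lsc > 0) (obs$mean_lsc - mr_lsc) / sdr_lsc else NA_real_,
      degenerate = degenerate
    ),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result %s: %d shuffles, LCCz = %s, LSCz = %s%s>\n",
              x$report_id, x$n_shuffles,
              formatC(x$lcc_z, digits = 3, format = "f"),
              formatC(x$lsc_z, digits = 3, format = "f"),
              if (length(x$degenerate))
                paste0(", degenerate: ", paste(x$degenerate, collapse = ","))
              else ""))
  invisible(x)
}

#' Shuffle-null z-scores for a whole corpus
#'
#' @param corpus list of [tokenized_report()] objects.
#' @inheritParams null_zscores
#' @return A data.frame with columns `report_id`, `n_shuffles`, `seed`,
#'   `mr_lcc`, `sdr_lcc`, `lcc_z`, `mr_lsc`, `sdr_lsc`, `lsc_z`.
#' @export
corpus_null_zscores <- function(corpus, n_shuffles = 1000L,
                                window_length = 30L, step = 1L, seed = 1L) {
  rows <- lapply(corpus, function(r) {
    z <- null_zscores(r, n_shuffles, window_length, step, seed)
    data.frame(report_id = z$report_id, n_shuffles = z$n_shuffles,
               seed = z$seed, mr_lcc = z$mr_lcc, sdr_lcc = z$sdr_lcc,
               lcc_z = z$lcc_z, mr_lsc = z$mr_lsc, sdr_lsc = z$sdr_lsc,
               lsc_z = z$lsc_z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
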