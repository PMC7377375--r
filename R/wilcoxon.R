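#' Participant-wise stage medians of a measure
#'
#' For each participant, the median of a measure within each of two sleep
#' stages.  Participants lacking reports in either stage are excluded (and
#' listed in the `excluded` attribute) so that every retained participant
#' contributes exactly one pair.
#'
#' @param measures a per-report measures table (see [corpus_measures()],
#'   possibly merged with z-scores) containing `participant_id`, `stage`
#'   and the measure column.
#' @param measure name of the measure column.
#' @param stages length-2 character; the two stages to pair (order defines
#'   the sign convention of downstream differences).
#' @return An object of class `paired_medians`: a data.frame with columns
#'   `participant_id`, `value1`, `value2` (medians in `stages[1]` and
#'   `stages[2]`), with attributes `stages`, `measure` and `excluded`.
#' @export
participant_medians <- function(measures, measure, stages = c("REM", "N2")) {
  stopifnot(measure %in% names(measures), length(stages) == 2)
  sub <- measures[measures$stage %in% stages & !is.na(measures[[measure]]), ]
  med <- function(pid, st) {
    v <- sub[[measure]][sub$participant_id == pid & sub$stage == st]
    if (length(v)) median(v) else NA_real_
  }
  pids <- unique(sub$participant_id)
  v1 <- vapply(pids, med, numeric(1), st = stages[1])
  v2 <- vapply(pids, med, numeric(1), st = stages[2])
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) {
    stop("no participant has reports in both stages ",
         paste(stages, collapse = " and "), call. = FALSE)
  }
  excluded <- pids[!ok]
  if (length(excluded)) {
    message("participant_medians: excluded participant(s) lacking one stage: ",
            paste(excluded, collapse = ", "))
  }
  structure(
    data.frame(participant_id = pids[ok], value1 = unname(v1[ok]),
               value2 = unname(v2[ok]), stringsAsFactors = FALSE),
    stages = stages, measure = measure, excluded = excluded,
    class = c("paired_medians", "data.frame")
  )
}

#' Wilcoxon signed-rank test on paired participant medians
#'
#' Signed-rank test on the paired differences `value2 - value1` (with the
#' default stage order REM, N2 this makes the z-score negative when REM
#' medians are larger, the display convention of stage-comparison tables).
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks; the z-score uses the normal approximation with tie-corrected
#' variance.  For small samples an exact p-value from full enumeration of
#' all sign assignments is available and is the default for 12 or fewer
#' pairs.
#'
#' The effect size is `r = |z| / sqrt(n_obs)`.  By convention `n_obs`
#' counts the observations entering the comparison: `"pairs_x2"` (default)
#' uses twice the number of non-zero pairs; `"pairs"` uses the number of
#' non-zero pairs; a number may be supplied directly.
#'
#' @param pairs a [participant_medians()] result, or a data.frame with
#'   `value1` and `value2` columns.
#' @param n_obs_convention `"pairs_x2"`, `"pairs"`, or a number.
#' @param exact logical; force (`TRUE`) or suppress (`FALSE`) the exact
#'   enumeration p-value.  Default: exact for <= 12 non-zero pairs.
#' @param continuity apply a 0.5 continuity correction to the normal
#'   approximation (default off).
#' @return An object of class `wilcoxon_result`: list with `z`, `p`,
#'   `p_normal`, `p_exact` (NA unless computed), `r`, `statistic` (sum of
#'   positive ranks), `n_pairs_used`, `n_obs`, `method`.
#' @export
wilcoxon_signed_rank <- function(pairs, n_obs_convention = "pairs_x2",
                                 exact = NULL, continuity = FALSE) {
  d <- pairs$value2 - pairs$value1
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero: no information for a signed-rank test",
         call. = FALSE)
  }
  r_abs <- rank(abs(d))
  W <- sum(r_abs[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r_abs)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    stop("degenerate signed-rank variance (all ranks tied at one value)",
         call. = FALSE)
  }
  dev <- W - mu
  cc <- if (continuity) sign(dev) * 0.5 else 0
  z <- (dev - cc) / sqrt(sigma2)
  p_normal <- min(1, 2 * pnorm(-abs(z)))
  do_exact <- if (is.null(exact)) n <= 12 else isTRUE(exact)
  p_exact <- if (do_exact) exact_signed_rank_p(r_abs, W) else NA_real_
  p <- if (do_exact) p_exact else p_normal
  n_obs <- if (is.numeric(n_obs_convention)) {
    n_obs_convention
  } else {
    switch(match.arg(n_obs_convention, c("pairs_x2", "pairs")),
           pairs_x2 = 2 * n, pairs = n)
  }
  structure(
    list(z = z, p = p, p_normal = p_normal, p_exact = p_exact,
         r = abs(z) / sqrt(n_obs), statistic = W,
         n_pairs_used = n, n_obs = n_obs,
         method = if (do_exact) "exact" else "normal"),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "<wilcoxon_result: W = %.1f, z = %.3f, r = %.3f, p = %.4g (%s, %d pairs)>\n",
    x$statistic, x$z, x$r, x$p, x$method, x$n_pairs_used))
  invisible(x)
}

# Exact two-sided p-value of the signed-rank statistic by dynamic
# programming over all 2^n sign assignments of the (mid-)ranks.  Ranks are
# doubled so mid-ranks become integers.
exact_signed_rank_p <- function(r_abs, W) {
  r2 <- as.integer(round(2 * r_abs))
  total <- sum(r2)
  counts <- numeric(total + 1)  # counts[s + 1] = #assignments with 2W = s
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  s <- 0:total
  obs_dev <- abs(2 * W - total / 2)
  sum(counts[abs(s - total / 2) >= obs_dev - 1e-9]) / 2^length(r2)
}

#' Stage-comparison table of Wilcoxon tests across measures
#'
#' One row per measure: participant-median summaries per stage (median and
#' SD of the participant medians), the signed-rank z, the effect size r and
#' the p-value.
#'
#' @param measures per-report measures table with z-score columns merged in.
#' @param measure_names columns to test (defaults to the six standard
#'   measures: TRC, Edges, LCC, LSC, LCCz, LSCz).
#' @param stages passed to [participant_medians()].
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return A data.frame with columns `measure`, `summary1`, `summary2`
#'   (named after the stages), `z`, `r`, `p`, `n_pairs`, `significant`.
#' @export
wilcoxon_table <- function(measures,
                           measure_names = c("trc", "mean_edges", "mean_lcc",
                                             "mean_lsc", "lcc_z", "lsc_z"),
                           stages = c("REM", "N2"), ...) {
  measure_names <- intersect(measure_names, names(measures))
  rows <- lapply(measure_names, function(m) {
    pm <- participant_medians(measures, m, stages)
    wt <- wilcoxon_signed_rank(pm, ...)
    fmt <- function(v) sprintf("%.2f ± %.2f", median(v), sd(v))
    data.frame(measure = measure_label(m),
               summary1 = fmt(pm$value1), summary2 = fmt(pm$value2),
               z = wt$z, r = wt$r, p = wt$p, n_pairs = wt$n_pairs_used,
               significant = wt$p < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "summary1"] <- stages[1]
  names(out)[names(out) == "summary2"] <- stages[2]
  out
}
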