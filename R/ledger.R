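#' Bottom-up model-comparison ledger
#'
#' Builds the hierarchical model-comparison tables used to evaluate graph
#' measures against report length: starting from a baseline model,
#' candidate predictors are added one at a time; each ledger row records
#' the model's Nagelkerke pseudo-R-squared relative to the null model, the
#' pseudo-R-squared change relative to that row's stated baseline, and the
#' likelihood-ratio p-value for the added term(s).
#'
#' Four designs are provided:
#' \describe{
#'   \item{`time_of_night`}{Gaussian outcome `minutes_since_lights_off`;
#'     baseline = sleep stage; each measure added individually.}
#'   \item{`stage_discernment`}{Binomial outcome `stage` (REM vs N2);
#'     individual measures vs the null model, then the composite
#'     TRC + LCC in both orders (each compared to the single-predictor
#'     model it extends).}
#'   \item{`pirs`}{Ordinal 0-9 complexity outcome; baseline = sleep
#'     stage; individual measures, composites over sleep stage + TRC, the
#'     LCC/LSCz double composites, and optionally stage-by-measure
#'     interaction rows (each compared to its additive model).}
#'   \item{`stage_given_pirs`}{Binomial outcome `stage`; baseline = the
#'     complexity rating, testing whether LCC/TRC still discern stage once
#'     complexity is partialled out.}
#' }
#'
#' @param measures per-report table (from [corpus_measures()] merged with
#'   [corpus_null_zscores()]): needs `stage`, `participant_id`, `night_id`
#'   and the predictor columns in use.
#' @param design one of `"time_of_night"`, `"stage_discernment"`,
#'   `"pirs"`, `"stage_given_pirs"`.
#' @param predictors measure columns considered as individual predictors.
#' @param random grouping columns for random intercepts (Gaussian/binomial
#'   families; the ordinal family uses the first).  Night identifiers are
#'   expected to be unique across participants (nights nested in
#'   participants).
#' @param interactions for the `pirs` design, also emit stage-by-measure
#'   interaction rows.
#' @param paragraph_covariate add `n_paragraphs` to every model (including
#'   baselines and the null), partialling paragraph count out of every
#'   comparison.
#' @param alpha significance threshold for the `significant` flag.
#' @return A data.frame of class `ledger` with columns `label`,
#'   `baseline_label`, `pseudo_r2`, `pseudo_r2_change`, `chi2`, `df`, `p`,
#'   `significant`, `converged`.
#' @export
build_ledger <- function(measures,
                         design = c("time_of_night", "stage_discernment",
                                    "pirs", "stage_given_pirs"),
                         predictors = c("trc", "mean_edges", "mean_lcc",
                                        "mean_lsc", "lcc_z", "lsc_z"),
                         random = c("participant_id", "night_id"),
                         interactions = FALSE,
                         paragraph_covariate = FALSE,
                         alpha = 0.05) {
  design <- match.arg(design)
  predictors <- intersect(predictors, names(measures))
  dat <- prepare_ledger_data(measures, predictors)
  covariate <- if (paragraph_covariate) "n_paragraphs" else character(0)
  if (design == "pirs" && length(random) > 1) {
    message("ordinal family supports one random intercept; using ", random[1])
    random <- random[1]
  }

  spec <- switch(design,
    time_of_night = list(
      outcome = "minutes_since_lights_off", family = "gaussian",
      rows = c(
        list(list(label = "Sleep Stage", terms = "stage", baseline = character(0))),
        lapply(predictors, function(p) list(
          label = paste("Sleep Stage +", measure_label(p)),
          terms = c("stage", p), baseline = "stage"))
      )
    ),
    stage_discernment = list(
      outcome = "stage", family = "binomial",
      rows = c(
        lapply(predictors, function(p) list(
          label = measure_label(p), terms = p, baseline = character(0))),
        if (all(c("trc", "mean_lcc") %in% predictors)) list(
          list(label = "TRC + LCC", terms = c("trc", "mean_lcc"), baseline = "trc"),
          list(label = "LCC + TRC", terms = c("mean_lcc", "trc"), baseline = "mean_lcc"))
      )
    ),
    pirs = list(
      outcome = "pirs", family = "ordinal",
      rows = c(
        list(list(label = "Sleep Stage", terms = "stage", baseline = character(0))),
        lapply(predictors, function(p) list(
          label = paste("Sleep Stage +", measure_label(p)),
          terms = c("stage", p), baseline = "stage")),
        if ("trc" %in% predictors) lapply(
          setdiff(predictors, "trc"), function(p) list(
            label = paste("Sleep Stage + TRC +", measure_label(p)),
            terms = c("stage", "trc", p), baseline = c("stage", "trc"))),
        if (all(c("trc", "mean_lcc", "lsc_z") %in% predictors)) list(
          list(label = "Sleep Stage + TRC + LSCz + LCC",
               terms = c("stage", "trc", "lsc_z", "mean_lcc"),
               baseline = c("stage", "trc", "lsc_z")),
          list(label = "Sleep Stage + TRC + LCC + LSCz",
               terms = c("stage", "trc", "mean_lcc", "lsc_z"),
               baseline = c("stage", "trc", "mean_lcc"))),
        if (interactions) lapply(predictors, function(p) list(
          label = paste0("Sleep Stage × ", measure_label(p)),
          terms = c("stage", p, paste0("stage:", p)),
          baseline = c("stage", p)))
      )
    ),
    stage_given_pirs = list(
      outcome = "stage", family = "binomial",
      rows = {
        base <- "pirs_num"
        c(
          list(list(label = "PIRS", terms = base, baseline = character(0))),
          if ("mean_lcc" %in% predictors) list(list(
            label = "PIRS + LCC", terms = c(base, "mean_lcc"), baseline = base)),
          if ("trc" %in% predictors) list(list(
            label = "PIRS + TRC", terms = c(base, "trc"), baseline = base)),
          if (all(c("trc", "mean_lcc") %in% predictors)) list(list(
            label = "PIRS + LCC + TRC", terms = c(base, "mean_lcc", "trc"),
            baseline = base))
        )
      }
    )
  )
  spec$rows <- Filter(Negate(is.null), spec$rows)

  # every fit must see the same rows: drop reports with a missing value in
  # any column the design touches (e.g. undefined z-scores)
  used_terms <- unique(unlist(lapply(spec$rows, `[[`, "terms")))
  used_cols <- unique(c(spec$outcome, covariate, random,
                        unlist(strsplit(used_terms, "[:*]"))))
  used_cols <- intersect(used_cols, names(dat))
  ok <- complete.cases(dat[used_cols])
  if (!all(ok)) {
    message("build_ledger: dropping ", sum(!ok),
            " report(s) with missing values in ",
            paste(used_cols[vapply(dat[used_cols],
                                   anyNA, logical(1))], collapse = ", "))
    dat <- dat[ok, , drop = FALSE]
  }

  cache <- new.env(parent = emptyenv())
  fit_terms <- function(terms, label = NULL) {
    terms <- c(covariate, terms)
    key <- paste0("m:", paste(sort(terms), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fit_model(dat, spec$outcome, fixed = terms, random = random,
                   family = spec$family, label = label)
    cache[[key]] <- f
    f
  }
  null_fit <- fit_terms(character(0), label = "Null")

  rows <- lapply(spec$rows, function(rw) {
    full <- fit_terms(rw$terms, rw$label)
    base <- fit_terms(rw$baseline)
    lrt <- lr_test(base, full)
    r2_full <- nagelkerke_r2(full, null_fit)
    r2_base <- nagelkerke_r2(base, null_fit)
    data.frame(label = rw$label,
               baseline_label = if (length(rw$baseline)) base$label else "Null",
               pseudo_r2 = r2_full,
               pseudo_r2_change = r2_full - r2_base,
               chi2 = lrt$chi2, df = lrt$df, p = lrt$p,
               significant = lrt$p < alpha,
               converged = full$converged && base$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ledger", "data.frame")
  attr(out, "design") <- design
  attr(out, "family") <- spec$family
  attr(out, "n_obs") <- null_fit$n_obs
  out
}

# Standardize continuous predictors (z-scale) for numerical stability;
# scaling a predictor leaves log-likelihoods, LRTs and pseudo-R2 unchanged.
prepare_ledger_data <- function(measures, predictors) {
  dat <- measures
  dat$stage <- factor(dat$stage, levels = c("N2", "REM"))
  if ("pirs" %in% names(dat)) {
    dat$pirs_num <- as.numeric(dat$pirs)
    dat$pirs <- factor(dat$pirs, ordered = TRUE)
  }
  for (p in unique(c(predictors, "pirs_num", "n_paragraphs",
                     "minutes_since_lights_off"))) {
    if (p %in% names(dat) && is.numeric(dat[[p]])) {
      s <- sd(dat[[p]], na.rm = TRUE)
      if (p != "minutes_since_lights_off") {
        dat[[p]] <- (dat[[p]] - mean(dat[[p]], na.rm = TRUE)) / if (s > 0) s else 1
      }
    }
  }
  dat
}

#' @export
print.ledger <- function(x, ...) {
  cat(sprintf("Model-comparison ledger (%s, %s family, n = %d)\n",
              attr(x, "design"), attr(x, "family"), attr(x, "n_obs")))
  df <- as.data.frame(x)
  df$pseudo_r2 <- sprintf("%.3f", df$pseudo_r2)
  df$pseudo_r2_change <- sprintf("%.3f", df$pseudo_r2_change)
  df$p <- format.pval(df$p, digits = 3, eps = 0.001)
  print(df[, c("label", "pseudo_r2", "pseudo_r2_change", "p", "significant")],
        row.names = FALSE)
  invisible(x)
}
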