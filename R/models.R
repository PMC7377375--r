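#' Fit a fixed- or mixed-effects model for the analysis pipeline
#'
#' A single maximum-likelihood interface over the three model families
#' used in the comparison ledgers: Gaussian (continuous outcomes such as
#' minutes since lights-off), binomial (REM/N2 stage discernment) and
#' ordinal (proportional-odds cumulative-link model for 0-9 complexity
#' ratings).  Random intercepts for grouping factors (participants,
#' nights) use `lme4` (Laplace approximation) for Gaussian/binomial
#' families; the ordinal family supports one random intercept integrated
#' by Gauss-Hermite quadrature.  Grouping factors with fewer than 3 levels
#' are dropped with a message.  All fits maximize the likelihood (never
#' REML), so log-likelihoods of nested fits are directly comparable.
#'
#' @param data a data.frame with one row per report.
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect terms (may include
#'   interaction terms such as `"stage:mean_lcc"`).
#' @param random character vector of random-intercept grouping columns.
#' @param family `"gaussian"`, `"binomial"` or `"ordinal"`.
#' @param label optional display label for ledger rows.
#' @return An object of class `model_fit`: list with `family`, `outcome`,
#'   `fixed`, `random`, `label`, `loglik`, `n_params`, `n_obs`,
#'   `coefficients`, `converged` and the underlying `fit`.
#' @export
fit_model <- function(data, outcome, fixed = character(0),
                      random = character(0),
                      family = c("gaussian", "binomial", "ordinal"),
                      label = NULL) {
  family <- match.arg(family)
  base_vars <- unique(unlist(strsplit(fixed, "[:*]")))
  used <- unique(c(outcome, base_vars, random))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[complete.cases(data[used]), used, drop = FALSE]
  n <- nrow(data)
  random <- keep_usable_groups(data, random)

  if (family == "binomial") {
    data[[outcome]] <- droplevels(as.factor(data[[outcome]]))
    if (nlevels(data[[outcome]]) != 2) {
      stop("binomial outcome must have exactly 2 observed levels", call. = FALSE)
    }
  }
  if (family == "ordinal") {
    return(fit_ordinal(data, outcome, fixed, random, label))
  }

  rhs <- paste(c("1", fixed, sprintf("(1 | %s)", random)), collapse = " + ")
  form <- as.formula(paste(outcome, "~", rhs))
  if (length(random) == 0) {
    fit <- if (family == "gaussian") {
      lm(form, data = data)
    } else {
      glm(form, data = data, family = binomial())
    }
    converged <- if (family == "binomial") fit$converged else TRUE
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    fit <- if (family == "gaussian") {
      lme4::lmer(form, data = data, REML = FALSE)
    } else {
      tryCatch(lme4::glmer(form, data = data, family = binomial()),
               error = identity)
    }
    if (inherits(fit, "error")) {
      # typically complete separation, which breaks glmer's PIRLS step;
      # refit the same mixed logistic model by Gauss-Hermite quadrature
      message("glmer failed (", conditionMessage(fit),
              "); refitting random-intercept logistic model by quadrature")
      return(fit_binary_ghq(data, outcome, fixed, random, family, label))
    }
    converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
    est <- lme4::fixef(fit)
    vc <- try(diag(as.matrix(stats::vcov(fit))), silent = TRUE)
    coefs <- data.frame(term = names(est), estimate = unname(est),
                        se = if (!inherits(vc, "try-error")) sqrt(as.numeric(vc)) else NA_real_,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  ll <- logLik(fit)
  structure(
    list(family = family, outcome = outcome, fixed = fixed, random = random,
         label = label %||% model_label(fixed),
         loglik = as.numeric(ll), n_params = attr(ll, "df"), n_obs = n,
         coefficients = coefs, converged = converged, fit = fit),
    class = "model_fit"
  )
}

# Mixed logistic regression as a 2-level cumulative-link model (identical
# likelihood), used when glmer cannot iterate (e.g. complete separation).
# P(Y = level2) = plogis(eta - theta_1), so slopes are on the glm scale.
fit_binary_ghq <- function(data, outcome, fixed, random, family, label) {
  y <- as.ordered(data[[outcome]])
  X <- if (length(fixed)) {
    mm <- model.matrix(as.formula(paste("~", paste(fixed, collapse = " + "))),
                       data = data)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  if (length(random) > 1) {
    message("quadrature refit supports one random intercept; using ", random[1])
  }
  res <- clm_fit(y, X, groups = data[[random[1]]])
  if (any(abs(res$beta) > 15)) {
    warning("very large slope in logistic refit: possible complete separation",
            call. = FALSE)
  }
  structure(
    list(family = family, outcome = outcome, fixed = fixed, random = random[1],
         label = label %||% model_label(fixed),
         loglik = res$loglik, n_params = res$n_params, n_obs = res$n_obs,
         coefficients = res$coefficients, converged = res$converged,
         fit = res),
    class = "model_fit"
  )
}

fit_ordinal <- function(data, outcome, fixed, random, label) {
  y <- as.ordered(data[[outcome]])
  X <- if (length(fixed)) {
    mm <- model.matrix(as.formula(paste("~", paste(fixed, collapse = " + "))),
                       data = data)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  groups <- if (length(random)) data[[random[1]]] else NULL
  if (length(random) > 1) {
    message("ordinal family supports one random intercept; using ", random[1])
    random <- random[1]
  }
  res <- clm_fit(y, X, groups = groups)
  structure(
    list(family = "ordinal", outcome = outcome, fixed = fixed, random = random,
         label = label %||% model_label(fixed),
         loglik = res$loglik, n_params = res$n_params, n_obs = res$n_obs,
         coefficients = res$coefficients, converged = res$converged, fit = res),
    class = "model_fit"
  )
}

# Drop grouping factors with too few levels to support a random intercept.
keep_usable_groups <- function(data, random) {
  keep <- vapply(random, function(g) {
    nl <- length(unique(data[[g]]))
    if (nl < 3) message("dropping random intercept for '", g,
                        "': only ", nl, " level(s)")
    nl >= 3
  }, logical(1))
  random[keep]
}

model_label <- function(fixed) {
  if (length(fixed) == 0) "Null" else paste(measure_label(fixed), collapse = " + ")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit [%s] %s: logLik = %.3f, k = %d, n = %d%s>\n",
              x$family, x$label, x$loglik, x$n_params, x$n_obs,
              if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi2 = 2 * (logLik_full - logLik_nested)` referred to the chi-square
#' distribution with degrees of freedom equal to the parameter-count
#' difference.
#'
#' @param nested,full [fit_model()] results on the same data and family,
#'   with `nested` a sub-model of `full`.
#' @param tol tolerance for a negative chi-square before erroring.
#' @return A list with `chi2`, `df`, `p`.
#' @export
lr_test <- function(nested, full, tol = 0.02) {
  stopifnot(inherits(nested, "model_fit"), inherits(full, "model_fit"))
  if (nested$family != full$family) {
    stop("cannot compare fits from different families (",
         nested$family, " vs ", full$family, ")", call. = FALSE)
  }
  if (nested$n_obs != full$n_obs) {
    stop("fits use different numbers of observations (",
         nested$n_obs, " vs ", full$n_obs, ")", call. = FALSE)
  }
  if (!all(nested$fixed %in% full$fixed) && nested$n_params > full$n_params) {
    stop("models are not nested: '", nested$label, "' vs '", full$label, "'",
         call. = FALSE)
  }
  chi2 <- 2 * (full$loglik - nested$loglik)
  if (chi2 < -tol) {
    stop(sprintf(
      "full model '%s' has lower log-likelihood than nested '%s' (chi2 = %.4f); refit or check convergence",
      full$label, nested$label, chi2), call. = FALSE)
  }
  chi2 <- max(chi2, 0)
  df <- full$n_params - nested$n_params
  p <- if (df <= 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2 = (1 - exp((2/n) * (LL0 - LL1))) / (1 - exp((2/n) * LL0))`, the
#' Cox-Snell ratio rescaled to a 0-1 range, with `LL0`/`LL1` the null and
#' full log-likelihoods and `n` the number of observations.  Clipped to
#' `[0, 1]`.
#'
#' @param fit,null_fit [fit_model()] results on the same data and family
#'   with `null_fit` nested in `fit`.
#' @return A number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "model_fit"), inherits(null_fit, "model_fit"))
  if (fit$n_obs != null_fit$n_obs) {
    stop("fits use different numbers of observations (",
         fit$n_obs, " vs ", null_fit$n_obs, ")", call. = FALSE)
  }
  n <- fit$n_obs
  cox_snell <- 1 - exp((2 / n) * (null_fit$loglik - fit$loglik))
  max_cs <- 1 - exp((2 / n) * null_fit$loglik)
  if (max_cs <= 0) return(0)
  min(max(cox_snell / max_cs, 0), 1)
}
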