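# Proportional-odds cumulative-link models (logit link) by direct maximum
# likelihood, with an optional Gaussian random intercept integrated out by
# Gauss-Hermite quadrature.  Thresholds are parameterized as
# (theta_1, log successive differences) to keep them ordered.

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via the
# Golub-Welsch eigenvalue method.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Fit a cumulative-link model.  y: ordered factor; X: numeric model matrix
# WITHOUT intercept (thresholds absorb it); groups: optional factor for a
# random intercept.
clm_fit <- function(y, X, groups = NULL, n_quad = 21, maxit = 500) {
  y <- droplevels(as.ordered(y))
  K <- nlevels(y)
  if (K < 2) stop("ordinal outcome needs at least 2 observed levels", call. = FALSE)
  yi <- as.integer(y)
  n <- length(yi)
  p <- ncol(X)
  mixed <- !is.null(groups) && nlevels(droplevels(as.factor(groups))) >= 3
  if (mixed) {
    g <- as.integer(droplevels(as.factor(groups)))
    gh <- gauss_hermite(n_quad)
    gh_w <- gh$weights / sqrt(pi)
  }

  cum_prop <- cumsum(tabulate(yi, K) / n)[-K]
  cum_prop <- pmin(pmax(cum_prop, 1 / (2 * n)), 1 - 1 / (2 * n))
  theta0 <- qlogis(cum_prop)
  zeta0 <- c(theta0[1], log(pmax(diff(theta0), 1e-3)))
  par0 <- c(zeta0, rep(0, p), if (mixed) log(0.3))
  if (mixed) {
    # warm start from the fixed-effects solution: cheaper, better-behaved,
    # and keeps nested mixed fits on comparable footing
    fixed_fit <- clm_fit(y, X, groups = NULL, maxit = maxit)
    theta_f <- fixed_fit$theta
    par0 <- c(theta_f[1], log(pmax(diff(theta_f), 1e-3)),
              fixed_fit$beta, log(0.3))
  }

  unpack <- function(par) {
    zeta <- par[seq_len(K - 1)]
    theta <- cumsum(c(zeta[1], exp(zeta[-1])))
    beta <- par[K - 1 + seq_len(p)]
    sigma <- if (mixed) exp(par[length(par)]) else 0
    list(theta = theta, beta = beta, sigma = sigma)
  }

  # log P(y_i | linear predictor eta_i) for each observation
  obs_logp <- function(theta, eta) {
    upper <- c(theta, Inf)[yi]
    lower <- c(-Inf, theta)[yi]
    log(pmax(plogis(upper - eta) - plogis(lower - eta), 1e-300))
  }

  negll <- function(par) {
    pr <- unpack(par)
    eta_fixed <- if (p) as.vector(X %*% pr$beta) else rep(0, n)
    if (!mixed) {
      return(-sum(obs_logp(pr$theta, eta_fixed)))
    }
    # n x Q matrix of log-probabilities at each quadrature node
    u <- sqrt(2) * pr$sigma * gh$nodes
    lp_g <- matrix(0, max(g), length(u))
    for (q in seq_along(u)) {
      lq <- obs_logp(pr$theta, eta_fixed + u[q])
      lp_g[, q] <- rowsum(lq, g)
    }
    m <- apply(lp_g, 1, max)
    -sum(m + log(pmax(exp(lp_g - m) %*% gh_w, 1e-300)))
  }

  # BFGS with restarts: re-running from the incumbent resets the Hessian
  # approximation and escapes the plateaus that occasionally trap a single
  # pass, keeping nested-model log-likelihoods consistent
  opt <- optim(par0, negll, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  for (round in 1:3) {
    opt2 <- optim(opt$par, negll, method = "BFGS",
                  control = list(maxit = maxit, reltol = 1e-10))
    if (opt$value - opt2$value < 1e-8) { opt <- opt2; break }
    opt <- opt2
  }
  opt$hessian <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
  if (is.null(opt$hessian)) opt$hessian <- diag(NA_real_, length(opt$par))
  pr <- unpack(opt$par)
  se <- rep(NA_real_, length(opt$par))
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(vc, "try-error")) {
    dg <- diag(vc)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }
  beta_idx <- K - 1 + seq_len(p)
  coefs <- data.frame(
    term = c(paste0("threshold_", seq_len(K - 1)), colnames(X),
             if (mixed) "log_sigma_participant"),
    estimate = c(pr$theta, pr$beta, if (mixed) log(pr$sigma)),
    se = c(rep(NA_real_, K - 1), se[beta_idx],
           if (mixed) se[length(se)]),
    stringsAsFactors = FALSE
  )
  list(
    loglik = -opt$value,
    n_params = length(opt$par),
    n_obs = n,
    coefficients = coefs,
    theta = pr$theta,
    beta = setNames(pr$beta, colnames(X)),
    sigma = pr$sigma,
    mixed = mixed,
    converged = opt$convergence == 0
  )
}
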