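test_that("a mixed logistic fit with vanishing cluster variance matches plain ML", {
  # identical clusters carry zero between-cluster variation, so the
  # random-intercept variance is estimated at the boundary (0) and the fit
  # must collapse to plain logistic maximum likelihood
  set.seed(3)
  base <- data.frame(x = rnorm(20))
  base$y <- rbinom(20, 1, plogis(-0.3 + 0.9 * base$x))
  d <- do.call(rbind, lapply(1:20, function(g) transform(base, g = g)))
  d$g <- factor(sprintf("g%02d", d$g))
  d$y <- factor(d$y)
  mixed <- suppressMessages(fit_model(d, "y", "x", random = "g",
                                      family = "binomial"))
  plain <- fit_model(d, "y", "x", family = "binomial")
  est_m <- mixed$coefficients$estimate[mixed$coefficients$term == "x"]
  est_p <- plain$coefficients$estimate[plain$coefficients$term == "x"]
  expect_lt(abs(est_m - est_p), 1e-3)
  expect_lt(abs(mixed$loglik - plain$loglik), 0.01)
})

test_that("glmer and the quadrature logistic refit agree on benign data", {
  set.seed(53)
  n_g <- 24; per <- 12
  g <- rep(seq_len(n_g), each = per)
  u <- rnorm(n_g, 0, 0.8)[g]
  x <- rnorm(n_g * per)
  d <- data.frame(x = x, g = factor(sprintf("g%02d", g)),
                  y = factor(rbinom(n_g * per, 1, plogis(0.2 + 0.7 * x + u))))
  via_glmer <- fit_model(d, "y", "x", random = "g", family = "binomial")
  via_ghq <- dreamgraph:::fit_binary_ghq(d, "y", "x", "g", "binomial", NULL)
  # against the adaptive-quadrature reference fit, the package quadrature
  # route should agree almost exactly; the Laplace fit to ~0.5 in logLik
  ref <- lme4::glmer(y ~ x + (1 | g), data = d, family = binomial(),
                     nAGQ = 21)
  expect_lt(abs(via_ghq$loglik - as.numeric(logLik(ref))), 0.01)
  b_ref <- unname(lme4::fixef(ref)["x"])
  b2 <- via_ghq$coefficients$estimate[via_ghq$coefficients$term == "x"]
  expect_lt(abs(b2 - b_ref), 0.01)
  expect_lt(abs(via_glmer$loglik - via_ghq$loglik), 0.5)
  expect_equal(via_glmer$n_params, via_ghq$n_params)
})

test_that("the logistic slope of a binary predictor equals the table log odds ratio", {
  counts <- matrix(c(30, 20, 12, 38), 2, 2)  # rows: x=0/1; cols: y=0/1
  d <- data.frame(
    x = rep(c(0, 0, 1, 1), times = c(counts[1, 1], counts[1, 2],
                                     counts[2, 1], counts[2, 2])),
    y = rep(c(0, 1, 0, 1), times = c(counts[1, 1], counts[1, 2],
                                     counts[2, 1], counts[2, 2]))
  )
  d$y <- factor(d$y)
  fit <- fit_model(d, "y", "x", family = "binomial")
  log_or <- log((counts[2, 2] * counts[1, 1]) / (counts[2, 1] * counts[1, 2]))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"],
               log_or, tolerance = 1e-6)
})

test_that("the cumulative-link model recovers a known slope at n = 2000", {
  set.seed(17)
  n <- 2000
  beta <- 0.8
  theta <- c(-1, 0, 1.2)
  x <- rnorm(n)
  u <- runif(n)
  cum <- plogis(outer(theta, beta * x, `-`))   # 3 x n cumulative probs
  # draw categories directly from the cumulative probabilities
  y <- integer(n)
  for (i in 1:n) y[i] <- 1 + sum(u[i] > cum[, i])
  d <- data.frame(y = ordered(y, levels = 1:4), x = x)
  fit <- fit_model(d, "y", "x", family = "ordinal")
  b_hat <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_lt(abs(b_hat - beta), 0.15)
  expect_true(fit$converged)
})

test_that("the fixed-effects cumulative-link fit agrees with the reference ML fit", {
  set.seed(21)
  n <- 300
  x <- rnorm(n)
  z <- rnorm(n)
  eta <- 0.7 * x - 0.4 * z
  cum <- plogis(outer(c(-0.8, 0.2, 1), eta, `-`))
  u <- runif(n)
  y <- integer(n)
  for (i in 1:n) y[i] <- 1 + sum(u[i] > cum[, i])
  d <- data.frame(y = ordered(y, levels = 1:4), x = x, z = z)
  mine <- fit_model(d, "y", c("x", "z"), family = "ordinal")
  ref <- MASS::polr(y ~ x + z, data = d, method = "logistic")
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(mine$coefficients$estimate[mine$coefficients$term == "x"],
               unname(coef(ref)["x"]), tolerance = 1e-3)
  expect_equal(mine$n_params, attr(logLik(ref), "df"))
})

test_that("the ordinal random intercept is integrated consistently", {
  set.seed(25)
  n_g <- 30
  per <- 10
  sigma <- 0.9
  g <- rep(seq_len(n_g), each = per)
  u <- rnorm(n_g, 0, sigma)[g]
  x <- rnorm(n_g * per)
  cum <- plogis(outer(c(-1, 0.5), 0.6 * x + u, `-`))
  un <- runif(n_g * per)
  y <- integer(n_g * per)
  for (i in seq_along(y)) y[i] <- 1 + sum(un[i] > cum[, i])
  d <- data.frame(y = ordered(y, levels = 1:3), x = x,
                  g = factor(sprintf("g%02d", g)))
  mixed <- fit_model(d, "y", "x", random = "g", family = "ordinal")
  plain <- fit_model(d, "y", "x", family = "ordinal")
  expect_gt(mixed$loglik, plain$loglik)          # RE explains real variance
  expect_equal(mixed$n_params, plain$n_params + 1)
  expect_gt(mixed$fit$sigma, 0.3)
  b_hat <- mixed$coefficients$estimate[mixed$coefficients$term == "x"]
  expect_lt(abs(b_hat - 0.6), 0.25)
})

test_that("likelihood-ratio tests behave at the identity and textbook points", {
  set.seed(2)
  d <- data.frame(x = rnorm(80), y = rnorm(80))
  f0 <- fit_model(d, "y", family = "gaussian")
  f1 <- fit_model(d, "y", "x", family = "gaussian")
  same <- lr_test(f0, f0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  out <- lr_test(f0, f1)
  expect_equal(out$df, 1)
  expect_gte(out$chi2, 0)
  # textbook quantile: chi2 = 3.84, df = 1 -> p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 0.001)
  # p matches numeric integration of the chi-square density
  dens_p <- integrate(function(t) dchisq(t, 1), out$chi2, Inf)$value
  expect_equal(out$p, dens_p, tolerance = 1e-5)
})

test_that("lr_test rejects incomparable fits", {
  set.seed(4)
  d <- data.frame(x = rnorm(60), y = rnorm(60),
                  b = factor(rbinom(60, 1, 0.5)))
  g1 <- fit_model(d, "y", "x", family = "gaussian")
  g2 <- fit_model(d, "b", "x", family = "binomial")
  expect_error(lr_test(g1, g2), "families")
  d2 <- d[1:50, ]
  g3 <- fit_model(d2, "y", "x", family = "gaussian")
  expect_error(lr_test(g3, g1), "observations")
})

test_that("Nagelkerke R2 is zero at equal likelihoods and monotone on nested chains", {
  set.seed(6)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  eta <- 0.8 * d$x1 + 0.4 * d$x2
  d$y <- factor(rbinom(n, 1, plogis(eta)))
  f0 <- fit_model(d, "y", family = "binomial")
  expect_equal(nagelkerke_r2(f0, f0), 0)
  chain <- list(
    f0,
    fit_model(d, "y", "x1", family = "binomial"),
    fit_model(d, "y", c("x1", "x2"), family = "binomial"),
    fit_model(d, "y", c("x1", "x2", "x3"), family = "binomial")
  )
  r2 <- vapply(chain, nagelkerke_r2, numeric(1), null_fit = f0)
  expect_true(all(diff(r2) >= -1e-10))
  expect_true(all(r2 >= 0 & r2 <= 1))
  # matches an independent recomputation from the raw log-likelihoods
  ll0 <- chain[[1]]$loglik
  ll1 <- chain[[3]]$loglik
  manual <- (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
  expect_equal(nagelkerke_r2(chain[[3]], f0), manual, tolerance = 1e-12)
})

test_that("Nagelkerke R2 approaches 1 on separable data", {
  d <- data.frame(x = c(rnorm(40, -3), rnorm(40, 3)),
                  y = factor(rep(0:1, each = 40)))
  f0 <- fit_model(d, "y", family = "binomial")
  f1 <- suppressWarnings(fit_model(d, "y", "x", family = "binomial"))
  expect_gt(nagelkerke_r2(f1, f0), 0.95)
})

test_that("random intercepts with too few levels are dropped with a message", {
  set.seed(8)
  d <- data.frame(x = rnorm(40), y = rnorm(40),
                  g = factor(rep(c("a", "b"), 20)))
  expect_message(fit <- fit_model(d, "y", "x", random = "g",
                                  family = "gaussian"),
                 "only 2 level")
  expect_length(fit$random, 0)
})
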