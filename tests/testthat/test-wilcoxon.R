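test_that("participant medians are the sort-and-pick group medians", {
  df <- data.frame(
    participant_id = rep(c("P1", "P2", "P3"), each = 4),
    stage = rep(c("REM", "REM", "N2", "N2"), 3),
    m = c(2, 4, 1, 3,   9, 2, 5, 5,   7, 7, 2, 8)
  )
  pm <- participant_medians(df, "m")
  expect_equal(pm$value1, c(3, 5.5, 7))   # REM medians
  expect_equal(pm$value2, c(2, 5, 5))     # N2 medians

  # odd-count median
  df2 <- data.frame(participant_id = "P1", stage = rep("REM", 3), m = c(2, 4, 9))
  df2 <- rbind(df2, data.frame(participant_id = "P1", stage = "N2", m = 1))
  pm2 <- participant_medians(df2, "m")
  expect_equal(pm2$value1, 4)
})

test_that("participants lacking a stage are excluded and logged", {
  df <- data.frame(
    participant_id = c("P1", "P1", "P2"),
    stage = c("REM", "N2", "N2"),
    m = c(1, 2, 3)
  )
  expect_message(pm <- participant_medians(df, "m"), "P2")
  expect_equal(pm$participant_id, "P1")
  expect_equal(attr(pm, "excluded"), "P2")

  df_none <- df[df$stage == "N2", ]
  expect_error(participant_medians(df_none, "m"), "both stages")
})

test_that("medians on a synthetic corpus match direct computation", {
  sim <- generate_corpus(small_study_config(8))
  m <- corpus_measures(filter_min_length(sim$corpus)$kept)
  pm <- suppressMessages(participant_medians(m, "mean_lcc"))
  for (i in seq_len(nrow(pm))) {
    pid <- pm$participant_id[i]
    expect_equal(pm$value1[i],
                 median(m$mean_lcc[m$participant_id == pid & m$stage == "REM"]))
    expect_equal(pm$value2[i],
                 median(m$mean_lcc[m$participant_id == pid & m$stage == "N2"]))
  }
})

test_that("identical paired vectors give the no-information error", {
  pairs <- data.frame(value1 = c(1, 2, 3), value2 = c(1, 2, 3))
  expect_error(wilcoxon_signed_rank(pairs), "zero")
})

test_that("exact p equals full sign-enumeration for small n", {
  # independent oracle: enumerate all 2^n sign assignments directly
  brute_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    rk <- rank(abs(d))
    W_obs <- sum(rk[d > 0])
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.vector(signs %*% rk)
    mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
  }
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d[d == 0] <- 0.5
    pairs <- data.frame(value1 = 0, value2 = d)
    res <- wilcoxon_signed_rank(pairs, exact = TRUE)
    expect_equal(res$p, brute_p(d), tolerance = 1e-12)
  }
  # with ties in |d|
  d <- c(1, -1, 2, 2, -3, 4, 4, 5)
  res <- wilcoxon_signed_rank(data.frame(value1 = 0, value2 = d), exact = TRUE)
  expect_equal(res$p, brute_p(d), tolerance = 1e-12)
})

test_that("exact p agrees with the reference implementation when tie-free", {
  set.seed(29)
  for (i in 1:6) {
    x <- rnorm(10)
    y <- x + rnorm(10, 0.4)
    pairs <- data.frame(value1 = x, value2 = y)
    res <- wilcoxon_signed_rank(pairs, exact = TRUE)
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normal approximation converges to the exact p at n = 12", {
  set.seed(37)
  x <- rnorm(12)
  y <- x + rnorm(12, 0.5)
  pairs <- data.frame(value1 = x, value2 = y)
  exact <- wilcoxon_signed_rank(pairs, exact = TRUE)
  approx <- wilcoxon_signed_rank(pairs, exact = FALSE)
  expect_equal(approx$p, exact$p, tolerance = 0.06)
})

test_that("effect size follows r = |z| / sqrt(n_obs) under each convention", {
  set.seed(43)
  x <- rnorm(19)
  y <- x + rnorm(19, 0.8)
  pairs <- data.frame(value1 = x, value2 = y)
  res <- wilcoxon_signed_rank(pairs)            # pairs_x2 default
  expect_equal(res$n_obs, 2 * res$n_pairs_used)
  expect_equal(res$r, abs(res$z) / sqrt(res$n_obs))
  res_p <- wilcoxon_signed_rank(pairs, n_obs_convention = "pairs")
  expect_equal(res_p$n_obs, res_p$n_pairs_used)
  res_n <- wilcoxon_signed_rank(pairs, n_obs_convention = 38)
  expect_equal(res_n$r, abs(res_n$z) / sqrt(38))
})

test_that("the sign convention makes z negative when stage-1 medians are larger", {
  pairs <- data.frame(value1 = c(5, 6, 7, 8, 9), value2 = c(1, 2, 3, 4, 5))
  res <- wilcoxon_signed_rank(pairs)
  expect_lt(res$z, 0)
})

test_that("wilcoxon_table produces one labeled row per measure", {
  sim <- generate_corpus(small_study_config(8))
  m <- measures_with_z(sim, n_shuffles = 60, seed = 8)
  tab <- suppressMessages(wilcoxon_table(m))
  expect_equal(tab$measure,
               c("TRC", "Edges", "LCC", "LSC", "LCCz", "LSCz"))
  expect_true(all(c("REM", "N2", "z", "r", "p") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
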