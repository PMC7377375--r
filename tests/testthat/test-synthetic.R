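test_that("configuration validation rejects infeasible settings", {
  expect_error(simulation_config(length_floor = 0), "length_floor")
  expect_error(simulation_config(vocabulary_size = 1), "vocabulary_size")
  expect_error(simulation_config(recurrence_range_by_stage = c(REM = 0, N2 = 4)),
               "recurrence_range")
  expect_error(simulation_config(stage_probabilities = c(REM = 1.2, N2 = 0.3)),
               "probabilities")
  expect_error(simulation_config(participant_sd = -1), "non-negative")
})

test_that("the same configuration and seed give a byte-identical corpus", {
  cfg <- small_study_config(99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)

  d1 <- tempfile(); d2 <- tempfile()
  write_corpus(a, d1); write_corpus(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  c2 <- generate_corpus(small_study_config(100))
  expect_false(identical(a$metadata, c2$metadata))
})

test_that("generated reports satisfy the tokenized-report invariants", {
  sim <- generate_corpus(preset_dream_study(11))
  for (r in sim$corpus) {
    expect_s3_class(r, "tokenized_report")
    expect_gt(length(r$tokens), 0)
    expect_equal(r$n_paragraphs, length(r$break_positions) + 1L)
    if (length(r$break_positions)) {
      expect_true(all(r$break_positions >= 1 &
                        r$break_positions <= length(r$tokens) - 1))
    }
  }
  expect_equal(anyDuplicated(sim$metadata$report_id), 0)
  expect_true(all(sim$metadata$pirs %in% 0:9))
})

test_that("most reports meet the 30-token floor under the study preset", {
  lens <- unlist(lapply(1:5, function(s) {
    vapply(generate_corpus(preset_dream_study(s))$corpus,
           function(r) length(r$tokens), 1L)
  }))
  expect_gte(mean(lens >= 30), 0.95)
})

test_that("the preset reproduces the target corpus shape", {
  stats <- lapply(1:10, function(s) {
    sim <- generate_corpus(preset_dream_study(s))
    kept <- filter_min_length(sim$corpus)$kept
    stage <- vapply(kept, function(r) r$meta$stage, "")
    npar <- vapply(kept, function(r) r$n_paragraphs, 1L)
    awk <- sim$ground_truth$awakenings
    list(n = length(kept),
         frac_n2 = mean(stage == "N2"),
         par_rem = mean(npar[stage == "REM"]),
         par_n2 = mean(npar[stage == "N2"]),
         recall_rem = mean(awk$recalled[awk$stage == "REM"]),
         recall_n2 = mean(awk$recalled[awk$stage == "N2"]))
  })
  get <- function(f) vapply(stats, `[[`, numeric(1), f)
  # expected retained corpus size near 133 reports (±20%)
  expect_gt(mean(get("n")), 133 * 0.8)
  expect_lt(mean(get("n")), 133 * 1.2)
  # N2-heavy awakening mix
  expect_gt(mean(get("frac_n2")), 0.55)
  # N2 reports have more paragraphs on average (targets 3.5 vs 2.5)
  expect_gt(mean(get("par_n2")), mean(get("par_rem")))
  # recall rates near the configured 0.907 / 0.724 (binomial error, pooled)
  expect_equal(mean(get("recall_rem")), 0.907, tolerance = 0.06)
  expect_equal(mean(get("recall_n2")), 0.724, tolerance = 0.06)
})

test_that("PIRS increases with the latent complexity in every corpus", {
  for (s in 1:5) {
    sim <- generate_corpus(small_study_config(s))
    gt <- sim$ground_truth$reports
    pirs <- sim$metadata$pirs[match(gt$report_id, sim$metadata$report_id)]
    expect_gt(cor(gt$latent, pirs, method = "spearman"), 0)
  }
})

test_that("a longer recurrence range yields larger windowed connectedness", {
  diffs <- vapply(1:6, function(s) {
    sim <- generate_corpus(preset_dream_study(s))
    m <- corpus_measures(filter_min_length(sim$corpus)$kept)
    pm <- suppressMessages(participant_medians(m, "mean_lcc"))
    median(pm$value1 - pm$value2)     # REM minus N2
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("written corpora round-trip through load_corpus", {
  sim <- generate_corpus(small_study_config(12))
  dir <- tempfile()
  write_corpus(sim, dir)
  reloaded <- load_corpus(file.path(dir, "metadata.tsv"), dir)
  expect_length(reloaded, length(sim$corpus))
  for (i in seq_along(reloaded)) {
    expect_equal(reloaded[[i]]$tokens, sim$corpus[[i]]$tokens)
    expect_equal(reloaded[[i]]$break_positions, sim$corpus[[i]]$break_positions)
    expect_equal(reloaded[[i]]$meta$stage, sim$corpus[[i]]$meta$stage)
  }
})

test_that("a configuration round-trips through the key-value text format", {
  cfg <- preset_dream_study(31)
  path <- tempfile(fileext = ".cfg")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  # and therefore regenerates the identical corpus
  expect_identical(generate_corpus(back)$metadata,
                   generate_corpus(cfg)$metadata)
})

test_that("the zero-effect preset equalizes every stage-dependent parameter", {
  cfg <- preset_null_effect(1)
  for (f in c("recall_probability_by_stage", "length_meanlog_by_stage",
              "length_sdlog_by_stage", "recurrence_prob_by_stage",
              "recurrence_range_by_stage", "paragraph_rate_by_stage")) {
    expect_equal(unname(cfg[[f]]["REM"]), unname(cfg[[f]]["N2"]))
  }
})
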