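#' Configuration for a full analysis run
#'
#' Defaults reproduce the standard analysis settings: 30-word windows
#' moved one word at a time (29-word overlap), a 30-token minimum report
#' length, and 1000 word-order shuffles per report for the null model.
#'
#' @param metadata_path,text_dir a transcript corpus on disk (see
#'   [load_corpus()]); ignored when `simulate` is given.
#' @param simulate a [simulation_config()]; when given the corpus is
#'   generated instead of loaded.
#' @param window_length,step sliding-window parameters.
#' @param min_tokens minimum report length for inclusion.
#' @param n_shuffles shuffles per report for the null z-scores.
#' @param master_seed seed for all randomness in the run.
#' @param stopword_file optional plain-text stop-word list (one word per
#'   line) used by the stop-word rerun.
#' @param analyses subset of `c("wilcoxon", "time_of_night",
#'   "stage_discernment", "pirs", "stage_given_pirs")`.
#' @param interactions emit stage-by-measure interaction rows in the
#'   complexity-rating ledger.
#' @param paragraph_covariate rerun every ledger with `n_paragraphs`
#'   partialled out (written as separate `*_paragraphs` outputs).
#' @param stopword_rerun recompute measures and ledgers on the stop-word
#'   filtered corpus (separate `stopword/` output subdirectory).
#' @param random grouping columns for random intercepts.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(metadata_path = NULL, text_dir = NULL, simulate = NULL,
                       window_length = 30L, step = 1L, min_tokens = 30L,
                       n_shuffles = 1000L, master_seed = 1L,
                       stopword_file = NULL,
                       analyses = c("wilcoxon", "time_of_night",
                                    "stage_discernment", "pirs",
                                    "stage_given_pirs"),
                       interactions = FALSE,
                       paragraph_covariate = FALSE,
                       stopword_rerun = FALSE,
                       random = c("participant_id", "night_id"),
                       out_dir = tempfile("dreamgraph_run")) {
  if (is.null(simulate) && (is.null(metadata_path) || is.null(text_dir))) {
    stop("either a corpus (metadata_path + text_dir) or a simulation config is required",
         call. = FALSE)
  }
  if (isTRUE(stopword_rerun) && is.null(stopword_file)) {
    stop("stopword_rerun requires a stopword_file", call. = FALSE)
  }
  structure(
    list(metadata_path = metadata_path, text_dir = text_dir,
         simulate = simulate, window_length = as.integer(window_length),
         step = as.integer(step), min_tokens = as.integer(min_tokens),
         n_shuffles = as.integer(n_shuffles),
         master_seed = as.integer(master_seed),
         stopword_file = stopword_file, analyses = analyses,
         interactions = isTRUE(interactions),
         paragraph_covariate = isTRUE(paragraph_covariate),
         stopword_rerun = isTRUE(stopword_rerun),
         random = random, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes: corpus acquisition (load or simulate) -> minimum-length
#' filtering -> windowed graph measures -> shuffle-null z-scores ->
#' requested analyses (participant-median Wilcoxon table and the four
#' model-comparison ledgers), plus optional confound reruns (stop-word
#' filtering; paragraph-count covariate).  All tables are written as
#' tab-delimited text under `config$out_dir` together with a JSON run
#' manifest; a rerun with an identical configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the measures table, the Wilcoxon table,
#'   the ledgers, exclusion log and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    sim <- generate_corpus(config$simulate)
    corpus <- sim$corpus
  } else {
    corpus <- load_corpus(config$metadata_path, config$text_dir)
  }

  results <- analyze_corpus(corpus, config, subdir = "")

  if (config$stopword_rerun) {
    sw_corpus <- lapply(corpus, apply_stopword_filter,
                        stopwords = config$stopword_file)
    results$stopword <- analyze_corpus(sw_corpus, config, subdir = "stopword")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dreamgraph")),
    master_seed = config$master_seed,
    window_length = config$window_length, step = config$step,
    min_tokens = config$min_tokens, n_shuffles = config$n_shuffles,
    analyses = config$analyses,
    interactions = config$interactions,
    paragraph_covariate = config$paragraph_covariate,
    stopword_rerun = config$stopword_rerun,
    simulated = !is.null(config$simulate),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# One analysis pass over a corpus; `subdir` separates confound reruns.
analyze_corpus <- function(corpus, config, subdir = "") {
  out_dir <- if (nzchar(subdir)) file.path(config$out_dir, subdir) else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flt <- filter_min_length(corpus, config$min_tokens)
  writeLines(c(flt$log,
               vapply(flt$excluded, function(r)
                 sprintf("excluded %s (%s): %d tokens < %d",
                         r$meta$report_id, r$meta$stage %||% "?",
                         length(r$tokens), config$min_tokens), "")),
             file.path(out_dir, "exclusions.txt"))
  if (length(flt$kept) == 0) stop("no reports survive the minimum word count", call. = FALSE)

  meas <- corpus_measures(flt$kept, config$window_length, config$step)
  nulls <- corpus_null_zscores(flt$kept, config$n_shuffles,
                               config$window_length, config$step,
                               seed = config$master_seed)
  meas <- merge(meas, nulls[, c("report_id", "lcc_z", "lsc_z")],
                by = "report_id", sort = FALSE)
  write_tsv(meas, file.path(out_dir, "measures.tsv"))
  jsonlite::write_json(meas, file.path(out_dir, "measures.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_tsv(nulls, file.path(out_dir, "nulls.tsv"))

  res <- list(measures = meas, nulls = nulls, exclusion_log = flt$log,
              out_dir = out_dir)

  if ("wilcoxon" %in% config$analyses) {
    res$wilcoxon <- wilcoxon_table(meas)
    write_tsv(res$wilcoxon, file.path(out_dir, "wilcoxon.tsv"))
  }
  ledger_designs <- intersect(config$analyses,
                              c("time_of_night", "stage_discernment",
                                "pirs", "stage_given_pirs"))
  res$ledgers <- list()
  for (d in ledger_designs) {
    led <- build_ledger(meas, design = d, random = config$random,
                        interactions = config$interactions && d == "pirs")
    res$ledgers[[d]] <- led
    write_ledger(led, file.path(out_dir, paste0("ledger_", d)))
    if (config$paragraph_covariate) {
      led_p <- build_ledger(meas, design = d, random = config$random,
                            interactions = config$interactions && d == "pirs",
                            paragraph_covariate = TRUE)
      res$ledgers[[paste0(d, "_paragraphs")]] <- led_p
      write_ledger(led_p, file.path(out_dir, paste0("ledger_", d, "_paragraphs")))
    }
  }
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

write_ledger <- function(led, stem) {
  write_tsv(as.data.frame(led), paste0(stem, ".tsv"))
  jsonlite::write_json(as.data.frame(led), paste0(stem, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Cheap deterministic fingerprint of the configuration (polynomial hash of
# its deparsed, simulation-relevant fields).
config_hash <- function(config) {
  x <- config[setdiff(names(config), "out_dir")]
  txt <- paste(deparse(x), collapse = "")
  m <- 2147483587
  h <- 7
  for (c in utf8ToInt(txt)) h <- (h * 131 + c) %% m
  sprintf("%08x", as.integer(h))
}
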