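#' Simulation configuration for synthetic dream-report corpora
#'
#' Collects every knob of the generator in one validated object.  The word
#' process is a two-urn recency model: at each step a report either emits a
#' previously unused word or, with the stage's recurrence probability,
#' re-emits a word drawn uniformly from its most recently used distinct
#' words (the stage's recurrence range).  The recurrence range is the
#' structural knob: words that recur over a longer range create longer
#' loops and more far-reaching connections, hence larger windowed
#' connectedness.
#'
#' @param n_participants number of participants.
#' @param nights_per_participant experimental nights per participant.
#' @param awakenings_per_night controlled awakenings per night.
#' @param stage_probabilities named numeric (`REM`, `N2`): probability that
#'   an awakening is performed in each stage.
#' @param recall_probability_by_stage named numeric: probability that an
#'   awakening yields a dream report.
#' @param length_meanlog_by_stage,length_sdlog_by_stage named numeric:
#'   log-normal parameters of the report token count per stage.
#' @param length_floor minimum report length in tokens (>= 1).
#' @param vocabulary_size distinct words available to a single report.
#' @param recurrence_prob_by_stage named numeric: per-token probability of
#'   re-emitting a recently used word.
#' @param recurrence_range_by_stage named integer: how many of the most
#'   recently used distinct words a recurrence may target.
#' @param paragraph_rate_by_stage named numeric: expected paragraphs per
#'   report (Poisson above a floor of one).
#' @param participant_sd,night_sd SDs of the participant and night random
#'   intercepts on the log-length scale.
#' @param pirs_noise_sd SD of the noise added to the latent complexity
#'   before it is discretized to the ordinal 0-9 complexity rating.
#' @param master_seed integer seed fully determining a corpus.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_participants = 20L,
                              nights_per_participant = 2L,
                              awakenings_per_night = 5L,
                              stage_probabilities = c(REM = 0.27, N2 = 0.73),
                              recall_probability_by_stage = c(REM = 0.907, N2 = 0.724),
                              length_meanlog_by_stage = c(REM = log(100), N2 = log(68)),
                              length_sdlog_by_stage = c(REM = 0.50, N2 = 0.40),
                              length_floor = 5L,
                              vocabulary_size = 1500L,
                              recurrence_prob_by_stage = c(REM = 0.25, N2 = 0.25),
                              recurrence_range_by_stage = c(REM = 12L, N2 = 4L),
                              paragraph_rate_by_stage = c(REM = 2.5, N2 = 3.5),
                              participant_sd = 0.15,
                              night_sd = 0.10,
                              pirs_noise_sd = 0.5,
                              master_seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    nights_per_participant = as.integer(nights_per_participant),
    awakenings_per_night = as.integer(awakenings_per_night),
    stage_probabilities = stage_probabilities,
    recall_probability_by_stage = recall_probability_by_stage,
    length_meanlog_by_stage = length_meanlog_by_stage,
    length_sdlog_by_stage = length_sdlog_by_stage,
    length_floor = as.integer(length_floor),
    vocabulary_size = as.integer(vocabulary_size),
    recurrence_prob_by_stage = recurrence_prob_by_stage,
    recurrence_range_by_stage = recurrence_range_by_stage,
    paragraph_rate_by_stage = paragraph_rate_by_stage,
    participant_sd = participant_sd,
    night_sd = night_sd,
    pirs_noise_sd = pirs_noise_sd,
    master_seed = as.integer(master_seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stages <- c("REM", "N2")
  named_ok <- function(x) all(stages %in% names(x))
  if (!named_ok(cfg$stage_probabilities) ||
      !named_ok(cfg$recall_probability_by_stage) ||
      !named_ok(cfg$length_meanlog_by_stage) ||
      !named_ok(cfg$length_sdlog_by_stage) ||
      !named_ok(cfg$recurrence_prob_by_stage) ||
      !named_ok(cfg$recurrence_range_by_stage) ||
      !named_ok(cfg$paragraph_rate_by_stage)) {
    stop("per-stage parameters must be named vectors with entries REM and N2",
         call. = FALSE)
  }
  probs <- c(cfg$stage_probabilities, cfg$recall_probability_by_stage,
             cfg$recurrence_prob_by_stage)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$length_floor < 1) stop("length_floor must be at least 1", call. = FALSE)
  if (cfg$vocabulary_size < 2) stop("vocabulary_size must be at least 2", call. = FALSE)
  if (any(cfg$recurrence_range_by_stage < 1)) {
    stop("recurrence_range must be at least 1", call. = FALSE)
  }
  if (any(c(cfg$participant_sd, cfg$night_sd, cfg$pirs_noise_sd) < 0)) {
    stop("random-effect and noise SDs must be non-negative", call. = FALSE)
  }
  if (cfg$n_participants < 1 || cfg$nights_per_participant < 1 ||
      cfg$awakenings_per_night < 1) {
    stop("design counts must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Default configuration emulating a two-stage sleep-laboratory study
#'
#' Returns the generator configuration used throughout the package: 20
#' participants, 2 experimental nights of 5 awakenings each (~200
#' awakenings), an N2-heavy awakening mix, stage-dependent recall
#' (REM 0.907, N2 0.724), longer REM reports, longer-range word recurrence
#' in REM (range 12 vs 4), and more paragraphs in N2 reports (rates 3.5 vs
#' 2.5).  Under this configuration the expected retained corpus is roughly
#' 130-155 reports with a heavy N2 majority.
#'
#' @param master_seed integer seed.
#' @return A [simulation_config()].
#' @export
preset_dream_study <- function(master_seed = 1L) {
  simulation_config(master_seed = master_seed)
}

#' Zero-effect variant of the study configuration
#'
#' Identical to [preset_dream_study()] except that every stage-dependent
#' parameter is equalized across REM and N2 (values midway between the
#' study preset's), so any detected stage effect is a false positive.
#' Used for type-I-error calibration of the analysis pipeline.
#'
#' @param master_seed integer seed.
#' @return A [simulation_config()].
#' @export
preset_null_effect <- function(master_seed = 1L) {
  simulation_config(
    recall_probability_by_stage = c(REM = 0.8, N2 = 0.8),
    length_meanlog_by_stage = c(REM = log(78), N2 = log(78)),
    length_sdlog_by_stage = c(REM = 0.45, N2 = 0.45),
    recurrence_range_by_stage = c(REM = 8L, N2 = 8L),
    paragraph_rate_by_stage = c(REM = 3, N2 = 3),
    master_seed = master_seed
  )
}

#' Generate a synthetic dream-report corpus with ground truth
#'
#' Simulates the full study design: for every awakening a sleep stage and
#' recall indicator are drawn; recalled awakenings produce a report whose
#' token count follows the stage's log-normal length distribution shifted
#' by participant and night random intercepts, whose tokens come from the
#' two-urn recency process, and whose paragraph breaks are placed uniformly
#' at random.  A latent complexity score (a fixed linear function of
#' log-length and the stage's recurrence parameters, plus noise) is
#' discretized through fixed equal-width thresholds into the ordinal 0-9
#' complexity rating; the metadata `trc` is the token count (no hesitation
#' fillers are generated).
#'
#' The corpus is fully determined by the configuration (including
#' `master_seed`): repeated calls are identical.
#'
#' @param config a [simulation_config()].
#' @return A list with `corpus` (list of [tokenized_report()]), `metadata`
#'   (data.frame in [load_corpus()] layout), and `ground_truth` (list with
#'   per-report latents/intercepts and the awakening log).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$master_seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  stages <- c("REM", "N2")
  p_stage <- cfg$stage_probabilities[stages] / sum(cfg$stage_probabilities[stages])
  corpus <- list()
  meta_rows <- list()
  truth_rows <- list()
  awk_rows <- list()
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    u_p <- rnorm(1, 0, cfg$participant_sd)
    for (k in seq_len(cfg$nights_per_participant)) {
      nid <- sprintf("%s-N%d", pid, k)
      u_n <- rnorm(1, 0, cfg$night_sd)
      minutes <- sort(round(runif(cfg$awakenings_per_night, 30, 470)))
      for (a in seq_len(cfg$awakenings_per_night)) {
        rid <- sprintf("%s-A%d", nid, a)
        stage <- sample(stages, 1, prob = p_stage)
        recalled <- runif(1) < cfg$recall_probability_by_stage[[stage]]
        awk_rows[[length(awk_rows) + 1L]] <- data.frame(
          report_id = rid, participant_id = pid, night_id = nid,
          stage = stage, recalled = recalled, stringsAsFactors = FALSE)
        if (!recalled) next
        len <- max(cfg$length_floor,
                   round(rlnorm(1, cfg$length_meanlog_by_stage[[stage]] + u_p + u_n,
                                cfg$length_sdlog_by_stage[[stage]])))
        tokens <- emit_tokens(len, cfg$vocabulary_size,
                              cfg$recurrence_prob_by_stage[[stage]],
                              cfg$recurrence_range_by_stage[[stage]])
        n_par <- 1L + rpois(1, max(cfg$paragraph_rate_by_stage[[stage]] - 1, 0))
        n_par <- min(n_par, len)
        breaks <- if (n_par > 1) sort(sample(seq_len(len - 1L), n_par - 1L)) else integer(0)
        latent <- latent_complexity(cfg, stage, len) + rnorm(1, 0, cfg$pirs_noise_sd)
        pirs <- min(max(findInterval(latent, pirs_thresholds()), 0L), 9L)
        meta <- list(report_id = rid, participant_id = pid, night_id = nid,
                     stage = stage, minutes_since_lights_off = minutes[a],
                     pirs = as.integer(pirs), trc = length(tokens))
        corpus[[length(corpus) + 1L]] <- tokenized_report(tokens, breaks, meta)
        meta_rows[[length(meta_rows) + 1L]] <-
          as.data.frame(meta, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          report_id = rid, latent = latent, u_participant = u_p, u_night = u_n,
          stage = stage, length = len,
          recurrence_range = cfg$recurrence_range_by_stage[[stage]],
          recurrence_prob = cfg$recurrence_prob_by_stage[[stage]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(corpus) == 0) stop("configuration produced no reports", call. = FALSE)
  list(
    corpus = corpus,
    metadata = do.call(rbind, meta_rows),
    ground_truth = list(
      reports = do.call(rbind, truth_rows),
      awakenings = do.call(rbind, awk_rows),
      config = unclass(cfg)
    )
  )
}

# Two-urn recency word process.  `recent` holds distinct words ordered by
# recency of last use; a recurrence targets one of its first `range`
# entries uniformly, otherwise an unused vocabulary word is emitted.
emit_tokens <- function(len, vocab_size, rec_prob, rec_range) {
  vocab <- sprintf("w%04d", seq_len(vocab_size))
  recent <- character(0)
  next_new <- 1L
  tokens <- character(len)
  for (i in seq_len(len)) {
    recur <- length(recent) > 0 &&
      (runif(1) < rec_prob || next_new > vocab_size)
    if (recur) {
      w <- recent[sample.int(min(rec_range, length(recent)), 1)]
      recent <- c(w, recent[recent != w])
    } else {
      w <- vocab[next_new]
      next_new <- next_new + 1L
      recent <- c(w, recent)
    }
    tokens[i] <- w
  }
  tokens
}

# Fixed linear latent-complexity score.  Constants are design choices, not
# fitted: they center the score near 0 for a mid-length report with a
# mid-range recurrence process so the fixed thresholds cover the scale.
latent_complexity <- function(cfg, stage, len) {
  0.9 * (log(len) - log(75)) / 0.5 +
    0.5 * (cfg$recurrence_range_by_stage[[stage]] - 8) / 4 +
    0.3 * (cfg$recurrence_prob_by_stage[[stage]] - 0.25) / 0.1
}

# Equal-width thresholds on the latent scale mapping to ratings 0..9.
pirs_thresholds <- function() seq(-2, 2, length.out = 9)

#' Write and read a simulation configuration as key-value text
#'
#' A flat `key = value` file (per-stage parameters as `name.REM` /
#' `name.N2`) that, together with its `master_seed`, fully determines a
#' corpus.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `path` invisibly; `read_simulation_config()` returns the
#'   reconstructed [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  lines <- unlist(lapply(names(config), function(nm) {
    v <- config[[nm]]
    if (length(v) > 1) {
      sprintf("%s.%s = %.17g", nm, names(v), as.numeric(v))
    } else {
      sprintf("%s = %.17g", nm, as.numeric(v))
    }
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  lines <- grep("=", readLines(path, warn = FALSE), value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      args[[parts[1]]][parts[2]] <- vals[i]
    } else {
      args[[keys[i]]] <- vals[i]
    }
  }
  int_fields <- c("recurrence_range_by_stage")
  for (f in int_fields) if (!is.null(args[[f]])) args[[f]] <- round(args[[f]])
  do.call(simulation_config, args)
}

#' Write a corpus to disk in the transcript + metadata layout
#'
#' Emits `metadata.tsv` plus one `<report_id>.txt` transcript per report
#' (tokens separated by spaces, paragraphs separated by blank lines), the
#' exact layout read back by [load_corpus()].
#'
#' @param sim result of [generate_corpus()], or any list with `corpus` and
#'   `metadata` elements.
#' @param dir output directory (created if needed).
#' @param ground_truth if `TRUE` and present, also writes
#'   `ground_truth.json`.
#' @return The metadata file path, invisibly.
#' @export
write_corpus <- function(sim, dir, ground_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  for (r in sim$corpus) {
    paras <- split(r$tokens, token_paragraph_ids(r))
    txt <- paste(vapply(paras, paste, character(1), collapse = " "),
                 collapse = "\n\n")
    writeLines(txt, file.path(dir, paste0(r$meta$report_id, ".txt")))
  }
  if (ground_truth && !is.null(sim$ground_truth)) {
    jsonlite::write_json(sim$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(meta_path)
}
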