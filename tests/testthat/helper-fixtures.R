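# Shared fixture builders.  All corpora are generated in code; nothing is
# read from disk except what the tests themselves write to tempdirs.

make_report <- function(tokens, breaks = integer(0), id = "R1", stage = "REM",
                        participant = "P01", night = "P01-N1",
                        minutes = 120, pirs = NA, trc = NA) {
  tokenized_report(tokens, breaks, meta = list(
    report_id = id, participant_id = participant, night_id = night,
    stage = stage, minutes_since_lights_off = minutes, pirs = pirs, trc = trc))
}

# Write a tiny on-disk corpus and return its paths.
write_demo_corpus <- function(dir = tempfile("corpus"), sep = ",") {
  dir.create(dir, recursive = TRUE)
  meta <- data.frame(
    report_id = c("r1", "r2", "r3"),
    participant_id = c("P01", "P01", "P02"),
    night_id = c("P01-N1", "P01-N1", "P02-N1"),
    stage = c("REM", "N2", "REM"),
    minutes_since_lights_off = c(95, 210, 300),
    pirs = c(7, 3, NA),
    trc = c(18, NA, 11),
    stringsAsFactors = FALSE
  )
  texts <- c(
    r1 = "I was flying over the city.\n\nThen the city became a forest.",
    r2 = "Something about a dog. The dog ran away, um, twice.",
    r3 = "A staircase going down and down and down."
  )
  path <- file.path(dir, "metadata.csv")
  write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  for (id in names(texts)) {
    writeLines(texts[[id]], file.path(dir, paste0(id, ".txt")))
  }
  list(metadata = path, dir = dir, meta = meta)
}

# A small simulated study used by model-layer tests (cheaper than the
# full default study configuration).
small_study_config <- function(seed = 1, ...) {
  simulation_config(n_participants = 10, nights_per_participant = 2,
                    awakenings_per_night = 4, master_seed = seed, ...)
}

# Measures table with z-scores for ledger tests.
measures_with_z <- function(sim, n_shuffles = 100, seed = 1) {
  flt <- filter_min_length(sim$corpus)
  m <- corpus_measures(flt$kept)
  nz <- corpus_null_zscores(flt$kept, n_shuffles = n_shuffles, seed = seed)
  merge(m, nz[, c("report_id", "lcc_z", "lsc_z")], by = "report_id",
        sort = FALSE)
}
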