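# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed for a (master seed, report id) pair so corpus-level
# runs are independent of report order.  Polynomial string hash folded into
# the positive 32-bit integer range.
seed_for_report <- function(master_seed, report_id) {
  m <- 2147483587
  h <- 17
  for (c in utf8ToInt(as.character(report_id))) {
    h <- (h * 131 + c) %% m
  }
  as.integer((as.numeric(master_seed) %% m * 7919 + h) %% m) + 1L
}

# Display labels used in Wilcoxon and ledger tables.
measure_label <- function(x) {
  map <- c(trc = "TRC", mean_edges = "Edges", mean_lcc = "LCC",
           mean_lsc = "LSC", lcc_z = "LCCz", lsc_z = "LSCz",
           stage = "Sleep Stage", pirs = "PIRS",
           n_paragraphs = "Paragraphs")
  out <- unname(map[x])
  out[is.na(out)] <- x[is.na(out)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
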