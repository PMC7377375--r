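# Brute-force oracle for graph connectedness measures, independent of the
# package implementation: boolean reachability-matrix closure plus
# exhaustive mutual-reachability partitioning.

oracle_measures <- function(tokens, break_positions = integer(0)) {
  nodes <- unique(tokens)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(tokens) > 1) {
    for (i in seq_len(length(tokens) - 1)) {
      if (i %in% break_positions) next
      A[tokens[i], tokens[i + 1]] <- TRUE
    }
  }
  edges <- sum(A)
  closure <- function(M) {
    R <- M | diag(TRUE, n)
    repeat {
      R2 <- R | ((R %*% R) > 0)
      if (identical(R2, R)) return(R)
      R <- R2
    }
  }
  comp_max <- function(R) {
    # mutual reachability is an equivalence relation; largest class size
    M <- R & t(R)
    ids <- apply(M, 1, function(row) paste(which(row), collapse = ","))
    max(table(ids))
  }
  lcc <- comp_max(closure(A | t(A)))
  lsc <- comp_max(closure(A))
  list(edges = edges, lcc = as.integer(lcc), lsc = as.integer(lsc))
}

# Random token sequence with optional paragraph breaks.
random_token_seq <- function(max_len = 40, vocab = 10, p_break = 0) {
  n <- sample(2:max_len, 1)
  tokens <- paste0("w", sample.int(vocab, n, replace = TRUE))
  breaks <- if (p_break > 0 && n > 2) {
    which(runif(n - 1) < p_break)
  } else {
    integer(0)
  }
  list(tokens = tokens, break_positions = breaks)
}
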