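test_that("tokenize lowercases, strips punctuation and records paragraphs", {
  tk <- tokenize("The dog. The dog ran.")
  expect_equal(tk$tokens, c("the", "dog", "the", "dog", "ran"))
  expect_equal(tk$break_positions, integer(0))

  tk2 <- tokenize("a b\n\nc d")
  expect_equal(tk2$tokens, c("a", "b", "c", "d"))
  expect_equal(tk2$break_positions, 2L)
  r <- tokenized_report(tk2$tokens, tk2$break_positions)
  expect_equal(r$n_paragraphs, 2L)

  # intra-word apostrophes and hyphens survive; other punctuation splits
  tk3 <- tokenize("I didn't re-enter -- honestly!")
  expect_equal(tk3$tokens, c("i", "didn't", "re-enter", "honestly"))

  expect_error(tokenize("!!! ..."), "no alphabetic tokens")
})

test_that("tokenization is idempotent on its own output", {
  set.seed(41)
  for (i in 1:20) {
    seq <- random_token_seq(40, 12)
    joined <- paste(seq$tokens, collapse = " ")
    expect_equal(tokenize(joined)$tokens, seq$tokens)
  }
})

test_that("load_corpus reads reports in metadata order for both delimiters", {
  for (sep in c(",", "\t")) {
    cp <- write_demo_corpus(sep = sep)
    corpus <- load_corpus(cp$metadata, cp$dir)
    expect_length(corpus, 3)
    expect_equal(vapply(corpus, function(r) r$meta$report_id, ""),
                 c("r1", "r2", "r3"))
    expect_equal(corpus[[1]]$n_paragraphs, 2L)
    expect_equal(corpus[[1]]$meta$pirs, 7)
    expect_true(is.na(corpus[[3]]$meta$pirs))
  }
})

test_that("metadata validation names the offending field and row", {
  cp <- write_demo_corpus()
  meta <- cp$meta
  meta$pirs[2] <- 12
  write.table(meta, cp$metadata, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  expect_error(load_corpus(cp$metadata, cp$dir), "pirs")
  expect_error(load_corpus(cp$metadata, cp$dir), "row 2")

  meta$pirs[2] <- 3
  meta$stage[1] <- "N5"
  write.table(meta, cp$metadata, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  expect_error(load_corpus(cp$metadata, cp$dir), "stage")
})

test_that("missing transcript files and duplicate ids are reported", {
  cp <- write_demo_corpus()
  file.remove(file.path(cp$dir, "r2.txt"))
  expect_error(load_corpus(cp$metadata, cp$dir), "r2")

  cp2 <- write_demo_corpus()
  meta <- cp2$meta
  meta$report_id[2] <- "r1"
  write.table(meta, cp2$metadata, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  expect_error(load_corpus(cp2$metadata, cp2$dir), "duplicate")
})

test_that("stop-word filtering removes tokens and re-indexes breaks", {
  r <- make_report(c("the", "dog", "ran"), id = "s1")
  f <- apply_stopword_filter(r, c("the"))
  expect_equal(f$tokens, c("dog", "ran"))

  # break survives between paragraphs that keep tokens
  r2 <- make_report(c("the", "dog", "the", "cat"), breaks = 2L)
  f2 <- apply_stopword_filter(r2, c("the"))
  expect_equal(f2$tokens, c("dog", "cat"))
  expect_equal(f2$break_positions, 1L)
  expect_equal(f2$n_paragraphs, 2L)

  # a paragraph emptied by the filter disappears
  r3 <- make_report(c("the", "a", "dog", "ran"), breaks = 2L)
  f3 <- apply_stopword_filter(r3, c("the", "a"))
  expect_equal(f3$tokens, c("dog", "ran"))
  expect_equal(f3$n_paragraphs, 1L)

  # disjoint list is the identity
  f4 <- apply_stopword_filter(r, c("zebra"))
  expect_equal(f4$tokens, r$tokens)

  expect_warning(apply_stopword_filter(r, character(0)), "empty")
})

test_that("stop-word filtering never increases token or paragraph counts", {
  set.seed(7)
  sw <- c("w1", "w2", "w3")
  for (i in 1:25) {
    seq <- random_token_seq(40, 8, p_break = 0.1)
    r <- make_report(seq$tokens, seq$break_positions)
    f <- tryCatch(apply_stopword_filter(r, sw), error = function(e) NULL)
    if (is.null(f)) next  # filter removed everything
    expect_lte(length(f$tokens), length(r$tokens))
    expect_lte(f$n_paragraphs, r$n_paragraphs)
    expect_false(any(f$tokens %in% sw))
  }
})

test_that("the bundled stop-word list is read from file", {
  path <- system.file("extdata", "stopwords_english.txt",
                      package = "dreamgraph")
  r <- make_report(c("i", "was", "flying", "over", "the", "sea"))
  f <- apply_stopword_filter(r, path)
  expect_equal(f$tokens, c("flying", "sea"))
})

test_that("filter_min_length partitions at the boundary and logs by stage", {
  r29 <- make_report(paste0("w", 1:29), id = "a", stage = "N2")
  r30 <- make_report(paste0("w", 1:30), id = "b", stage = "REM")
  out <- filter_min_length(list(r29, r30))
  expect_equal(vapply(out$kept, function(r) r$meta$report_id, ""), "b")
  expect_equal(vapply(out$excluded, function(r) r$meta$report_id, ""), "a")
  expect_match(out$log, "N2 = 1")

  # partition property on a mixed corpus
  set.seed(11)
  corpus <- lapply(1:20, function(i) {
    n <- sample(20:45, 1)
    make_report(paste0("w", seq_len(n)), id = paste0("r", i),
                stage = sample(c("REM", "N2"), 1))
  })
  out2 <- filter_min_length(corpus)
  expect_equal(length(out2$kept) + length(out2$excluded), length(corpus))
  expect_true(all(vapply(out2$kept, function(r) length(r$tokens), 1L) >= 30))
  expect_true(all(vapply(out2$excluded, function(r) length(r$tokens), 1L) < 30))

  all_kept <- filter_min_length(list(r30, r30))
  expect_length(all_kept$excluded, 0)
})

test_that("word_count discounts fillers and effective_trc prefers the rated value", {
  r <- make_report(c("i", "was", "um", "flying"))
  expect_equal(word_count(r), 3)
  expect_equal(word_count(r, fillers = character(0)), 4)

  r_rated <- make_report(c("i", "was", "um", "flying"), trc = 51)
  expect_equal(effective_trc(r_rated), 51)
  expect_equal(effective_trc(r), 3)
})
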