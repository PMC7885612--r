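test_that("single-header text becomes one full-cover section", {
  s <- segment_sections("FAMILY HISTORY: none.")
  expect_equal(nrow(s), 1L)
  expect_equal(s$name, "FAMILY_HISTORY")
  expect_equal(s$start, 1L)
  expect_equal(s$end, nchar("FAMILY HISTORY: none.") + 1L)
})

test_that("the seven canonical history headers segment in order", {
  headers <- c("CLINICAL HISTORY", "HISTORY OF PRESENT ILLNESS",
               "PAST MEDICAL HISTORY", "ALLERGIES", "FAMILY HISTORY",
               "CHIEF COMPLAINT", "MAJOR SURGICAL OR INVASIVE PROCEDURE")
  text <- paste(paste0(headers, ": stuff here."), collapse = " ")
  s <- segment_sections(text)
  expect_equal(nrow(s), 7L)
  expect_equal(s$name, gsub(" ", "_", headers))
})

test_that("section spans partition the text exactly", {
  set.seed(5)
  headers <- unlist(lapply(section_lexicon(), `[[`, 1))
  for (rep in 1:10) {
    hs <- sample(headers, sample(2:6, 1))
    text <- paste0(if (rep %% 2) "preamble text " else "",
                   paste(paste0(hs, ": ", rep, " content."),
                         collapse = " "))
    s <- segment_sections(text)
    expect_equal(s$start[1], 1L)
    expect_equal(s$end[nrow(s)], nchar(text) + 1L)
    if (nrow(s) > 1L) {
      expect_equal(s$start[-1], s$end[-nrow(s)])  # no gaps, no overlaps
    }
    rebuilt <- paste(vapply(seq_len(nrow(s)), function(j) {
      substr(text, s$start[j], s$end[j] - 1L)
    }, character(1)), collapse = "")
    expect_identical(rebuilt, text)
  }
})

test_that("headerless text is a single OTHER section", {
  s <- segment_sections("no headers at all here")
  expect_equal(s$name, "OTHER")
  expect_equal(s$end - s$start, nchar("no headers at all here"))
})

test_that("tokenization lowercases, strips punctuation, flags stop words", {
  tk <- tokenize_text("Systolic Blood Pressure.")
  expect_equal(tk$tokens, c("systolic", "blood", "pressure"))
  expect_false(any(tk$stopword))
  tk2 <- tokenize_text("the urine")
  expect_equal(tk2$tokens, c("the", "urine"))
  expect_equal(tk2$stopword, c(TRUE, FALSE))
  expect_length(tokenize_text("")$tokens, 0L)
  expect_length(tokenize_text("  ...  ")$tokens, 0L)
})

test_that("tokenizing detokenized output is a fixed point", {
  set.seed(8)
  texts <- c("Pt w/ CHF, on pressors; urine output 30cc/hr.",
             "ALLERGIES: none known. Family hx of DM-2!",
             paste(sample(letters, 30, replace = TRUE), collapse = " "))
  for (tx in texts) {
    t1 <- tokenize_text(tx)$tokens
    t2 <- tokenize_text(paste(t1, collapse = " "))$tokens
    expect_identical(t2, t1)
  }
})

test_that("pad_or_truncate enforces the length contract", {
  long <- pad_or_truncate(sprintf("t%04d", 1:1200), 1000L)
  expect_equal(long$content_length, 1000L)
  expect_equal(long$tokens[1000], "t1000")
  short <- pad_or_truncate(sprintf("t%03d", 1:900), 1000L)
  expect_equal(short$content_length, 900L)
  expect_true(all(short$tokens[901:1000] == ""))
  expect_false(any(short$stopword_mask[901:1000]))
  empty <- pad_or_truncate(character(0), 50L)
  expect_equal(empty$content_length, 0L)
  expect_true(all(empty$tokens == ""))
})

test_that("truncation clips section spans to retained content", {
  sec <- data.frame(name = c("A", "B"), start = c(1L, 6L), end = c(6L, 11L))
  sq <- pad_or_truncate(letters[1:10], 8L, sections = sec)
  expect_equal(sq$sections$end, c(6L, 9L))
  # pad ids fill the tail after vocabulary encoding
  enc <- encode_tokens(sq, build_vocab(list(letters[1:10])))
  expect_true(all(enc$ids[1:8] > 1L))
})

test_that("bundle text puts history notes before window notes", {
  hist_note <- make_note(-60, "PAST MEDICAL HISTORY: oldword here.")
  win_note <- make_note(5, "CHIEF COMPLAINT: newword now.")
  e <- make_episode(notes = list(win_note, hist_note))
  sq <- assemble_bundle_text(select_notes(e, 48, chronic = TRUE), 50L)
  toks <- sq$tokens[seq_len(sq$content_length)]
  expect_lt(which(toks == "oldword"), which(toks == "newword"))
  # non-chronic bundle equals the window note alone
  sq_non <- assemble_bundle_text(select_notes(e, 48, chronic = FALSE), 50L)
  sq_win <- assemble_bundle_text(
    select_notes(make_episode(notes = list(win_note)), 48, chronic = FALSE),
    50L)
  expect_identical(sq_non, sq_win)
})

test_that("window notes are ordered by chart time regardless of input order", {
  n1 <- make_note(2, "CHIEF COMPLAINT: first note.")
  n2 <- make_note(20, "FAMILY HISTORY: second note.")
  n3 <- make_note(40, "ALLERGIES: third note.")
  perms <- list(list(n1, n2, n3), list(n3, n1, n2), list(n2, n3, n1))
  ref <- NULL
  for (pp in perms) {
    sq <- assemble_bundle_text(
      select_notes(make_episode(notes = pp), 48, chronic = FALSE), 60L)
    if (is.null(ref)) ref <- sq else expect_identical(sq, ref)
  }
})

test_that("assembled section spans partition the content", {
  cohort <- generate_cohort(cohort_spec(5, prevalence = 0.5, seed = 12))
  for (p in cohort) {
    e <- as_episodes(list(p))[[1]]
    sq <- assemble_bundle_text(select_notes(e, 48, chronic = TRUE), 200L)
    s <- sq$sections
    expect_equal(s$start[1], 1L)
    expect_equal(s$end[nrow(s)], sq$content_length + 1L)
    if (nrow(s) > 1L) expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  # an empty bundle yields an all-pad sequence
  sq0 <- assemble_bundle_text(list(stay_id = "x", notes = list(), K = 0L),
                              30L)
  expect_equal(sq0$content_length, 0L)
})

test_that("vocabulary reserves pad and UNK; unknown tokens map to UNK", {
  v <- build_vocab(list(c("b", "a", "b")))
  expect_equal(v[1:2], c("<pad>", "<unk>"))
  expect_equal(v[3], "b")  # frequency order
  sq <- encode_tokens(pad_or_truncate(c("b", "zzz"), 4L), v)
  expect_equal(sq$ids, c(match("b", v), 2L, 1L, 1L))
  expect_equal(build_vocab(list()), c("<pad>", "<unk>"))
})

test_that("word2vec text files parse and seed the embedding table", {
  path <- tempfile()
  writeLines(c("3 4",
               "sepsis 0.1 0.2 0.3 0.4",
               "urine -1 0 1 0.5",
               "foley 2 2 2 2"), path)
  vec <- read_word2vec(path)
  expect_equal(dim(vec), c(3L, 4L))
  expect_equal(vec["urine", ], c(-1, 0, 1, 0.5))
  expect_error(read_word2vec(tempfile()), "not found")
  bad <- tempfile(); writeLines(c("2 4", "w1 1 2 3"), bad)
  expect_error(read_word2vec(bad), "promises")

  cfg <- small_config(L_max = 20L)
  cfg$embed_dim <- 4L
  vocab <- c("<pad>", "<unk>", "sepsis", "other")
  set.seed(1)
  params <- mortnet:::init_params(cfg, length(vocab))
  out <- mortnet:::apply_pretrained_embeddings(params, vocab, path, cfg)
  expect_equal(out$emb[3, ], c(0.1, 0.2, 0.3, 0.4))   # found in the file
  expect_equal(out$emb[4, ], params$emb[4, ])          # kept random init
  expect_equal(out$emb[1, ], rep(0, 4))                # pad stays zero
  expect_equal(attr(out, "n_pretrained"), 1L)
  cfg$embed_dim <- 5L
  expect_error(mortnet:::apply_pretrained_embeddings(params, vocab, path,
                                                     cfg), "dimension")
})
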