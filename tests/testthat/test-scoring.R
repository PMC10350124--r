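test_that("text cleaning lower-cases, strips punctuation, tokenizes", {
  expect_equal(clean_text("Abbey skipped rocks."), c("abbey", "skipped", "rocks"))
  expect_equal(clean_text("Don't stop!"), c("dont", "stop"))
  expect_equal(clean_text(""), character(0))
  expect_equal(clean_text("  well-known,  fact "), c("wellknown", "fact"))
})

test_that("sentence scoring counts common words regardless of order", {
  s <- score_sentences("Skipped Abbey rocks", "Abbey skipped rocks")
  expect_equal(s$n_correct, 3L)
  expect_equal(s$percent, 100)
  # identity scores 100% for any input
  txt <- c("a big brown dog", "the cat sat on the mat")
  expect_equal(score_sentences(txt, txt)$percent, 100)
  # repeated words count with multiset semantics (min of per-word counts)
  s2 <- score_sentences(list(c("the", "the", "cat")), list(c("the", "cat", "sat")))
  expect_equal(s2$n_correct, 2L)
  expect_equal(s2$n_total, 3L)
  expect_error(score_sentences(list("a"), list("a", "b")), "equal length")
})

test_that("sentence scoring is invariant to word order and pools totals", {
  set.seed(11)
  vocab <- c("the", "cat", "dog", "sat", "ran", "big")
  for (i in 1:20) {
    tra <- sample(vocab, sample(2:6, 1), replace = TRUE)
    res <- sample(vocab, sample(1:6, 1), replace = TRUE)
    base <- score_sentences(list(res), list(tra))
    perm <- score_sentences(list(sample(res)), list(tra))
    expect_equal(perm$n_correct, base$n_correct)
  }
  pooled <- score_sentences(list(c("a", "b"), c("c", "d", "e")),
                            list(c("a", "x"), c("c", "d", "y")))
  expect_equal(pooled$n_correct, 3L)
  expect_equal(pooled$n_total, 5L)
  expect_equal(pooled$percent, 60)
})

test_that("word matching is spelling-exact unless a phonetic backend matches", {
  be <- homophone_backend()
  expect_true(words_match("cat", "cat"))
  expect_false(words_match("cat", "dog"))
  expect_false(words_match("wine", "whine"))
  expect_true(words_match("wine", "whine", phonetic = be))
  expect_true(words_match("knight", "night", phonetic = be))
  expect_false(words_match("wine", "vine", phonetic = be))
  # symmetry
  pairs <- list(c("wine", "whine"), c("sea", "see"), c("cat", "dog"),
                c("their", "there"))
  for (p in pairs) {
    expect_equal(words_match(p[1], p[2], phonetic = be),
                 words_match(p[2], p[1], phonetic = be))
  }
})

test_that("a failing phonetic backend falls back to spelling with a warning", {
  bad <- function(token) stop("boom")
  # one warning per token the backend fails on
  expect_warning(
    expect_warning(out <- words_match("wine", "whine", phonetic = bad),
                   "falling back"),
    "falling back"
  )
  expect_false(out)
})

test_that("homophones count as correct in scoring when the backend is on", {
  be <- homophone_backend()
  off <- score_sentences("the wine was red", "the whine was red")
  on <- score_sentences("the wine was red", "the whine was red", phonetic = be)
  expect_equal(off$n_correct, 3L)
  expect_equal(on$n_correct, 4L)
  al <- align_and_score_words("one two tail", "won too tale", phonetic = be)
  expect_equal(al$percent, 100)
})

test_that("alignment scoring equalizes lengths by best single-word deletions", {
  # equal lengths: plain positional comparison
  expect_equal(align_and_score_words(c("a", "b"), c("a", "c"))$n_correct, 1L)
  # surplus in the result: delete "big"
  s <- align_and_score_words(c("the", "big", "cat", "sat"), c("the", "cat", "sat"))
  expect_equal(s$n_correct, 3L)
  expect_equal(s$n_total, 3L)
  # surplus in the transcript: delete "the" from the transcript
  s2 <- align_and_score_words(c("cat", "sat"), c("the", "cat", "sat"))
  expect_equal(s2$n_correct, 2L)
  expect_equal(s2$n_total, 3L)
  # an empty model result scores 0 over the transcript length
  s3 <- align_and_score_words(character(0), c("a", "b", "c"))
  expect_equal(s3$n_correct, 0L)
  expect_equal(s3$n_total, 3L)
  expect_error(align_and_score_words(c("a"), character(0)), "empty transcript")
})

test_that("the exhaustive oracle matches hand-computed optima", {
  expect_equal(
    brute_force_alignment_score(c("the", "big", "cat", "sat"),
                                c("the", "cat", "sat"))$n_correct, 3L)
  expect_equal(
    brute_force_alignment_score(c("a", "b"), c("a", "c"))$n_correct, 1L)
  expect_error(
    brute_force_alignment_score(letters[1:15], letters[1:10], max_size = 20),
    "too large")
})

test_that("greedy alignment never beats the oracle on random instances", {
  set.seed(23)
  vocab <- c("a", "b", "c", "d")
  for (i in 1:100) {
    tlen <- sample(1:6, 1)
    rlen <- max(1, tlen + sample(-2:2, 1))
    tra <- sample(vocab, tlen, replace = TRUE)
    res <- sample(vocab, rlen, replace = TRUE)
    g <- align_and_score_words(res, tra)$n_correct
    b <- brute_force_alignment_score(res, tra)$n_correct
    expect_lte(g, b)
    if (tlen == rlen) expect_equal(g, b)
  }
})
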