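#' Clean raw text into a scoring word sequence
#'
#' Lower-cases the text, strips all punctuation (including apostrophes and
#' hyphens, which are removed without inserting a space: "Don't" becomes
#' "dont"), and splits on whitespace.
#'
#' @param text A character scalar (or vector, cleaned elementwise and
#'   concatenated in order).
#' @return Character vector of lower-case, punctuation-free tokens; empty
#'   input yields `character(0)`.
#' @examples
#' clean_text("Abbey skipped rocks.")
#' clean_text("Don't stop!")
#' @export
clean_text <- function(text) {
  if (length(text) == 0) {
    return(character(0))
  }
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^a-z0-9 \t\r\n]+", "", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

as_word_seq <- function(x) {
  if (is.character(x) && length(x) == 1) clean_text(x) else as.character(x)
}

#' Built-in homophone phonetic backend
#'
#' A grapheme-to-phoneme lookup over a bundled dictionary of common English
#' homophone sets (ARPAbet pronunciations with stress digits). Words outside
#' the dictionary return `NA`, which makes [words_match()] fall back to
#' spelling comparison. Any function mapping a token to a phoneme string (or
#' `NA`) can be supplied in its place, e.g. an external g2p engine.
#'
#' @return A function `token -> phoneme string or NA`.
#' @examples
#' backend <- homophone_backend()
#' backend("wine")
#' words_match("wine", "whine", phonetic = backend)
#' @export
homophone_backend <- function() {
  dict <- homophone_dictionary()
  function(token) {
    p <- dict[[token]]
    if (is.null(p)) NA_character_ else p
  }
}

# Bundled pronunciations (ARPAbet, CMU-style stress digits) for common
# homophone sets. Not a general pronouncing dictionary: coverage is the
# homophone pairs a word scorer actually confuses.
homophone_dictionary <- function() {
  list(
    wine = "W AY1 N", whine = "W AY1 N",
    ate = "EY1 T", eight = "EY1 T",
    bare = "B EH1 R", bear = "B EH1 R",
    be = "B IY1", bee = "B IY1",
    blew = "B L UW1", blue = "B L UW1",
    brake = "B R EY1 K", "break" = "B R EY1 K",
    buy = "B AY1", by = "B AY1", bye = "B AY1",
    cell = "S EH1 L", sell = "S EH1 L",
    cent = "S EH1 N T", scent = "S EH1 N T", sent = "S EH1 N T",
    flour = "F L AW1 ER0", flower = "F L AW1 ER0",
    "for" = "F AO1 R", four = "F AO1 R", fore = "F AO1 R",
    hear = "HH IY1 R", here = "HH IY1 R",
    hole = "HH OW1 L", whole = "HH OW1 L",
    hour = "AW1 ER0", our = "AW1 ER0",
    knight = "N AY1 T", night = "N AY1 T",
    knew = "N UW1", new = "N UW1",
    know = "N OW1", no = "N OW1",
    made = "M EY1 D", maid = "M EY1 D",
    mail = "M EY1 L", male = "M EY1 L",
    meat = "M IY1 T", meet = "M IY1 T",
    one = "W AH1 N", won = "W AH1 N",
    pair = "P EH1 R", pear = "P EH1 R", pare = "P EH1 R",
    peace = "P IY1 S", piece = "P IY1 S",
    plain = "P L EY1 N", plane = "P L EY1 N",
    right = "R AY1 T", write = "R AY1 T", rite = "R AY1 T",
    road = "R OW1 D", rode = "R OW1 D",
    role = "R OW1 L", roll = "R OW1 L",
    sail = "S EY1 L", sale = "S EY1 L",
    sea = "S IY1", see = "S IY1",
    son = "S AH1 N", sun = "S AH1 N",
    steal = "S T IY1 L", steel = "S T IY1 L",
    tail = "T EY1 L", tale = "T EY1 L",
    their = "DH EH1 R", there = "DH EH1 R", theyre = "DH EH1 R",
    threw = "TH R UW1", through = "TH R UW1",
    to = "T UW1", too = "T UW1", two = "T UW1",
    wait = "W EY1 T", weight = "W EY1 T",
    waist = "W EY1 S T", waste = "W EY1 S T",
    weak = "W IY1 K", week = "W IY1 K",
    wood = "W UH1 D", would = "W UH1 D"
  )
}

# Equivalence key for a token: phoneme key (stress digits stripped) when the
# backend knows the word, otherwise its spelling. Namespaces are prefixed so
# a phoneme string can never collide with a spelling.
word_keys <- function(tokens, phonetic = NULL) {
  if (is.null(phonetic)) {
    return(paste0("s:", tokens))
  }
  vapply(tokens, function(tok) {
    p <- tryCatch(phonetic(tok), error = function(e) {
      warning("phonetic backend failed on \"", tok,
              "\"; falling back to spelling", call. = FALSE)
      NA_character_
    })
    if (is.na(p) || !is.character(p) || length(p) != 1) {
      paste0("s:", tok)
    } else {
      paste0("p:", gsub("[0-9]", "", p))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Do two tokens count as the same word?
#'
#' True when the spellings are identical, or — with a phonetic backend — when
#' the phoneme sequences (lexical stress stripped) are identical, so
#' homophones like "whine"/"wine" score as correct.
#'
#' @param a,b Cleaned tokens (see [clean_text()]).
#' @param phonetic Optional backend function `token -> phoneme string or NA`,
#'   e.g. [homophone_backend()].
#' @return Logical scalar; symmetric in `a` and `b`.
#' @export
words_match <- function(a, b, phonetic = NULL) {
  if (identical(a, b)) {
    return(TRUE)
  }
  if (is.null(phonetic)) {
    return(FALSE)
  }
  keys <- word_keys(c(a, b), phonetic)
  keys[1] == keys[2]
}

score_result <- function(n_correct, n_total) {
  stopifnot(n_correct >= 0, n_correct <= n_total)
  tibble::tibble(
    n_correct = as.integer(n_correct),
    n_total = as.integer(n_total),
    percent = 100 * n_correct / n_total
  )
}

#' Order-insensitive sentence scoring
#'
#' Scores each model-result sentence against its transcript by counting
#' common words regardless of order (multiset intersection: a word repeated
#' twice in the transcript needs to appear twice in the result to count
#' twice). Totals are pooled over sentences: the percent score is total
#' correct words over total transcript words.
#'
#' @param results,transcripts Equal-length lists of word sequences (character
#'   vectors from [clean_text()]), or character vectors of raw sentences
#'   (cleaned automatically).
#' @param phonetic Optional phonetic backend for homophone-aware matching.
#' @param per_sentence Return one row per sentence instead of the pooled
#'   totals.
#' @return A tibble with `n_correct`, `n_total`, `percent` (one row, or one
#'   per sentence with a `sentence` index column).
#' @examples
#' score_sentences("Skipped Abbey rocks", "Abbey skipped rocks") # 3 of 3
#' @export
score_sentences <- function(results, transcripts, phonetic = NULL,
                            per_sentence = FALSE) {
  if (is.character(results)) results <- as.list(results)
  if (is.character(transcripts)) transcripts <- as.list(transcripts)
  if (length(results) != length(transcripts)) {
    stop("results and transcripts must have equal length", call. = FALSE)
  }
  if (length(transcripts) == 0) {
    stop("no transcripts", call. = FALSE)
  }
  rows <- purrr::map2(results, transcripts, function(r, t) {
    r <- as_word_seq(r)
    t <- as_word_seq(t)
    if (length(t) == 0) stop("empty transcript sentence", call. = FALSE)
    rk <- word_keys(r, phonetic)
    tk <- word_keys(t, phonetic)
    shared <- intersect(unique(rk), unique(tk))
    n_common <- sum(vapply(shared, function(k) {
      min(sum(rk == k), sum(tk == k))
    }, numeric(1)))
    c(n_common, length(t))
  })
  tab <- do.call(rbind, rows)
  if (per_sentence) {
    out <- score_result(tab[, 1], tab[, 2])
    return(tibble::add_column(out, sentence = seq_len(nrow(tab)), .before = 1))
  }
  score_result(sum(tab[, 1]), sum(tab[, 2]))
}

word_codes <- function(result, transcript, phonetic) {
  rk <- word_keys(result, phonetic)
  tk <- word_keys(transcript, phonetic)
  all_keys <- unique(c(rk, tk))
  list(result = match(rk, all_keys), transcript = match(tk, all_keys))
}

#' Word-list scoring with greedy alignment
#'
#' Compares a model result against a word-list transcript word by word. When
#' the lengths differ (the recognizer dropped a word, or split one word into
#' several), the longer sequence is shrunk to the transcript length by
#' iterative single-word deletion: each word of the longer sequence is
#' trial-deleted, the positional similarity of the remaining words is
#' computed, and the deletion giving the highest similarity is made permanent
#' (leftmost on ties) until lengths match. The final score counts positions
#' where the words match.
#'
#' @param result,transcript Word sequences (character vectors) or raw strings
#'   (cleaned automatically). Transcript must be non-empty.
#' @param phonetic Optional phonetic backend for homophone-aware matching.
#' @return A one-row tibble with `n_correct`, `n_total`, `percent`;
#'   `n_total` is the transcript length.
#' @examples
#' align_and_score_words("the big cat sat", "the cat sat") # 3 of 3
#' @export
align_and_score_words <- function(result, transcript, phonetic = NULL) {
  result <- as_word_seq(result)
  transcript <- as_word_seq(transcript)
  if (length(transcript) == 0) {
    stop("empty transcript", call. = FALSE)
  }
  codes <- word_codes(result, transcript, phonetic)
  n_correct <- .greedy_align_core(codes$result, codes$transcript)
  score_result(n_correct, length(transcript))
}

#' Exhaustive alignment oracle
#'
#' Enumerates every deletion set from the longer sequence that equalizes the
#' lengths and returns the maximum positional-match score. Exponential in the
#' length difference; intended as a reference check for
#' [align_and_score_words()] on small instances.
#'
#' @param result,transcript Word sequences or raw strings.
#' @param phonetic Optional phonetic backend.
#' @param max_size Refuse instances whose combined length exceeds this.
#' @return A one-row tibble with `n_correct`, `n_total`, `percent`.
#' @export
brute_force_alignment_score <- function(result, transcript, phonetic = NULL,
                                        max_size = 20) {
  result <- as_word_seq(result)
  transcript <- as_word_seq(transcript)
  if (length(transcript) == 0) {
    stop("empty transcript", call. = FALSE)
  }
  if (length(result) + length(transcript) > max_size) {
    stop("instance too large for exhaustive enumeration (",
         length(result) + length(transcript), " > ", max_size, ")",
         call. = FALSE)
  }
  codes <- word_codes(result, transcript, phonetic)
  n_correct <- .brute_align_core(codes$result, codes$transcript)
  score_result(n_correct, length(transcript))
}

#' Sweep the greedy aligner against the exhaustive oracle
#'
#' Runs [align_and_score_words()]'s greedy core and the exhaustive oracle on
#' every pair of token sequences up to a transcript length and surplus bound
#' over a small alphabet, and reports where they disagree. The greedy score
#' can never exceed the oracle; strict shortfalls (instances where greedy
#' alignment is suboptimal) are enumerated.
#'
#' @param max_transcript Longest transcript length swept.
#' @param max_surplus Largest absolute length difference swept.
#' @param alphabet Number of distinct tokens.
#' @param max_cases Cap on recorded shortfall instances.
#' @return A list with counts `n_instances`, `n_greedy_exceeds_oracle`,
#'   `n_shortfalls`, and a tibble `shortfalls` of recorded cases.
#' @export
alignment_sweep <- function(max_transcript = 6, max_surplus = 2, alphabet = 3,
                            max_cases = 1000) {
  raw <- .alignment_sweep_core(as.integer(max_transcript),
                               as.integer(max_surplus),
                               as.integer(alphabet),
                               as.integer(max_cases))
  list(
    n_instances = raw$n_instances,
    n_greedy_exceeds_oracle = raw$n_greedy_exceeds_oracle,
    n_shortfalls = raw$n_shortfalls,
    shortfalls = tibble::tibble(
      result = raw$shortfall_result,
      transcript = raw$shortfall_transcript,
      greedy = raw$shortfall_greedy,
      oracle = raw$shortfall_oracle
    )
  )
}
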