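# Text preprocessing for assay descriptions: tokenization, stop-word
# removal, and Porter stemming. No external NLP dependency is used; the
# stemmer is a direct implementation of Porter's 1980 suffix-stripping
# algorithm.

#' Default assay-specific stop words
#'
#' Generic assay vocabulary that carries no discriminative information about
#' the experiment type (it occurs in descriptions of almost every assay
#' class). This list is configuration, not ground truth: callers working with
#' a particular corpus are expected to extend or replace it.
#'
#' @return Character vector of lowercase stop words.
#' @export
assay_stopwords <- function() {
  c("assay", "assays", "human", "activity", "compound", "compounds",
    "inhibition", "effect", "cells", "evaluated", "against", "tested",
    "using", "based", "determined")
}

#' Tokenize a free-text description
#'
#' Lowercases the text and extracts maximal alphanumeric runs, dropping runs
#' shorter than two characters. Digits are kept as token characters:
#' radioligand labels such as `[3H]` or `[125I]` and compound codes such as
#' `CGS21680` are informative assay vocabulary.
#'
#' @param text Character scalar (may be empty).
#' @return Character vector of tokens in order of appearance, possibly empty.
#' @export
tokenize_description <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
  toks[nchar(toks) >= 2L]
}

# ---- Porter stemmer ---------------------------------------------------------
# Straight transcription of the 1980 algorithm. Words are lowercase ASCII;
# tokens containing digits pass through unchanged (the measure/condition
# machinery is defined over letters only).

.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of a stem: number of VC sequences in [C](VC){m}[V]
.p_measure <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(0L)
  flags <- vapply(seq_len(n), function(i) .p_is_cons(chars, i), logical(1))
  m <- 0L
  prev_vowel <- FALSE
  for (i in seq_len(n)) {
    if (flags[i]) {
      if (prev_vowel) m <- m + 1L
      prev_vowel <- FALSE
    } else prev_vowel <- TRUE
  }
  m
}

.p_has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) .p_is_cons(chars, i), logical(1)))
}

.p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  chars[n] == chars[n - 1L] && .p_is_cons(chars, n)
}

# *o condition: stem ends consonant-vowel-consonant, final not w, x or y
.p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  .p_is_cons(chars, n - 2L) && !.p_is_cons(chars, n - 1L) &&
    .p_is_cons(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  nc <- nchar(word); ns <- nchar(suffix)
  nc > ns && substring(word, nc - ns + 1L, nc) == suffix
}

.p_stem_part <- function(word, suffix) {
  substring(word, 1L, nchar(word) - nchar(suffix))
}

# Apply the first matching rule of a step-2/3/4 style table: rows are
# (suffix, replacement); cond takes the stem and returns TRUE to fire.
.p_rule_table <- function(word, rules, cond) {
  for (k in seq_len(nrow(rules))) {
    suf <- rules[k, 1L]
    if (.p_ends(word, suf)) {
      stem <- .p_stem_part(word, suf)
      if (cond(stem)) return(paste0(stem, rules[k, 2L]))
      return(word)  # longest matching suffix decides, fire or not
    }
  }
  word
}

.p_step1a <- function(w) {
  if (.p_ends(w, "sses")) return(paste0(.p_stem_part(w, "sses"), "ss"))
  if (.p_ends(w, "ies"))  return(paste0(.p_stem_part(w, "ies"), "i"))
  if (.p_ends(w, "ss"))   return(w)
  if (.p_ends(w, "s"))    return(.p_stem_part(w, "s"))
  w
}

.p_step1b <- function(w) {
  if (.p_ends(w, "eed")) {
    stem <- .p_stem_part(w, "eed")
    if (.p_measure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  fired <- FALSE
  if (.p_ends(w, "ed") && .p_has_vowel(.p_stem_part(w, "ed"))) {
    w <- .p_stem_part(w, "ed"); fired <- TRUE
  } else if (.p_ends(w, "ing") && .p_has_vowel(.p_stem_part(w, "ing"))) {
    w <- .p_stem_part(w, "ing"); fired <- TRUE
  }
  if (fired) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !(substring(w, nchar(w)) %in% c("l", "s", "z"))) {
      w <- substring(w, 1L, nchar(w) - 1L)
    } else if (.p_measure(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.p_step1c <- function(w) {
  if (.p_ends(w, "y") && .p_has_vowel(.p_stem_part(w, "y")))
    return(paste0(.p_stem_part(w, "y"), "i"))
  w
}

.p_step2_rules <- matrix(c(
  "ational", "ate", "tional", "tion", "enci", "ence", "anci", "ance",
  "izer", "ize", "abli", "able", "alli", "al", "entli", "ent", "eli", "e",
  "ousli", "ous", "ization", "ize", "ation", "ate", "ator", "ate",
  "alism", "al", "iveness", "ive", "fulness", "ful", "ousness", "ous",
  "aliti", "al", "iviti", "ive", "biliti", "ble"
), ncol = 2L, byrow = TRUE)

.p_step3_rules <- matrix(c(
  "icate", "ic", "ative", "", "alize", "al", "iciti", "ic",
  "ical", "ic", "ful", "", "ness", ""
), ncol = 2L, byrow = TRUE)

.p_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.p_step4 <- function(w) {
  # longest matching suffix decides
  hits <- .p_step4_suffixes[vapply(.p_step4_suffixes, .p_ends,
                                   logical(1), word = w)]
  if (length(hits) == 0L) return(w)
  suf <- hits[which.max(nchar(hits))]
  stem <- .p_stem_part(w, suf)
  if (.p_measure(stem) <= 1L) return(w)
  if (suf == "ion" && !(substring(stem, nchar(stem)) %in% c("s", "t")))
    return(w)
  stem
}

.p_step5 <- function(w) {
  if (.p_ends(w, "e")) {
    stem <- .p_stem_part(w, "e")
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }
  if (.p_measure(substring(w, 1L, nchar(w) - 1L)) > 1L && .p_double_cons(w) &&
      substring(w, nchar(w)) == "l")
    w <- substring(w, 1L, nchar(w) - 1L)
  w
}

#' Porter stem of a single token
#'
#' Suffix-stripping stemmer after Porter (1980). Tokens shorter than three
#' characters and tokens containing non-letter characters (digit-bearing
#' codes such as `3h` or `cgs21680`) are returned unchanged.
#'
#' @param word Lowercase token.
#' @return The stemmed token.
#' @export
porter_stem <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  w <- .p_step1a(word)
  w <- .p_step1b(w)
  w <- .p_step1c(w)
  w <- .p_rule_table(w, .p_step2_rules, function(s) .p_measure(s) > 0L)
  w <- .p_rule_table(w, .p_step3_rules, function(s) .p_measure(s) > 0L)
  w <- .p_step4(w)
  .p_step5(w)
}

# memoised vectorized stemming over a token vector
.stem_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  uniq <- unique(tokens)
  stems <- vapply(uniq, porter_stem, character(1), USE.NAMES = TRUE)
  unname(stems[tokens])
}

#' Preprocess an assay description into tokens
#'
#' Pipeline: lowercase, tokenize into maximal alphanumeric runs of length at
#' least two, remove stop words (both the general English list and the
#' assay-specific list, matched on the unstemmed surface form), then Porter-stem
#' each surviving token. Order and duplicates are preserved.
#'
#' @param text Character scalar.
#' @param language_stopwords Character vector of general-language stop words;
#'   defaults to [english_stopwords()].
#' @param assay_stopwords Character vector of corpus-specific stop words;
#'   defaults to [assay_stopwords()].
#' @return Character vector of stemmed tokens (possibly empty).
#' @export
preprocess_description <- function(text,
                                   language_stopwords = english_stopwords(),
                                   assay_stopwords = assaycontext::assay_stopwords()) {
  toks <- tokenize_description(text)
  toks <- toks[!(toks %in% language_stopwords) & !(toks %in% assay_stopwords)]
  .stem_tokens(toks)
}

# Preprocess many descriptions at once, memoising on the unique strings.
.preprocess_many <- function(texts, language_stopwords = english_stopwords(),
                             assay_stopwords = assaycontext::assay_stopwords()) {
  uniq <- unique(texts)
  toklist <- lapply(uniq, preprocess_description,
                    language_stopwords = language_stopwords,
                    assay_stopwords = assay_stopwords)
  names(toklist) <- uniq
  toklist[texts]
}
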