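#' Default English stop-word list
#'
#' Reads the stop-word list shipped with the package (one token per line,
#' UTF-8), or a custom list in the same format.
#'
#' @param path optional path to a custom list.
#' @return character vector of stop words (lower case).
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "peersuggest")
  }
  sw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tolower(trimws(sw[nzchar(trimws(sw))]))
}

#' Split text into sentences of filtered content tokens
#'
#' Sentences are split on terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace and an upper-case letter, digit or quote (a configurable
#' abbreviation list suppresses false splits). Tokens are lower-cased word
#' characters; stop words are removed. When a part-of-speech tagger is
#' supplied only the word classes in `keep_classes` are retained; with the
#' default null tagger, stop-word filtering alone applies.
#'
#' @param text a character scalar.
#' @param stopwords character vector of stop words ([load_stopwords()] by
#'   default).
#' @param tagger `NULL` (null tagger) or a function `f(tokens)` returning one
#'   part-of-speech label per token, using labels `"noun"`, `"adjective"`,
#'   `"verb"`, `"other"`.
#' @param keep_classes word classes kept when `tagger` is supplied.
#' @param abbreviations tokens after which a period never ends a sentence.
#' @return Object of class `sentence_set`: a list of character vectors, one
#'   per sentence (possibly empty after filtering; empty text gives an empty
#'   set).
#' @export
split_and_filter <- function(text, stopwords = load_stopwords(),
                             tagger = NULL,
                             keep_classes = c("noun", "adjective", "verb"),
                             abbreviations = c("e.g", "i.e", "et al", "fig",
                                               "vs", "cf", "approx")) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(), class = "sentence_set"))
  }
  sentences <- split_sentences(text, abbreviations)
  out <- lapply(sentences, function(s) {
    toks <- tokenize_words(s)
    if (!is.null(tagger) && length(toks)) {
      tags <- tagger(toks)
      toks <- toks[tags %in% keep_classes]
    }
    toks[!toks %in% stopwords]
  })
  out <- out[vapply(out, length, 0L) > 0L]
  structure(out, class = "sentence_set")
}

split_sentences <- function(text, abbreviations = character()) {
  text <- gsub("\\s+", " ", trimws(text))
  # protect known abbreviations so their trailing period does not split
  for (ab in abbreviations) {
    text <- gsub(paste0("(?i)\\b", gsub("\\.", "\\\\.", ab), "\\."),
                 gsub("\\.", "\x01", paste0(ab, ".")), text, perl = TRUE)
  }
  parts <- strsplit(text, "(?<=[.!?])\\s+(?=[\"'(]?[A-Z0-9])",
                    perl = TRUE)[[1L]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts[nzchar(trimws(parts))]
}

tokenize_words <- function(s) {
  toks <- regmatches(s, gregexpr("[[:alpha:]][[:alnum:]'-]*", s))[[1L]]
  toks <- gsub("['-]+$", "", tolower(toks))
  toks[nzchar(toks)]
}

# binary sentence-term incidence matrix (sentences x unique terms)
incidence_matrix <- function(sentence_set) {
  terms <- sort(unique(unlist(sentence_set, use.names = FALSE)))
  if (length(terms) == 0L) {
    return(matrix(0, nrow = 0L, ncol = 0L))
  }
  m <- matrix(0, nrow = length(sentence_set), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_along(sentence_set)) {
    m[i, unique(sentence_set[[i]])] <- 1
  }
  m
}

#' Fuzzy co-occurrence relation strength between terms
#'
#' A graded pairwise association derived from co-occurrence within
#' sentences: with `s(i)` the number of sentences containing term `i` and
#' `s(i,j)` the number containing both, the relation strength is
#' `mu(i,j) = s(i,j)^2 / (s(i) * s(j))`. It is symmetric, lies in `[0, 1]`,
#' equals 1 when two terms always co-occur, and 0 when they never do.
#'
#' @param sentence_set a [split_and_filter()] result.
#' @return Symmetric numeric matrix of relation strengths with terms as
#'   dimnames (diagonal set to 0).
#' @export
relation_strength <- function(sentence_set) {
  m <- incidence_matrix(sentence_set)
  if (ncol(m) == 0L) {
    return(matrix(0, 0L, 0L))
  }
  joint <- crossprod(m)            # s(i,j), diagonal s(i)
  s <- diag(joint)
  mu <- joint^2 / outer(s, s)
  diag(mu) <- 0
  mu
}

#' Keyword scores for the terms of a text
#'
#' A term's raw score is the sum of its relation strengths to all other
#' terms ([relation_strength()]); the more and stronger relations a word
#' has, the higher its score. Scores are normalized by the maximum raw
#' score, so the best-connected term scores 1 whenever any pair of terms
#' co-occurs; a text with no co-occurring pairs scores all terms 0.
#'
#' @inheritParams relation_strength
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
keyword_scores <- function(sentence_set) {
  mu <- relation_strength(sentence_set)
  if (ncol(mu) == 0L) {
    return(setNames(numeric(), character()))
  }
  r <- rowSums(mu)
  mx <- max(r)
  if (mx == 0) r else r / mx
}

#' Extract a bounded, thresholded keyword profile from text
#'
#' Composes [split_and_filter()] and [keyword_scores()], keeping at most
#' `max_terms` terms with score strictly greater than `min_score`, sorted by
#' descending score and then lexicographically. A too-short text that yields
#' no co-occurring content words produces an empty profile.
#'
#' @inheritParams split_and_filter
#' @param max_terms maximum number of keywords retained (default 50).
#' @param min_score strict lower bound on retained scores (default 0.05).
#' @return Object of class `keyword_profile`: data.frame with columns
#'   `term`, `score`, plus attributes `max_terms`, `min_score`.
#' @export
extract_keywords <- function(text, max_terms = 50L, min_score = 0.05,
                             stopwords = load_stopwords(), tagger = NULL) {
  ss <- split_and_filter(text, stopwords = stopwords, tagger = tagger)
  k <- keyword_scores(ss)
  k <- k[k > min_score]
  ord <- order(-k, names(k))
  k <- k[ord][seq_len(min(length(k), max_terms))]
  structure(data.frame(term = names(k), score = unname(k),
                       stringsAsFactors = FALSE),
            max_terms = max_terms, min_score = min_score,
            class = c("keyword_profile", "data.frame"))
}
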