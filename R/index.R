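#' Build an inverted index over expert profiles
#'
#' @param store named list of `expert_profile` objects (see
#'   [build_profile_store()]); must be non-empty with unique author ids.
#' @return Object of class `expert_index`: `postings` (term -> data.frame
#'   of `author_id`, `tf`), `doc_freq` (term -> number of profiles
#'   containing it), `n_docs`, `doc_len` (author_id -> total filtered token
#'   count).
#' @export
build_index <- function(store) {
  if (length(store) == 0L) stop("empty profile store")
  ids <- vapply(store, `[[`, "", "author_id")
  if (anyDuplicated(ids)) {
    stop("duplicate author_id in profile store: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ord <- order(ids)
  store <- store[ord]
  ids <- ids[ord]
  term_v <- unlist(lapply(store, function(p) names(p$term_counts)),
                   use.names = FALSE)
  tf_v <- unlist(lapply(store, function(p) unname(p$term_counts)),
                 use.names = FALSE)
  id_v <- rep(ids, times = vapply(store, function(p) length(p$term_counts),
                                  0L))
  postings <- split(data.frame(author_id = id_v, tf = tf_v,
                               stringsAsFactors = FALSE), term_v)
  doc_len <- setNames(vapply(store, function(p) sum(p$term_counts), 0),
                      ids)
  structure(list(postings = postings,
                 doc_freq = vapply(postings, nrow, 0L),
                 n_docs = length(store),
                 doc_len = doc_len),
            class = "expert_index")
}

#' @export
print.expert_index <- function(x, ...) {
  cat("expert_index:", x$n_docs, "profiles,", length(x$postings),
      "distinct terms\n")
  invisible(x)
}

# inverse document frequency with a small positive floor so that rare-term
# matches can never be cancelled by negative contributions on tiny corpora
idf <- function(index, terms, floor = 1e-6) {
  df <- index$doc_freq[terms]
  df[is.na(df)] <- 0L
  pmax(1 + log(index$n_docs / (df + 1)), floor)
}

#' TF-IDF similarity between a keyword profile and one expert
#'
#' Practical TF-IDF scoring in the style of classic retrieval libraries:
#' `score = coord * sum_t w_q(t) * idf(t)^2 * sqrt(tf(t, d)) * norm(d)`
#' over the terms shared by the query and the profile, with
#' `idf(t) = 1 + ln(n_docs / (doc_freq(t) + 1))` floored at a small positive
#' value, `norm(d) = 1 / sqrt(doc_len(d))`, coordination factor
#' `coord = |overlap| / |query|`, and `w_q(t)` the query keyword score.
#'
#' @param query a [extract_keywords()] profile (columns `term`, `score`).
#' @param author_id an indexed author id.
#' @param index an [build_index()] result.
#' @return Non-negative numeric score; 0 iff no term overlaps.
#' @export
score_expert <- function(query, author_id, index) {
  if (!author_id %in% names(index$doc_len)) {
    stop("author_id not indexed: ", author_id)
  }
  if (nrow(query) == 0L) return(0)
  tf <- vapply(query$term, function(t) {
    p <- index$postings[[t]]
    if (is.null(p)) return(0)
    i <- match(author_id, p$author_id)
    if (is.na(i)) 0 else p$tf[i]
  }, 0)
  hit <- tf > 0
  if (!any(hit)) return(0)
  w <- query$score[hit]
  id2 <- idf(index, query$term[hit])^2
  coord <- sum(hit) / nrow(query)
  coord * sum(w * id2 * sqrt(tf[hit])) / sqrt(index$doc_len[[author_id]])
}

#' Read a journal-to-subject map
#'
#' TSV with two columns (`journal_id`, `subject`), one pair per line, no
#' header.
#'
#' @param path file path.
#' @return Named list: journal_id -> character vector of subject labels.
#' @export
read_subject_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("journal_id", "subject"),
                   colClasses = "character")
  lapply(split(df$subject, df$journal_id), unique)
}

#' Rank candidate peer reviewers for a keyword profile
#'
#' Scores every indexed profile against the query with [score_expert()] and
#' returns the `top_k` best, ties broken by author id. When `subjects` are
#' given, candidates are first restricted to authors having at least one
#' citation in a journal mapped to any selected subject; scores are still
#' computed with document frequencies from the full index, so a surviving
#' author's score is identical with and without the filter.
#'
#' @inheritParams score_expert
#' @param store the profile store backing the index (journal metadata and
#'   display keywords come from it).
#' @param top_k number of results to return (default 20).
#' @param subjects optional character vector of subject labels.
#' @param subject_map required with `subjects`: journal_id -> subjects
#'   ([read_subject_map()]).
#' @param n_keywords how many profile terms (by tf-idf) to display per hit.
#' @return data.frame of class `ranked_experts`: `rank`, `author_id`,
#'   `score`, `name_key`, `anchor_coauthor`, `n_refs`, `keywords`
#'   (semicolon-joined top profile terms).
#' @export
search_experts <- function(query, index, store, top_k = 20L,
                           subjects = NULL, subject_map = NULL,
                           n_keywords = 10L) {
  if (nrow(query) == 0L) {
    stop("no keywords: the query text did not yield any scored terms")
  }
  store <- setNames(store, vapply(store, `[[`, "", "author_id"))
  candidates <- names(index$doc_len)
  if (!is.null(subjects)) {
    if (is.null(subject_map)) stop("subject filtering requires subject_map")
    ok_journals <- names(subject_map)[vapply(subject_map, function(s)
      any(s %in% subjects), logical(1L))]
    candidates <- candidates[vapply(candidates, function(id)
      any(store[[id]]$journals %in% ok_journals), logical(1L))]
  }
  scores <- vapply(candidates, score_expert, 0, query = query, index = index)
  ord <- order(-scores, candidates)
  top <- head(ord, top_k)
  res <- data.frame(
    rank = seq_along(top),
    author_id = candidates[top],
    score = unname(scores[top]),
    name_key = vapply(candidates[top], function(id) store[[id]]$name_key, ""),
    anchor_coauthor = vapply(candidates[top], function(id)
      store[[id]]$anchor_coauthor %||% NA_character_, ""),
    n_refs = vapply(candidates[top], function(id) store[[id]]$n_refs, 0L),
    keywords = vapply(candidates[top], function(id)
      paste(display_keywords(store[[id]], index, n_keywords),
            collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("ranked_experts", "data.frame")
  res
}

#' Most relevant keywords of an expert profile
#'
#' Top profile terms ranked by tf*idf against the index, ties broken
#' lexicographically.
#'
#' @param profile an `expert_profile`.
#' @param index the [build_index()] the profile is indexed in.
#' @param n number of terms.
#' @return character vector of terms.
#' @export
display_keywords <- function(profile, index, n = 10L) {
  tc <- profile$term_counts
  if (length(tc) == 0L) return(character())
  w <- tc * idf(index, names(tc))
  ord <- order(-w, names(w))
  names(w)[head(ord, n)]
}

#' Journal table for a result set
#'
#' Counts, for each journal, how many of the returned top experts have
#' published there (an author publishing in several journals counts once in
#' each).
#'
#' @param results a [search_experts()] result.
#' @param store the backing profile store.
#' @return data.frame with columns `journal_id`, `n_experts`, sorted by
#'   descending count then journal id.
#' @export
journal_table <- function(results, store) {
  if (nrow(results) == 0L) stop("empty result set")
  store <- setNames(store, vapply(store, `[[`, "", "author_id"))
  ji <- unlist(lapply(results$author_id, function(id)
    unique(store[[id]]$journals)), use.names = FALSE)
  tab <- table(ji)
  df <- data.frame(journal_id = names(tab), n_experts = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$n_experts, df$journal_id), , drop = FALSE]
}
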