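#' Eligibility of a disambiguated author for expertise profiling
#'
#' An identity is profiled only if at least one attributed citation has the
#' identity's name key in first or last author position, a publication year
#' inside `[year_min, year_max]` (bounds inclusive), and a journal in
#' `journal_set`. An empty `journal_set` means no journal restriction. A
#' single-author paper counts as both first and last authored.
#'
#' @param author a `disambiguated_author` (see [disambiguate_name()]).
#' @param corpus the [citation_corpus()] the author's pmids resolve in.
#' @param journal_set character vector of admissible journal ids (empty =
#'   all).
#' @param year_min,year_max inclusive publication-year window (defaults
#'   2000-2010).
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(author, corpus, journal_set = character(),
                        year_min = 2000L, year_max = 2010L) {
  cts <- resolve_citations(author, corpus)
  any(vapply(cts, function(ct) {
    pos_ok <- ct$authors[1L] == author$name_key ||
      ct$authors[length(ct$authors)] == author$name_key
    year_ok <- !is.na(ct$year) && ct$year >= year_min && ct$year <= year_max
    journal_ok <- length(journal_set) == 0L || ct$journal_id %in% journal_set
    pos_ok && year_ok && journal_ok
  }, logical(1L)))
}

resolve_citations <- function(author, corpus) {
  missing <- setdiff(author$pmids, names(corpus$citations))
  if (length(missing)) {
    stop("author ", author$author_id, " references unknown pmid(s): ",
         paste(missing, collapse = ", "))
  }
  corpus$citations[author$pmids]
}

#' Build the expertise profile of a disambiguated author
#'
#' Concatenates the abstracts of the author's attributed citations and
#' tokenizes them under the same filtering contract as
#' [split_and_filter()] — with a part-of-speech tagger the profile keeps
#' nouns only; with the null tagger all non-stop words are kept, so query
#' and profile vocabularies stay symmetric. Term counts are raw occurrence
#' counts. Citations without an abstract contribute nothing to the counts
#' but still contribute their journal and year.
#'
#' @inheritParams is_eligible
#' @param stopwords stop-word vector ([load_stopwords()] by default).
#' @param tagger `NULL` or a part-of-speech tagger (see
#'   [split_and_filter()]); when supplied, only nouns are kept.
#' @return Object of class `expert_profile`: `author_id`, `name_key`,
#'   `anchor_coauthor`, `term_counts` (named integer), `n_abstracts`,
#'   `n_refs`, `journals`, `years`, `indexable` (`FALSE` when every abstract
#'   is empty).
#' @export
build_expert_profile <- function(author, corpus,
                                 stopwords = load_stopwords(),
                                 tagger = NULL) {
  cts <- resolve_citations(author, corpus)
  abstracts <- vapply(cts, function(ct) ct$abstract %||% "", "")
  has_abs <- nzchar(trimws(abstracts))
  ss <- split_and_filter(paste(abstracts[has_abs], collapse = " "),
                         stopwords = stopwords, tagger = tagger,
                         keep_classes = "noun")
  toks <- unlist(ss, use.names = FALSE)
  counts <- if (length(toks)) {
    tab <- table(toks)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(), character())
  structure(list(author_id = author$author_id,
                 name_key = author$name_key,
                 anchor_coauthor = author$anchor_coauthor,
                 term_counts = counts,
                 n_abstracts = sum(has_abs),
                 n_refs = length(author$pmids),
                 journals = sort(unique(vapply(cts, `[[`, "", "journal_id"))),
                 years = sort(unique(vapply(cts, `[[`, 0L, "year"))),
                 indexable = length(counts) > 0L),
            class = "expert_profile")
}

#' Build the profile store for every eligible disambiguated author
#'
#' Applies the eligibility filter then [build_expert_profile()] to each
#' identity; unindexable profiles (all abstracts empty) are dropped.
#'
#' @param disambiguated output of [disambiguate_corpus()].
#' @inheritParams build_expert_profile
#' @inheritParams is_eligible
#' @return Named list of `expert_profile` objects keyed by `author_id`.
#' @export
build_profile_store <- function(disambiguated, corpus,
                                journal_set = character(),
                                year_min = 2000L, year_max = 2010L,
                                stopwords = load_stopwords(),
                                tagger = NULL) {
  flat <- unlist(disambiguated, recursive = FALSE, use.names = FALSE)
  elig <- Filter(function(a) is_eligible(a, corpus, journal_set,
                                         year_min, year_max), flat)
  profs <- lapply(elig, build_expert_profile, corpus = corpus,
                  stopwords = stopwords, tagger = tagger)
  profs <- Filter(function(p) p$indexable, profs)
  setNames(profs, vapply(profs, `[[`, "", "author_id"))
}

#' Write / read a profile store as line-delimited JSON
#'
#' One JSON object per line: `author_id`, `name_key`, `anchor_coauthor`,
#' `n_abstracts`, `n_refs`, `journals`, `years`, `term_counts`.
#'
#' @param store named list of `expert_profile` objects.
#' @param path file path.
#' @return `write_profile_store()`: `path` invisibly;
#'   `read_profile_store()`: the store.
#' @export
write_profile_store <- function(store, path) {
  lines <- vapply(store, function(p) {
    anchor <- if (is.na(p$anchor_coauthor)) "" else p$anchor_coauthor
    jsonlite::toJSON(list(author_id = p$author_id, name_key = p$name_key,
                          anchor_coauthor = anchor,
                          n_abstracts = p$n_abstracts, n_refs = p$n_refs,
                          journals = p$journals, years = p$years,
                          term_counts = as.list(p$term_counts)),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_profile_store
#' @export
read_profile_store <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  profs <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    tc <- unlist(r$term_counts)
    structure(list(author_id = r$author_id, name_key = r$name_key,
                   anchor_coauthor = if (is.null(r$anchor_coauthor) ||
                                         !nzchar(r$anchor_coauthor))
                     NA_character_ else r$anchor_coauthor,
                   term_counts = setNames(as.integer(tc), names(tc)),
                   n_abstracts = as.integer(r$n_abstracts),
                   n_refs = as.integer(r$n_refs),
                   journals = as.character(r$journals),
                   years = as.integer(r$years),
                   indexable = length(tc) > 0L),
              class = "expert_profile")
  })
  setNames(profs, vapply(profs, `[[`, "", "author_id"))
}
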