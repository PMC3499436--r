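#' Coauthor frequencies for a name within a citation subset
#'
#' Counts, for every other name key, the number of citations in `citations`
#' in which it co-occurs with `key`. A coauthor is counted at most once per
#' citation; `key` itself is excluded.
#'
#' @param key a name key (`"lastname_initials"`).
#' @param citations list of citation records, each listing `key` as an author.
#' @return Named integer vector of counts (empty for an empty subset).
#' @export
coauthor_frequencies <- function(key, citations) {
  co <- unlist(lapply(citations, function(ct) {
    a <- unique(ct$authors)
    if (!key %in% a) {
      stop("citation ", ct$pmid, " does not list name key '", key, "'")
    }
    setdiff(a, key)
  }), use.names = FALSE)
  if (length(co) == 0L) {
    return(setNames(integer(), character()))
  }
  tab <- table(co)
  setNames(as.integer(tab), names(tab))
}

#' Disambiguate one author name into identities by recurrent coauthors
#'
#' Partitions the citations bearing one name key into disambiguated author
#' identities with a greedy loop: find the most frequent coauthor among the
#' remaining citations; while that maximum count is at least `min_repeat`,
#' emit an identity anchored to the winning coauthor, containing exactly the
#' remaining citations that include it, and remove them. Frequencies are
#' re-counted over the remainder at every step. Leftover citations become
#' singleton identities, one each. Ties among equally frequent coauthors are
#' broken lexicographically, so the output is a pure function of the
#' citation set.
#'
#' @param key the name key to disambiguate.
#' @param corpus a [citation_corpus()].
#' @param min_repeat minimum coauthor recurrence to anchor an identity
#'   (default 2).
#' @param drop_single_author if `TRUE`, citations whose author list is just
#'   `key` are dropped entirely instead of becoming singletons.
#' @return List of `disambiguated_author` objects: `author_id` (key + `"#"` +
#'   zero-padded ordinal), `name_key`, `anchor_coauthor` (`NA` for
#'   singletons), `pmids` (sorted), `is_singleton`.
#' @export
disambiguate_name <- function(key, corpus, min_repeat = 2L,
                              drop_single_author = FALSE) {
  stopifnot(inherits(corpus, "citation_corpus"))
  pmids <- corpus$name_index[[key]]
  if (is.null(pmids)) stop("unknown name key: '", key, "'")
  remaining <- sort(unique(pmids))
  if (drop_single_author) {
    multi <- vapply(corpus$citations[remaining],
                    function(ct) length(unique(ct$authors)) > 1L, logical(1L))
    remaining <- remaining[multi]
  }
  profiles <- list()
  repeat {
    freq <- coauthor_frequencies(key, corpus$citations[remaining])
    if (length(freq) == 0L || max(freq) < min_repeat) break
    winners <- names(freq)[freq == max(freq)]
    anchor <- sort(winners)[1L]
    hit <- vapply(corpus$citations[remaining],
                  function(ct) anchor %in% ct$authors, logical(1L))
    profiles[[length(profiles) + 1L]] <-
      list(anchor = anchor, pmids = remaining[hit])
    remaining <- remaining[!hit]
  }
  for (p in remaining) {
    profiles[[length(profiles) + 1L]] <- list(anchor = NA_character_,
                                              pmids = p)
  }
  lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    structure(list(author_id = sprintf("%s#%03d", key, i),
                   name_key = key,
                   anchor_coauthor = pr$anchor,
                   pmids = pr$pmids,
                   is_singleton = is.na(pr$anchor)),
              class = "disambiguated_author")
  })
}

#' @export
print.disambiguated_author <- function(x, ...) {
  cat(x$author_id, if (x$is_singleton) "(singleton)" else
      paste0("anchor=", x$anchor_coauthor),
      paste0(length(x$pmids), " refs\n"))
  invisible(x)
}

#' Disambiguate every author name in a corpus
#'
#' Applies [disambiguate_name()] independently to each name key. The result
#' is deterministic regardless of the corpus record order.
#'
#' @inheritParams disambiguate_name
#' @return Named list (one entry per name key, keys sorted) of lists of
#'   `disambiguated_author` objects.
#' @export
disambiguate_corpus <- function(corpus, min_repeat = 2L,
                                drop_single_author = FALSE) {
  keys <- sort(names(corpus$name_index))
  setNames(lapply(keys, disambiguate_name, corpus = corpus,
                  min_repeat = min_repeat,
                  drop_single_author = drop_single_author), keys)
}

#' Flatten disambiguation results to a data.frame / TSV
#'
#' @param result output of [disambiguate_corpus()] (or a list of
#'   `disambiguated_author`).
#' @param path optional path; when given, the table is written as TSV.
#' @return data.frame with columns `author_id`, `name_key`,
#'   `anchor_coauthor`, `n_refs`, `pmids` (comma-joined).
#' @export
authors_table <- function(result, path = NULL) {
  flat <- if (length(result) && inherits(result[[1L]], "disambiguated_author"))
    result else unlist(result, recursive = FALSE, use.names = FALSE)
  df <- data.frame(
    author_id = vapply(flat, `[[`, "", "author_id"),
    name_key = vapply(flat, `[[`, "", "name_key"),
    anchor_coauthor = vapply(flat, `[[`, "", "anchor_coauthor"),
    n_refs = vapply(flat, function(a) length(a$pmids), 0L),
    pmids = vapply(flat, function(a) paste(a$pmids, collapse = ","), ""),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
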