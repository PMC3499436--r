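#' Normalize raw author strings into name keys
#'
#' MEDLINE identifies an author mention as "last name_initials"; many distinct
#' people share one such key. This function maps a raw author string in
#' MEDLINE style (e.g. `"Garcia-Abadillo MA"`) to that key space: the last
#' name is lower-cased and diacritic-folded (combining marks dropped, hyphens
#' and apostrophes kept), the initials are lower-cased. An input that is
#' already a key (contains `"_"`) round-trips unchanged, so normalization is
#' idempotent.
#'
#' The final whitespace token is taken as the initials when it is 1-3
#' upper-case letters; otherwise (collective/group authors, suffix tokens
#' such as "Jr") the whole string becomes the last-name token and the
#' initials are empty.
#'
#' @param x character vector of raw author strings or name keys.
#' @return A data.frame with one row per input and columns `last_name`,
#'   `initials`, `key` (`key == paste(last_name, initials, sep = "_")`).
#' @examples
#' normalize_name("Garcia-Abadillo MA")$key  # "garcia-abadillo_ma"
#' normalize_name("Müller J")$key       # "muller_j"
#' @export
normalize_name <- function(x) {
  if (length(x) == 0L) {
    return(data.frame(last_name = character(), initials = character(),
                      key = character(), stringsAsFactors = FALSE))
  }
  x <- trimws(x)
  if (any(is.na(x) | x == "")) {
    stop("malformed author record: empty or missing author string")
  }
  one <- function(s) {
    if (grepl("_", s, fixed = TRUE)) {
      # already in key space: split at the last underscore
      pos <- max(gregexpr("_", s, fixed = TRUE)[[1L]])
      last <- substr(s, 1L, pos - 1L)
      init <- substr(s, pos + 1L, nchar(s))
    } else {
      toks <- strsplit(s, "\\s+")[[1L]]
      n <- length(toks)
      if (n >= 2L && grepl("^[A-Z]{1,3}$", toks[n])) {
        last <- paste(toks[-n], collapse = " ")
        init <- toks[n]
      } else {
        last <- paste(toks, collapse = " ")
        init <- ""
      }
    }
    c(fold_name_token(last), fold_name_token(init))
  }
  m <- vapply(x, one, character(2L), USE.NAMES = FALSE)
  last <- m[1L, ]
  init <- m[2L, ]
  if (any(last == "")) stop("malformed author record: empty last name")
  data.frame(last_name = last, initials = init,
             key = paste(last, init, sep = "_"), stringsAsFactors = FALSE)
}

# lower-case, fold diacritics to base letters, keep letters/digits and
# intra-name hyphens/apostrophes/spaces
fold_name_token <- function(s) {
  s <- stringi::stri_trans_general(tolower(s), "Latin-ASCII")
  s <- gsub("[^a-z0-9' -]", "", s)
  gsub("\\s+", " ", trimws(s))
}

#' Name keys for raw author strings
#'
#' @param x character vector of raw author strings.
#' @return character vector of `"lastname_initials"` keys.
#' @export
name_key <- function(x) normalize_name(x)$key

new_citation <- function(pmid, title, abstract, authors, journal_id, year) {
  structure(list(pmid = pmid, title = title, abstract = abstract,
                 authors = authors, journal_id = journal_id,
                 year = as.integer(year)),
            class = "citation")
}

#' Construct a citation corpus
#'
#' A corpus holds bibliographic records plus an inverted name index
#' (name key -> pmids) used by the disambiguation stage. Author strings are
#' normalized with [normalize_name()]; record order is preserved but none of
#' the downstream algorithms depend on it.
#'
#' @param citations list of citation records (each a list with fields `pmid`,
#'   `title`, `abstract`, `authors` (raw strings or keys), `journal_id`,
#'   `year`).
#' @return An object of class `citation_corpus` with elements `citations`
#'   (named by pmid) and `name_index` (named list of pmid vectors).
#' @export
citation_corpus <- function(citations) {
  pmids <- vapply(citations, function(ct) as.character(ct$pmid), "")
  if (anyDuplicated(pmids)) {
    stop("duplicate PMID in corpus: ",
         paste(unique(pmids[duplicated(pmids)]), collapse = ", "))
  }
  citations <- lapply(citations, function(ct) {
    if (length(ct$authors) < 1L) stop("citation ", ct$pmid, " has no authors")
    new_citation(as.character(ct$pmid), ct$title %||% "",
                 ct$abstract %||% "", name_key(ct$authors),
                 as.character(ct$journal_id %||% ""), ct$year)
  })
  names(citations) <- pmids
  idx <- new.env(parent = emptyenv())
  for (ct in citations) {
    for (k in unique(ct$authors)) {
      idx[[k]] <- c(idx[[k]], ct$pmid)
    }
  }
  structure(list(citations = citations, name_index = as.list(idx)),
            class = "citation_corpus")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.citation_corpus <- function(x, ...) {
  cat("citation_corpus:", length(x$citations), "citations,",
      length(x$name_index), "distinct name keys\n")
  invisible(x)
}

#' Parse a citation corpus from a flat file
#'
#' Reads either the MEDLINE flat-file dialect (tagged lines `PMID- `,
#' `TI  - `, `AB  - `, `AU  - `, `JT  - `, `DP  - `; continuation lines
#' indented, joined with single spaces) or a line-delimited JSON fixture
#' dialect (one object per line with fields `pmid`, `title`, `abstract`,
#' `authors`, `journal_id`, `year`).
#'
#' Records missing a PMID, an author list, or a parseable 4-digit year are
#' skipped with a warning and counted; a duplicate PMID is an error. The year
#' is the first 4-digit sequence in the DP field.
#'
#' @param path path to the input file.
#' @param dialect `"medline"` or `"jsonl"`.
#' @return A [citation_corpus()] with attribute `n_skipped`.
#' @export
parse_medline <- function(path, dialect = c("medline", "jsonl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- if (dialect == "medline") parse_medline_lines(lines)
          else parse_jsonl_lines(lines)
  keep <- vapply(recs, function(r) {
    ok <- !is.null(r$pmid) && nzchar(r$pmid) && length(r$authors) >= 1L &&
      !is.na(r$year)
    ok
  }, logical(1L))
  if (any(!keep)) {
    warning(sum(!keep), " record(s) skipped (missing PMID, authors or year)")
  }
  corpus <- citation_corpus(recs[keep])
  attr(corpus, "n_skipped") <- sum(!keep)
  corpus
}

parse_medline_lines <- function(lines) {
  recs <- list()
  cur <- NULL
  cur_tag <- NULL
  flush <- function() if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
  push <- function(tag, value) {
    if (tag == "AU") cur$authors <<- c(cur$authors, value)
    else cur[[tag]] <<- value
  }
  for (ln in lines) {
    if (grepl("^\\s*$", ln)) next
    m <- regmatches(ln, regexec("^([A-Z]{1,4})\\s*- (.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      tag <- m[2L]
      val <- m[3L]
      if (tag == "PMID") {
        flush()
        cur <- list(authors = character())
      }
      if (is.null(cur)) next  # stray field before any PMID
      cur_tag <- tag
      push(tag, if (tag == "AU") val else paste(c(cur[[tag]], val), collapse = " "))
    } else if (grepl("^\\s+\\S", ln) && !is.null(cur) && !is.null(cur_tag)) {
      # continuation of the previous field, joined with a single space
      val <- trimws(ln)
      if (cur_tag == "AU") {
        n <- length(cur$authors)
        cur$authors[n] <- paste(cur$authors[n], val)
      } else {
        cur[[cur_tag]] <- paste(cur[[cur_tag]], val)
      }
    }
  }
  flush()
  lapply(recs, function(r) {
    list(pmid = r$PMID %||% "", title = r$TI %||% "",
         abstract = r$AB %||% "", authors = r$authors,
         journal_id = r$JT %||% "", year = extract_year(r$DP %||% ""))
  })
}

parse_jsonl_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    list(pmid = as.character(r$pmid %||% ""), title = r$title %||% "",
         abstract = r$abstract %||% "",
         authors = as.character(r$authors %||% character()),
         journal_id = as.character(r$journal_id %||% ""),
         year = if (is.null(r$year)) NA_integer_ else as.integer(r$year))
  })
}

extract_year <- function(dp) {
  m <- regmatches(dp, regexpr("[0-9]{4}", dp))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

#' Write a corpus in the line-delimited JSON fixture dialect
#'
#' One JSON object per line with fields `pmid`, `title`, `abstract`,
#' `authors` (normalized keys), `journal_id`, `year`. Re-parsing the output
#' with [parse_medline()] (`dialect = "jsonl"`) reproduces the corpus.
#'
#' @param corpus a [citation_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "citation_corpus"))
  lines <- vapply(corpus$citations, function(ct) {
    jsonlite::toJSON(list(pmid = ct$pmid, title = ct$title,
                          abstract = ct$abstract, authors = ct$authors,
                          journal_id = ct$journal_id, year = ct$year),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
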