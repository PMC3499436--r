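#' Cited-author check with self-author skipping
#'
#' Benchmark logic for judging a ranked reviewer list against the reference
#' list of a manuscript: scan the results in rank order, skip any expert
#' whose name key belongs to the manuscript's own authors, and evaluate the
#' first non-self expert as "the top suggestion". The check succeeds when
#' that expert's name key matches an author of any cited reference.
#'
#' @param results a [search_experts()] result (needs a `name_key` column).
#' @param cited_author_keys character vector of name keys of cited-reference
#'   authors.
#' @param self_author_keys character vector of name keys of the manuscript's
#'   own authors (may overlap with `cited_author_keys`).
#' @return List: `hit` (logical), `rank` (1-based position of the evaluated
#'   suggestion among non-self results; `NA` when every result is a self
#'   author or the result list is empty), `author_id`, `name_key`,
#'   `n_skipped` (self authors skipped before the evaluated suggestion).
#' @export
cited_author_check <- function(results, cited_author_keys,
                               self_author_keys = character()) {
  if (nrow(results) == 0L) {
    return(list(hit = FALSE, rank = NA_integer_, author_id = NA_character_,
                name_key = NA_character_, n_skipped = 0L))
  }
  non_self <- !results$name_key %in% self_author_keys
  if (!any(non_self)) {
    return(list(hit = FALSE, rank = NA_integer_, author_id = NA_character_,
                name_key = NA_character_, n_skipped = nrow(results)))
  }
  i <- which(non_self)[1L]
  list(hit = results$name_key[i] %in% cited_author_keys,
       rank = 1L,
       author_id = results$author_id[i],
       name_key = results$name_key[i],
       n_skipped = i - 1L)
}

choose2 <- function(n) n * (n - 1) / 2

#' Pairwise precision and recall of a disambiguation against ground truth
#'
#' Clustering-recovery metrics computed over pairs of same-name
#' authorships: of all pairs placed in the same predicted profile
#' (co-clustered), precision is the fraction that truly belong to the same
#' identity; of all pairs truly belonging to one identity (co-identical),
#' recall is the fraction co-clustered. An undefined ratio (zero
#' denominator) is reported as 1.0 and flagged vacuous. Coauthor-based
#' disambiguation is expected to be high precision / lower recall
#' (atomization): splitting one identity across collaborator groups costs
#' recall, never precision.
#'
#' @param predicted output of [disambiguate_corpus()] (name key -> list of
#'   `disambiguated_author`).
#' @param truth data.frame with columns `pmid`, `name_key`, `identity_id`
#'   covering exactly the authorships of `predicted`.
#' @param include_singletons if `FALSE`, authorships assigned to singleton
#'   profiles are removed from both sides before pair enumeration, so the
#'   metrics describe the non-singleton clustering only.
#' @return List: `precision`, `recall`, `f1`, `n_pairs_clustered`,
#'   `n_pairs_identical`, `n_pairs_correct`, `vacuous_precision`,
#'   `vacuous_recall`.
#' @export
pairwise_cluster_metrics <- function(predicted, truth,
                                     include_singletons = TRUE) {
  flat <- unlist(predicted, recursive = FALSE, use.names = FALSE)
  pred <- do.call(rbind, lapply(flat, function(a)
    data.frame(pmid = a$pmids, name_key = a$name_key,
               cluster = a$author_id, singleton = a$is_singleton,
               stringsAsFactors = FALSE)))
  pkey <- paste(pred$pmid, pred$name_key, sep = "\r")
  tkey <- paste(truth$pmid, truth$name_key, sep = "\r")
  if (!setequal(pkey, tkey) || anyDuplicated(pkey) || anyDuplicated(tkey)) {
    stop("predicted clustering and ground truth cover different authorships")
  }
  pred$identity <- truth$identity_id[match(pkey, tkey)]
  if (!include_singletons) {
    pred <- pred[!pred$singleton, , drop = FALSE]
  }
  # pair counts within each name key, via group sizes
  n_clustered <- sum(choose2(table(pred$cluster)))
  n_identical <- sum(choose2(table(paste(pred$name_key, pred$identity,
                                         sep = "\r"))))
  n_correct <- sum(choose2(table(paste(pred$cluster, pred$identity,
                                       sep = "\r"))))
  vac_p <- n_clustered == 0
  vac_r <- n_identical == 0
  precision <- if (vac_p) 1 else n_correct / n_clustered
  recall <- if (vac_r) 1 else n_correct / n_identical
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_pairs_clustered = n_clustered, n_pairs_identical = n_identical,
       n_pairs_correct = n_correct,
       vacuous_precision = vac_p, vacuous_recall = vac_r)
}
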