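# Independent brute-force oracles. These deliberately use explicit loops
# over pairs/sentences, sharing no code with the package implementation.

oracle_relation <- function(sentences, a, b) {
  in_s <- function(t) vapply(sentences, function(s) t %in% s, logical(1L))
  sa <- sum(in_s(a)); sb <- sum(in_s(b)); sab <- sum(in_s(a) & in_s(b))
  if (sa == 0 || sb == 0) return(0)
  sab^2 / (sa * sb)
}

oracle_keyword_scores <- function(sentences) {
  terms <- sort(unique(unlist(sentences)))
  r <- setNames(numeric(length(terms)), terms)
  for (a in terms) {
    for (b in terms) {
      if (a != b) r[a] <- r[a] + oracle_relation(sentences, a, b)
    }
  }
  if (length(r) == 0 || max(r) == 0) return(r)
  r / max(r)
}

random_sentence_set <- function(max_sentences = 8L, max_terms = 10L) {
  vocab <- paste0("w", seq_len(sample(2:max_terms, 1L)))
  n <- sample(1:max_sentences, 1L)
  sents <- lapply(seq_len(n), function(i)
    sample(vocab, sample(1:length(vocab), 1L)))
  structure(sents, class = "sentence_set")
}

# brute-force TF-IDF scorer mirroring the documented formula from scratch
oracle_score <- function(query, author_id, store) {
  n_docs <- length(store)
  doc <- NULL
  for (p in store) if (p$author_id == author_id) doc <- p
  stopifnot(!is.null(doc))
  total <- 0
  n_overlap <- 0
  for (i in seq_len(nrow(query))) {
    t <- query$term[i]
    tf <- if (t %in% names(doc$term_counts)) doc$term_counts[[t]] else 0
    if (tf == 0) next
    n_overlap <- n_overlap + 1
    df <- 0
    for (p in store) if (t %in% names(p$term_counts)) df <- df + 1
    idf <- max(1 + log(n_docs / (df + 1)), 1e-6)
    total <- total + query$score[i] * idf^2 * sqrt(tf)
  }
  if (n_overlap == 0) return(0)
  coord <- n_overlap / nrow(query)
  coord * total / sqrt(sum(doc$term_counts))
}

random_store <- function(max_profiles = 20L, max_terms = 30L) {
  vocab <- paste0("t", seq_len(max_terms))
  n <- sample(2:max_profiles, 1L)
  profs <- lapply(seq_len(n), function(i) {
    terms <- sample(vocab, sample(1:10, 1L))
    mk_profile(sprintf("auth_%02d#001", i),
               setNames(sample(1:6, length(terms), replace = TRUE), terms))
  })
  setNames(profs, vapply(profs, `[[`, "", "author_id"))
}

# explicit pair-enumeration clustering metrics
oracle_pair_metrics <- function(predicted, truth) {
  flat <- unlist(predicted, recursive = FALSE, use.names = FALSE)
  rows <- list()
  for (a in flat) {
    for (p in a$pmids) {
      rows[[length(rows) + 1L]] <- c(p, a$name_key, a$author_id)
    }
  }
  m <- do.call(rbind, rows)
  identity <- truth$identity_id[match(paste(m[, 1L], m[, 2L]),
                                      paste(truth$pmid, truth$name_key))]
  tp <- 0; co_cl <- 0; co_id <- 0
  n <- nrow(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (m[i, 2L] != m[j, 2L]) next  # pairs only within one name key
      same_cl <- m[i, 3L] == m[j, 3L]
      same_id <- identity[i] == identity[j]
      if (same_cl) co_cl <- co_cl + 1
      if (same_id) co_id <- co_id + 1
      if (same_cl && same_id) tp <- tp + 1
    }
  }
  list(precision = if (co_cl == 0) 1 else tp / co_cl,
       recall = if (co_id == 0) 1 else tp / co_id)
}
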