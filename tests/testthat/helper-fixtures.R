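# compact corpus construction: mk_corpus(list(pmid, authors, ...), ...)
mk_cit <- function(pmid, authors, abstract = "", title = "",
                   journal_id = "J01", year = 2005L) {
  list(pmid = pmid, title = title, abstract = abstract, authors = authors,
       journal_id = journal_id, year = year)
}

mk_corpus <- function(...) citation_corpus(list(...))

mk_sentences <- function(...) structure(list(...), class = "sentence_set")

# a hand-rolled expert profile for index tests
mk_profile <- function(author_id, term_counts, name_key = NULL,
                       anchor = "x_y", journals = "J01",
                       years = 2005L, n_refs = 2L) {
  structure(list(author_id = author_id,
                 name_key = name_key %||% sub("#.*$", "", author_id),
                 anchor_coauthor = anchor,
                 term_counts = term_counts,
                 n_abstracts = n_refs, n_refs = n_refs,
                 journals = journals, years = years,
                 indexable = length(term_counts) > 0L),
            class = "expert_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small corpus configs for property tests (kept tiny for speed);
# the collision count is drawn feasibly (at most half the identities)
random_small_config <- function(seed) {
  n_ident <- sample(1:6, 1L)
  n_dup <- sample(0:(n_ident %/% 2L), 1L)
  generator_config(
    n_identities = n_ident,
    name_collision_rate = n_dup / n_ident,
    papers_per_identity = sort(sample(1:4, 2L, replace = TRUE)),
    coauthors_per_identity = sort(sample(1:4, 2L, replace = TRUE)),
    n_topics = 2L, topic_vocab_size = 12L,
    background_vocab_size = 8L,
    sentences_per_abstract = c(1L, 3L), words_per_sentence = c(3L, 6L),
    separable = sample(c(TRUE, FALSE), 1L),
    seed = seed)
}

# shuffle a corpus's citation order
shuffle_corpus <- function(corpus, seed = 1L) {
  cts <- unname(corpus$citations)
  set.seed(seed)
  citation_corpus(cts[sample(length(cts))])
}
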