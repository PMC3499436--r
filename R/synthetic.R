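#' Configuration for the synthetic citation-corpus generator
#'
#' Defaults describe a small but realistic ambiguous corpus: 50 author
#' identities, half of them sharing their "lastname_initials" key with
#' another identity, five papers each, a disjoint recurring-coauthor clique
#' per identity, three disjoint topic vocabularies and a shared background
#' vocabulary mixed into abstracts at weight 0.2, publication years
#' 1996-2010 over six journals with broad subject labels.
#'
#' @param n_identities number of target author identities.
#' @param name_collision_rate fraction of identities that re-use another
#'   identity's name key.
#' @param papers_per_identity integer range `c(min, max)` of papers per
#'   identity.
#' @param coauthors_per_identity integer range of clique sizes (the first
#'   clique member is the dedicated anchor).
#' @param n_topics number of topic vocabularies.
#' @param topic_vocab_size words per topic vocabulary.
#' @param topic_overlap fraction of each topic vocabulary shared with the
#'   next topic (0 = fully disjoint).
#' @param background_vocab_size size of the background vocabulary.
#' @param background_weight probability that an abstract word is drawn from
#'   the background instead of the topic vocabulary.
#' @param sentences_per_abstract integer range of sentences per abstract.
#' @param words_per_sentence integer range of words per sentence.
#' @param year_range inclusive publication-year range.
#' @param n_journals size of the journal pool.
#' @param subjects pool of broad subject labels assigned to journals.
#' @param separable if `TRUE`, every paper of an identity includes its
#'   dedicated anchor coauthor, making identities recoverable exactly.
#' @param seed integer random seed; the same seed reproduces the corpus
#'   byte for byte.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_identities = 50L,
                             name_collision_rate = 0.5,
                             papers_per_identity = c(5L, 5L),
                             coauthors_per_identity = c(3L, 5L),
                             n_topics = 3L,
                             topic_vocab_size = 40L,
                             topic_overlap = 0,
                             background_vocab_size = 30L,
                             background_weight = 0.2,
                             sentences_per_abstract = c(3L, 6L),
                             words_per_sentence = c(6L, 10L),
                             year_range = c(1996L, 2010L),
                             n_journals = 6L,
                             subjects = c("biochemistry", "cardiology",
                                          "genetics", "microbiology",
                                          "neurology", "oncology",
                                          "pharmacology", "physiology"),
                             separable = TRUE,
                             seed = 1L) {
  cfg <- list(n_identities = as.integer(n_identities),
              name_collision_rate = name_collision_rate,
              papers_per_identity = as.integer(papers_per_identity),
              coauthors_per_identity = as.integer(coauthors_per_identity),
              n_topics = as.integer(n_topics),
              topic_vocab_size = as.integer(topic_vocab_size),
              topic_overlap = topic_overlap,
              background_vocab_size = as.integer(background_vocab_size),
              background_weight = background_weight,
              sentences_per_abstract = as.integer(sentences_per_abstract),
              words_per_sentence = as.integer(words_per_sentence),
              year_range = as.integer(year_range),
              n_journals = as.integer(n_journals),
              subjects = subjects,
              separable = isTRUE(separable),
              seed = as.integer(seed))
  stopifnot(cfg$n_identities >= 1L,
            cfg$name_collision_rate >= 0, cfg$name_collision_rate <= 1,
            all(cfg$papers_per_identity >= 1L),
            all(cfg$coauthors_per_identity >= 1L),
            cfg$n_topics >= 1L, cfg$topic_vocab_size >= 1L,
            cfg$topic_overlap >= 0, cfg$topic_overlap <= 1,
            cfg$background_weight >= 0, cfg$background_weight < 1,
            all(cfg$sentences_per_abstract >= 1L),
            all(cfg$words_per_sentence >= 1L),
            cfg$n_journals >= 1L)
  structure(cfg, class = "generator_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [generator_config()].
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

# pronounceable unique last names built from syllables
random_names <- function(n, taken = character()) {
  syl <- c("an", "bar", "chen", "dov", "el", "far", "gol", "hab", "iv",
           "jor", "kal", "lim", "mor", "nas", "ol", "pet", "qui", "ros",
           "sar", "tor", "ul", "vas", "wes", "xi", "yan", "zam")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    last <- vapply(seq_len(need), function(i)
      paste(sample(syl, sample(2:3, 1L), replace = TRUE), collapse = ""),
      "")
    init <- vapply(seq_len(need), function(i)
      paste(sample(letters, sample(1:2, 1L), replace = TRUE), collapse = ""),
      "")
    cand <- paste(last, init, sep = "_")
    out <- unique(c(out, setdiff(cand, taken)))
  }
  out[seq_len(n)]
}

# unique lowercase pseudo-words, disjoint from `taken`
random_words <- function(n, len_range = c(5L, 8L), taken = character()) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i)
      paste(sample(letters, sample(len_range[1L]:len_range[2L], 1L),
                   replace = TRUE), collapse = ""), "")
    out <- unique(c(out, setdiff(cand, taken)))
  }
  out[seq_len(n)]
}

sample_range <- function(range) {
  if (range[1L] == range[2L]) range[1L]
  else sample(range[1L]:range[2L], 1L)
}

make_abstract <- function(vocab, background, cfg) {
  n_sent <- sample_range(cfg$sentences_per_abstract)
  sents <- vapply(seq_len(n_sent), function(i) {
    n_w <- sample_range(cfg$words_per_sentence)
    from_bg <- stats::runif(n_w) < cfg$background_weight
    w <- ifelse(from_bg & length(background) > 0L,
                sample(background, n_w, replace = TRUE),
                sample(vocab, n_w, replace = TRUE))
    paste0(paste(w, collapse = " "), ".")
  }, "")
  paste(sents, collapse = " ")
}

#' Generate a synthetic citation corpus with ground truth
#'
#' Emulates the ambiguity structure of real bibliographic data: several
#' distinct identities can share one "lastname_initials" key, each identity
#' publishes with its own coauthor clique (cliques are disjoint across
#' identities), and each identity writes about one topic, with abstracts
#' drawn as bags of words from the topic vocabulary plus a shared
#' background vocabulary. In separable mode every paper of an identity also
#' lists its dedicated anchor coauthor, which makes the coauthor-based
#' disambiguation exact by construction.
#'
#' @param config a [generator_config()].
#' @return List with elements `corpus` (a [citation_corpus()]), `truth`
#'   (data.frame `pmid`, `name_key`, `identity_id` covering every
#'   authorship), `identities` (data.frame `identity_id`, `name_key`,
#'   `topic`, `anchor`), `topics` (list of topic vocabularies),
#'   `background` (background vocabulary), `journals` (data.frame
#'   `journal_id`, `subjects` semicolon-joined).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_dup <- round(cfg$name_collision_rate * cfg$n_identities)
  n_orig <- cfg$n_identities - n_dup
  if (n_dup > n_orig) {
    stop("infeasible config: more colliding identities (", n_dup,
         ") than available name keys (", n_orig, ")")
  }
  keys <- random_names(n_orig)
  id_keys <- c(keys, keys[seq_len(n_dup)])  # duplicates reuse the first keys

  # disjoint coauthor cliques, disjoint from identity keys
  clique_sizes <- vapply(seq_len(cfg$n_identities), function(i)
    sample_range(cfg$coauthors_per_identity), 0L)
  pool <- random_names(sum(clique_sizes), taken = keys)
  cliques <- split(pool, rep(seq_len(cfg$n_identities), clique_sizes))

  # topic vocabularies with optional pairwise overlap, plus background
  n_shared <- round(cfg$topic_overlap * cfg$topic_vocab_size)
  n_own <- cfg$topic_vocab_size - n_shared
  all_words <- random_words(cfg$n_topics * n_own + n_shared +
                              cfg$background_vocab_size)
  shared <- if (n_shared > 0L) all_words[seq_len(n_shared)] else character()
  own <- matrix(all_words[n_shared + seq_len(cfg$n_topics * n_own)],
                ncol = cfg$n_topics)
  topics <- lapply(seq_len(cfg$n_topics), function(t)
    c(own[, t], shared))
  background <- all_words[cfg$n_topics * n_own + n_shared +
                            seq_len(cfg$background_vocab_size)]

  journals <- sprintf("J%02d", seq_len(cfg$n_journals))
  journal_subjects <- lapply(journals, function(j)
    sample(cfg$subjects, sample(1:2, 1L)))
  names(journal_subjects) <- journals

  topic_of <- sample(cfg$n_topics, cfg$n_identities, replace = TRUE)
  identity_ids <- sprintf("I%03d", seq_len(cfg$n_identities))

  citations <- list()
  truth <- list()
  pid <- 0L
  for (i in seq_len(cfg$n_identities)) {
    clique <- cliques[[i]]
    anchor <- clique[1L]
    n_papers <- sample_range(cfg$papers_per_identity)
    for (p in seq_len(n_papers)) {
      pid <- pid + 1L
      others <- if (length(clique) > 1L) {
        n_extra <- sample(0:(length(clique) - 1L), 1L)
        clique[-1L][sample.int(length(clique) - 1L, n_extra)]
      } else character()
      co <- if (cfg$separable) c(anchor, others) else {
        clique[sample.int(length(clique),
                          max(1L, sample_range(c(1L, length(clique)))))]
      }
      co <- sample(co)  # shuffle coauthor order; identity stays first
      pmid <- sprintf("S%05d", pid)
      citations[[pid]] <- list(
        pmid = pmid,
        title = paste(sample(topics[[topic_of[i]]], 4L), collapse = " "),
        abstract = make_abstract(topics[[topic_of[i]]], background, cfg),
        authors = c(id_keys[i], co),
        journal_id = sample(journals, 1L),
        year = sample(cfg$year_range[1L]:cfg$year_range[2L], 1L))
      truth[[pid]] <- data.frame(
        pmid = pmid,
        name_key = c(id_keys[i], co),
        identity_id = c(identity_ids[i], paste0("C_", co)),
        stringsAsFactors = FALSE)
    }
  }
  list(corpus = citation_corpus(citations),
       truth = do.call(rbind, truth),
       identities = data.frame(identity_id = identity_ids,
                               name_key = id_keys, topic = topic_of,
                               anchor = vapply(cliques, `[[`, "", 1L),
                               stringsAsFactors = FALSE),
       topics = topics,
       background = background,
       journals = data.frame(journal_id = journals,
                             subjects = vapply(journal_subjects, paste,
                                               "", collapse = ";"),
                             stringsAsFactors = FALSE))
}

#' One identity with two disjoint collaborator groups
#'
#' Models a scientist who works on two somewhat different matters with two
#' disjoint sets of recurring collaborators. The ground truth labels both
#' groups as one identity; coauthor-based disambiguation necessarily splits
#' them into two profiles (atomization: precision stays 1, recall drops).
#'
#' @param papers_per_group papers in each collaborator group (default 3).
#' @param merge_groups if `TRUE`, a single recurring coauthor spans all
#'   papers (control case: one profile).
#' @param seed integer seed.
#' @param config optional `generator_config` supplying vocabulary and
#'   journal settings.
#' @return Same shape as [generate_corpus()] (without `identities`).
#' @export
split_clique_scenario <- function(papers_per_group = 3L,
                                  merge_groups = FALSE, seed = 1L,
                                  config = generator_config(seed = seed)) {
  cfg <- config
  set.seed(cfg$seed)
  keyset <- random_names(4L)
  id_key <- keyset[1L]
  g1 <- keyset[2L]
  g2 <- keyset[3L]
  n <- 2L * papers_per_group
  fillers <- random_names(n, taken = keyset)
  vocab_words <- random_words(cfg$topic_vocab_size)
  citations <- list()
  truth <- list()
  for (p in seq_len(n)) {
    recurring <- if (merge_groups) g1 else if (p <= papers_per_group) g1
                 else g2
    pmid <- sprintf("S%05d", p)
    authors <- c(id_key, recurring, fillers[p])
    citations[[p]] <- list(
      pmid = pmid,
      title = paste(sample(vocab_words, 4L), collapse = " "),
      abstract = make_abstract(vocab_words, character(), cfg),
      authors = authors,
      journal_id = "J01",
      year = sample(cfg$year_range[1L]:cfg$year_range[2L], 1L))
    truth[[p]] <- data.frame(
      pmid = pmid, name_key = authors,
      identity_id = c("I001", paste0("C_", authors[-1L])),
      stringsAsFactors = FALSE)
  }
  list(corpus = citation_corpus(citations),
       truth = do.call(rbind, truth),
       name_key = id_key,
       topics = list(vocab_words),
       background = character(),
       journals = data.frame(journal_id = "J01",
                             subjects = cfg$subjects[1L],
                             stringsAsFactors = FALSE))
}

#' Write ground truth as TSV
#'
#' @param truth data.frame (`pmid`, `name_key`, `identity_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @param path TSV path to read.
#' @return `read_truth_tsv()`: the truth data.frame.
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             colClasses = "character")
}
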