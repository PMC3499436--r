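test_that("the inverted index is consistent with its profiles", {
  store <- list(
    a = mk_profile("a_a#001", c(kinase = 2L, cell = 1L)),
    b = mk_profile("b_b#001", c(kinase = 5L)),
    c = mk_profile("c_c#001", c(genome = 3L)))
  idx <- build_index(store)
  expect_equal(idx$n_docs, 3L)
  expect_equal(unname(idx$doc_freq["kinase"]), 2L)
  expect_equal(unname(idx$doc_freq["genome"]), 1L)
  expect_equal(unname(idx$doc_len["a_a#001"]), 3)
  # postings contain every (author, term) occurrence
  expect_setequal(idx$postings[["kinase"]]$author_id,
                  c("a_a#001", "b_b#001"))

  expect_error(build_index(list()), "empty profile store")
  expect_error(build_index(c(store, store["a"])), "duplicate author_id")

  # shuffled stores index identically
  idx2 <- build_index(store[c(3, 1, 2)])
  expect_equal(idx2$doc_freq, idx$doc_freq)
  expect_equal(idx2$postings, idx$postings)
})

test_that("the TF-IDF score matches the closed-form single-doc case", {
  store <- list(a = mk_profile("a_a#001", c(kinase = 4L)))
  idx <- build_index(store)
  # single-term query with weight 1: coord * idf^2 * sqrt(tf) / sqrt(len)
  one <- data.frame(term = "kinase", score = 1)
  expect_equal(score_expert(one, "a_a#001", idx), (1 + log(0.5))^2,
               tolerance = 1e-12)

  # no overlap scores exactly zero
  none <- data.frame(term = "ribosome", score = 1)
  expect_equal(score_expert(none, "a_a#001", idx), 0)
  expect_error(score_expert(one, "ghost#001", idx), "not indexed")

  # doubling the matched term frequency strictly increases the score
  s4 <- score_expert(one, "a_a#001", build_index(list(
    a = mk_profile("a_a#001", c(kinase = 4L, buffer = 4L)))))
  s8 <- score_expert(one, "a_a#001", build_index(list(
    a = mk_profile("a_a#001", c(kinase = 8L, buffer = 4L)))))
  expect_gt(s8, s4)
})

test_that("ranked scores match the brute-force oracle on random stores", {
  for (i in 1:20) {
    set.seed(200 + i)
    store <- random_store(max_profiles = 20L, max_terms = 30L)
    idx <- build_index(store)
    q_terms <- sample(paste0("t", 1:30), sample(2:8, 1L))
    query <- data.frame(term = q_terms,
                        score = round(runif(length(q_terms), 0.06, 1), 3),
                        stringsAsFactors = FALSE)
    for (id in names(store)) {
      expect_equal(score_expert(query, id, idx),
                   oracle_score(query, id, store), tolerance = 1e-9)
    }
  }
})

test_that("search ranks by score with deterministic ties and filters by
           subject without re-weighting", {
  store <- list(
    a = mk_profile("a_a#001", c(kinase = 4L, cell = 2L), journals = "J01"),
    b = mk_profile("b_b#001", c(kinase = 1L), journals = "J02"),
    c = mk_profile("c_c#001", c(genome = 3L), journals = c("J01", "J02")))
  idx <- build_index(store)
  query <- data.frame(term = c("kinase", "cell"), score = c(1, 0.5))

  res <- search_experts(query, idx, store, top_k = 3L)
  expect_s3_class(res, "ranked_experts")
  expect_equal(res$author_id[1L], "a_a#001")
  expect_true(all(diff(res$score) <= 0))
  expect_equal(res$rank, 1:3)

  # subjects = none equals unfiltered ranking
  smap <- list(J01 = "cardiology", J02 = c("genetics", "microbiology"))
  unfiltered <- search_experts(query, idx, store, top_k = 3L)
  filtered <- search_experts(query, idx, store, top_k = 3L,
                             subjects = "genetics", subject_map = smap)
  expect_setequal(filtered$author_id, c("b_b#001", "c_c#001"))
  # a surviving author's score is identical with and without the filter
  for (id in filtered$author_id) {
    expect_equal(filtered$score[filtered$author_id == id],
                 unfiltered$score[unfiltered$author_id == id])
  }
  # a subject covering none of an author's journals removes it regardless
  expect_false("a_a#001" %in% filtered$author_id)

  expect_error(search_experts(query[0, ], idx, store), "no keywords")
  expect_error(search_experts(query, idx, store, subjects = "x"),
               "subject_map")
})

test_that("display keywords are the top tf-idf profile terms", {
  store <- list(
    a = mk_profile("a_a#001", c(common = 10L, rare = 6L)),
    b = mk_profile("b_b#001", c(common = 10L)),
    c = mk_profile("c_c#001", c(common = 10L)))
  idx <- build_index(store)
  kw <- display_keywords(store$a, idx, n = 1L)
  # idf: rare = 1+ln(3/2), common = 1+ln(3/4); 6*1.405 > 10*0.712
  expect_equal(kw, "rare")
  expect_equal(display_keywords(store$a, idx, n = 5L),
               c("rare", "common"))
})

test_that("the journal table counts distinct experts per journal", {
  store <- list(
    a = mk_profile("a_a#001", c(x = 1L), journals = c("J01", "J02")),
    b = mk_profile("b_b#001", c(x = 1L), journals = "J01"),
    c = mk_profile("c_c#001", c(y = 1L), journals = "J03"))
  idx <- build_index(store)
  res <- search_experts(data.frame(term = "x", score = 1), idx, store,
                        top_k = 3L)
  jt <- journal_table(res, store)
  expect_equal(jt$n_experts[jt$journal_id == "J01"], 2L)
  expect_equal(jt$n_experts[jt$journal_id == "J02"], 1L)
  # multi-journal authors make the counts sum to >= number of experts
  expect_gte(sum(jt$n_experts), nrow(res))
  expect_error(journal_table(res[0, ], store), "empty result")
})

test_that("subject maps read journal-subject pairs from TSV", {
  path <- system.file("extdata", "example_subjects.tsv",
                      package = "peersuggest")
  smap <- read_subject_map(path)
  expect_setequal(smap[["J Card Res"]], c("cardiology", "physiology"))
  expect_setequal(smap[["J Microb Genomics"]],
                  c("microbiology", "genetics"))
})
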