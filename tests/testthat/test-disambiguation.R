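test_that("coauthor frequencies count once per citation and exclude self", {
  corpus <- mk_corpus(
    mk_cit("1", c("a_x", "b_y")),
    mk_cit("2", c("a_x", "b_y", "c_z")),
    mk_cit("3", c("a_x", "c_z")))
  freq <- coauthor_frequencies("a_x", corpus$citations)
  expect_equal(freq[order(names(freq))], c(b_y = 2L, c_z = 2L))

  # single-author citations contribute nothing
  solo <- mk_corpus(mk_cit("1", "a_x"), mk_cit("2", "a_x"))
  expect_length(coauthor_frequencies("a_x", solo$citations), 0L)
  expect_length(coauthor_frequencies("a_x", list()), 0L)

  # a pathological duplicate listing still counts once
  dup <- mk_corpus(mk_cit("1", c("a_x", "b_y", "b_y")))
  expect_equal(unname(coauthor_frequencies("a_x", dup$citations)["b_y"]), 1L)
})

test_that("greedy loop anchors identities and leaves singletons", {
  corpus <- mk_corpus(
    mk_cit("r1", c("smith_j", "lee_k")),
    mk_cit("r2", c("smith_j", "lee_k", "wu_q")),
    mk_cit("r3", c("smith_j", "chen_h")))
  profs <- disambiguate_name("smith_j", corpus)
  expect_length(profs, 2L)
  expect_equal(profs[[1]]$anchor_coauthor, "lee_k")
  expect_equal(profs[[1]]$pmids, c("r1", "r2"))
  expect_false(profs[[1]]$is_singleton)
  expect_true(profs[[2]]$is_singleton)
  expect_equal(profs[[2]]$pmids, "r3")
  expect_equal(profs[[1]]$author_id, "smith_j#001")
  expect_equal(profs[[2]]$author_id, "smith_j#002")

  expect_error(disambiguate_name("nobody_z", corpus), "unknown name key")
})

test_that("ties among equally frequent coauthors break lexicographically", {
  corpus <- mk_corpus(
    mk_cit("r1", c("a_a", "b_b")),
    mk_cit("r2", c("a_a", "c_c")),
    mk_cit("r3", c("a_a", "b_b")),
    mk_cit("r4", c("a_a", "c_c")))
  profs <- disambiguate_name("a_a", corpus)
  expect_length(profs, 2L)
  expect_equal(profs[[1]]$anchor_coauthor, "b_b")
  expect_equal(profs[[1]]$pmids, c("r1", "r3"))
  expect_equal(profs[[2]]$anchor_coauthor, "c_c")
  expect_equal(profs[[2]]$pmids, c("r2", "r4"))
})

test_that("a lone citation becomes a single singleton profile", {
  corpus <- mk_corpus(mk_cit("r1", c("solo_s", "other_o")))
  profs <- disambiguate_name("solo_s", corpus)
  expect_length(profs, 1L)
  expect_true(profs[[1]]$is_singleton)
})

test_that("min_repeat raises the recurrence bar and the drop flag removes
           single-author papers", {
  corpus <- mk_corpus(
    mk_cit("r1", c("a_a", "b_b")),
    mk_cit("r2", c("a_a", "b_b")),
    mk_cit("r3", "a_a"))
  profs <- disambiguate_name("a_a", corpus, min_repeat = 3L)
  expect_true(all(vapply(profs, `[[`, TRUE, "is_singleton")))

  kept <- disambiguate_name("a_a", corpus, drop_single_author = TRUE)
  expect_equal(sort(unlist(lapply(kept, `[[`, "pmids"))), c("r1", "r2"))
})

test_that("corpus-level disambiguation is order invariant", {
  sim <- generate_corpus(random_small_config(11))
  d1 <- disambiguate_corpus(sim$corpus)
  d2 <- disambiguate_corpus(shuffle_corpus(sim$corpus, seed = 99))
  expect_equal(d1, d2)
  expect_setequal(names(d1), names(sim$corpus$name_index))
})

test_that("profiles partition each name's citations with contained anchors
           and non-increasing anchored sizes", {
  for (seed in c(2, 5, 8, 13)) {
    set.seed(seed)
    sim <- generate_corpus(random_small_config(seed))
    d <- disambiguate_corpus(sim$corpus)
    for (key in names(d)) {
      profs <- d[[key]]
      pmids <- unlist(lapply(profs, `[[`, "pmids"))
      # partition: disjoint and covering
      expect_false(anyDuplicated(pmids) > 0)
      expect_setequal(pmids, sim$corpus$name_index[[key]])
      sizes <- integer()
      for (p in profs) {
        for (pm in p$pmids) {
          authors <- sim$corpus$citations[[pm]]$authors
          expect_true(key %in% authors)
          if (!p$is_singleton) {
            # anchor containment: every citation lists the anchor
            expect_true(p$anchor_coauthor %in% authors)
          }
        }
        if (!p$is_singleton) sizes <- c(sizes, length(p$pmids))
      }
      # greedy dominance: anchored profile sizes never increase
      expect_true(all(diff(sizes) <= 0))
    }
  }
})

test_that("two same-name identities with disjoint recurring coauthors give
           exactly two anchored profiles", {
  sim <- generate_corpus(generator_config(
    n_identities = 2L, name_collision_rate = 0.5,
    papers_per_identity = c(4L, 4L), coauthors_per_identity = c(2L, 3L),
    seed = 21))
  key <- sim$identities$name_key[1L]
  expect_equal(sim$identities$name_key[2L], key)  # collided by construction
  profs <- disambiguate_name(key, sim$corpus)
  anchored <- Filter(function(p) !p$is_singleton, profs)
  expect_length(anchored, 2L)
  # each anchored profile matches one ground-truth identity exactly
  truth_key <- sim$truth[sim$truth$name_key == key, ]
  for (p in anchored) {
    ids <- unique(truth_key$identity_id[match(p$pmids, truth_key$pmid)])
    expect_length(ids, 1L)
  }
})

test_that("authors_table flattens results and writes TSV", {
  corpus <- mk_corpus(
    mk_cit("r1", c("smith_j", "lee_k")),
    mk_cit("r2", c("smith_j", "lee_k")))
  df <- authors_table(disambiguate_corpus(corpus))
  expect_named(df, c("author_id", "name_key", "anchor_coauthor", "n_refs",
                     "pmids"))
  expect_equal(df$pmids[df$author_id == "smith_j#001"], "r1,r2")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  authors_table(disambiguate_corpus(corpus), tmp)
  expect_equal(nrow(read.delim(tmp)), nrow(df))
})
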