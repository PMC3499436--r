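---
title: "Methods: coauthor disambiguation, keyword profiles and expert retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coauthor disambiguation, keyword profiles and expert retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peersuggest)
```

# The problem

Editors looking for peer reviewers would like to turn a manuscript abstract
into a ranked list of scientists whose publication record matches its
content. Two obstacles make this hard in bibliographic databases of the
MEDLINE kind. First, an author mention is only a "last name + initials"
string, and many distinct people share one such string, so publication
records cannot be attributed to individuals directly. Second, expertise is
distributed over many abstracts per person, so matching a query against
single documents under-uses the signal.

`peersuggest` addresses both: it partitions each ambiguous name into
*disambiguated identities* using recurrent coauthors, aggregates the
abstracts attributed to each identity into a term-frequency *expertise
profile*, summarizes the query abstract into a bounded *keyword profile*,
and ranks identities with a TF-IDF similarity score.

# Author-name disambiguation by recurrent coauthors

Every author mention is normalized to the key `lastname_initials` (lower
case, diacritics folded to base letters, hyphens and apostrophes kept — so
accent variants of one name merge while hyphenated names stay intact).
For one key, the citations carrying it are partitioned greedily:

1. count, over the remaining citations, how often every other name key
   co-occurs (at most once per citation);
2. if the maximum count is at least `min_repeat` (default 2), emit an
   identity *anchored* to the winning coauthor, consisting of exactly the
   remaining citations that list that coauthor, and remove them;
3. repeat on the remainder; when no coauthor recurs, each leftover
   citation becomes its own *singleton* identity.

Frequencies are re-counted over the remainder at each step, ties between
equally frequent coauthors break lexicographically, and pmid sets are
processed in sorted order, so the partition is a pure function of the
citation multiset — record order never matters. The identity id is
`name_key#NNN` in extraction order.

The method is deliberately *atomizing*: a scientist who maintains two
disjoint collaborator circles is split into two identities. Pairwise
precision stays 1 (citations grouped together really do belong to one
person whenever coauthor cliques are disjoint) while recall drops; for
expert finding this bias is acceptable, since either fragment is still a
coherent body of work on one theme. `split_clique_scenario()` constructs
the canonical example — six papers, two disjoint recurring coauthors —
where the algorithm returns two profiles and pairwise recall is
6/15 = 0.4 by enumeration.

Single-author papers carry no coauthor signal; they are kept as singletons
by default, and `drop_single_author = TRUE` removes them, matching builds
restricted to multi-author records.

# Keyword profiles from query text

The query abstract is split into sentences (terminal `.!?` followed by
whitespace and an upper-case/digit boundary; a configurable abbreviation
list suppresses false splits), lower-cased, tokenized, and stripped of
stop words. A part-of-speech tagger can be plugged in as a plain function
to restrict tokens to nouns/adjectives/verbs (nouns only for expertise
profiles); the default build uses the *null tagger* — stop-word filtering
alone — because no redistributable tagger ships with the package, and the
same filtering contract is applied to queries and profiles so the two
vocabularies stay symmetric. That symmetry is what the similarity score
requires; a tagger changes which tokens survive, not the contract.

Word importance is scored with a fuzzy binary relation derived from
sentence co-occurrence. With `s(i)` the number of sentences containing
term `i` and `s(i,j)` the number containing both,

    mu(i,j) = s(i,j)^2 / (s(i) * s(j))

is symmetric, lies in `[0,1]`, is 1 exactly when two terms always co-occur
and 0 when they never do, and adding a sentence containing both terms can
never decrease it. A term's raw score is the sum of its relations,
normalized by the maximum, so the best-connected word scores 1 whenever
any co-occurrence exists:

```{r}
ss <- split_and_filter("Cell division cycle. Cell cycle. Protein division.",
                       stopwords = character())
keyword_scores(ss)
```

This presence/absence formulation is a design choice: it satisfies every
property the score needs (frequent, well-connected words on top; bounded
scores; duplication invariance — doubling every sentence changes nothing)
while remaining simple enough to verify against brute-force pair
enumeration, which the test suite does to 1e-12 on random texts. Weighting
by within-sentence distance or token multiplicity was deliberately not
guessed at.

A keyword profile keeps at most `max_terms = 50` terms with score
*strictly* greater than `min_score = 0.05`, sorted by score then
alphabetically. A too-short or unspecific text yields an empty profile and
the search entry points refuse it explicitly ("no keywords") rather than
returning arbitrary results.

# Expertise profiles and eligibility

An identity is profiled when at least one attributed citation has its name
key in **first or last** author position, a year in the inclusive window
2000–2010 (both configurable), and — when a journal list is supplied — a
journal in that list. An empty journal list means no restriction; tests
and examples use synthetic journal ids. The profile concatenates the
attributed abstracts and counts raw term occurrences (counts, not
presence/absence, because they are richer and reduce score ties);
abstract-free citations still contribute their journal and year metadata.
Profiles with no usable tokens are flagged unindexable and dropped from
the store.

# Retrieval

Profiles are held in an inverted index (`term → (author, tf)` postings,
document frequencies, document lengths). The similarity between a query
keyword profile and an expert is the classic practical TF-IDF scoring of
Lucene-style retrieval libraries:

    score(q, d) = coord * sum_t  w_q(t) * idf(t)^2 * sqrt(tf(t,d)) / sqrt(len(d))

with `idf(t) = 1 + ln(N / (df(t) + 1))`, `coord` the fraction of query
terms matched, and `w_q(t)` the query keyword score acting as a per-term
boost. On corpora small enough that a term appears in more than about
`N/e` profiles this idf would go negative, so it is floored at `1e-6`;
scores are therefore non-negative and zero exactly when no term overlaps.
A brute-force scorer in the tests reproduces ranked scores to 1e-9.

Subject filtering restricts the *candidate set* to authors with at least
one citation in a journal mapped to a selected broad subject; document
frequencies are still taken from the full index, so a surviving author's
score is identical with and without the filter (narrowing the candidates
is a selection, not a re-weighting). Each hit is displayed with its
anchor coauthor (itself a useful alternative suggestion), its top-10
profile terms by tf·idf, and a journal table counting where the returned
experts publish.

# The synthetic corpus generator

Real MEDLINE-scale inputs are neither shippable nor necessary to test the
machinery; the generator builds corpora whose ground truth is known by
construction. Its defaults are the reference conditions used throughout
the tests: 50 identities, half of them re-using another identity's name
key (25 shared keys), 5 papers per identity, a coauthor clique of 3–5
names per identity (cliques pairwise disjoint, first member the dedicated
anchor appearing on every paper in separable mode), 3 disjoint topic
vocabularies of 40 pseudo-words, a 30-word background vocabulary mixed in
at weight 0.2, publication years 1996–2010 — wide enough that the
2000–2010 eligibility window actually excludes records — and 6 journals
carrying 1–2 broad subject labels. Abstracts are bags of words: the
keyword and retrieval stages only consume co-occurrence and frequencies,
so no grammar is simulated.

Under these defaults the disambiguation is exact (pairwise precision and
recall 1.0): every identity's papers all contain its anchor, and cliques
are disjoint, so the greedy loop peels identities off perfectly. This is
what the generator is *for* — a separability control. What passing these
tests does **not** show is performance on real data, where coauthor
cliques overlap, collaborators change over time, and the same person
publishes under name variants; the split-clique scenario quantifies the
predictable failure mode (recall loss by atomization), but real corpora
will sit somewhere between the two constructions.

# Numerical and design notes

* All randomness flows through a single integer seed; the same
  configuration and seed reproduce corpora byte for byte.
* Tie-breaks are lexicographic everywhere (anchor choice, keyword order,
  result order by author id at equal score) to keep every output
  deterministic and testable.
* Pairwise clustering metrics enumerate same-name authorship pairs via
  group-size combinatorics; undefined ratios (no co-clustered or no
  co-identical pairs) are reported as 1.0 with a `vacuous_*` flag rather
  than NaN.
* The cited-author benchmark harness evaluates the first suggestion that
  is not an author of the manuscript itself (self authors are skipped),
  and reports a miss with the evaluated expert rather than scanning
  deeper — matching how such benchmarks treat a ranked list with a single
  "top suggestion".
* Problem sizes in the tests (corpora of up to a few hundred citations,
  200 random configurations for the partition properties, brute-force
  oracles up to 20 profiles / 30 terms) were chosen as the smallest sizes
  at which every contract is exercised, keeping the whole suite fast.

# Limitations

* Disambiguation uses coauthor recurrence only — no affiliations,
  subjects, or citation graphs; single-author bodies of work cannot be
  disambiguated at all and surface as singletons.
* The fuzzy relation is presence/absence within sentences; long abstracts
  with many one-off terms dilute scores.
* The retrieval score is a fixed TF-IDF variant, not a learned model;
  scores are comparable within one query, not across queries.
* The shipped stop-word list is English-only, and tokenization assumes
  Latin-script text.
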