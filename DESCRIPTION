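Package: peersuggest
Title: Peer-Reviewer Suggestion from Coauthor-Disambiguated Publication Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Suggests candidate peer reviewers for a manuscript abstract by
    mining a MEDLINE-style citation corpus. Author names are disambiguated
    into identities by a greedy most-frequent-coauthor partitioning, keyword
    profiles are extracted from query text via fuzzy sentence co-occurrence
    relations, expertise profiles are built from the abstracts attributed to
    each disambiguated author, and candidates are ranked with a TF-IDF
    similarity score over an inverted index. Includes a synthetic corpus
    generator with ground-truth identity labels, pairwise clustering
    evaluation metrics, a cited-author benchmark harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
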