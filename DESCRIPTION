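Package: convrel
Title: Inferring Dyadic Social Relationships from Observed Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how third-party observers infer dyadic social
    relationships (friendship, rivalry, likely winner) from passively observed
    conversations. Implements percent-chosen aggregation of forced-choice
    triplet responses, intersubject correlation with bootstrap null
    distributions, three conversational linguistic features (valence-shifter
    sentiment, a transparent clout proxy, and embedding-based semantic
    similarity with a deterministic hashed backend) aggregated at four
    temporal and dyadic levels, and beta-binomial hierarchical Bayesian models
    linking features to relational judgments, with Bayes factors for
    condition-by-feature interactions. A seeded synthetic-study generator
    produces transcripts and observer responses with known latent relationship
    structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    coda,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
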