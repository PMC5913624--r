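Package: litmech
Title: Literature-Based Discovery of Mechanistic Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate mechanistic intermediates linking two
    biomedical concepts from annotated literature. Given two article sets and
    a corpus of subject-PREDICATE-object predications plus MeSH annotations,
    the package finds terms and predication triples statistically enriched in
    each set against the corpus background (two-tailed Fisher's exact test
    with Benjamini-Hochberg correction), chains enriched triples across the
    two sets where the object of one set's triple is the subject of the
    other's, scores and filters the resulting mechanism chains, and exports
    provenance-linked tables plus Sankey and force-directed network documents.
    A synthetic-corpus generator with planted mechanisms supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
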