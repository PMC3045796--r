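Package: aliasprofiler
Title: Disclosing Ambiguous Gene Aliases by Literature Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the ambiguity of gene aliases from the content of their
    associated literature. For each gene, abstracts retrieved with the
    official symbol, its aliases and randomly picked internal-control
    symbols are tokenized; a group-specific informative vocabulary is
    extracted with a baseline-frequency filter and a corpus-size-adjusted
    difference filter; names are compared by Jaccard distance on binarized
    term profiles; and an alias is labelled ambiguous when it lies at least
    as far from its official symbol as the nearest unrelated control.
    Includes readers for tab-separated and Medline-format corpora, an
    optional PubMed eUtils fetcher, a synthetic bag-of-words corpus
    generator with planted topic structure for offline validation, and
    evaluation utilities (corpus redundancy, fold-increase in unique
    documents, official-symbol occurrence, Kruskal-Wallis/Dunn comparison
    of vocabulary sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
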