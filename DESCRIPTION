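Package: SpliceRewire
Title: Phosphoproteomic Network Rewiring and Exon-Probe Splice Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking phosphoproteomic rewiring to mRNA splicing
    variation across related cell lines. Implements spectral-count based
    phosphosite change scoring (+1/-1 at a fold threshold), per-protein net
    phosphorylation scores, interaction-network cluster summaries and tiered
    keynode identification; a per-gene exon-probe standard-deviation
    statistic of splice variation with binned fold-change summaries,
    rank-sum distribution tests, positional probe profiles and
    hypergeometric gene-set enrichment with Benjamini-Hochberg correction;
    plus synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
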