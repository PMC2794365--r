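Package: relmod
Title: Regulatory-Linkage Module Detection in Segregating Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects regulatory-linkage (ReL) modules from genotype and
    expression data of a segregating population combined with a compendium
    of regulatory-mutant expression signatures. For every (marker,
    signature) pair the package selects an eQTL-likelihood threshold by a
    hypergeometric scan, scores the induced gene split with a Welch t-test
    (Bonferroni corrected), and then extracts modules -- contiguous marker
    intervals paired with signature sets -- by a contiguity-constrained
    iterative signature algorithm with dynamic-programming interval
    optimization. Modules are annotated with target genes, regulatory
    protein scores, process enrichments, telomere flags and putative causal
    regulators, and assessed by column-permutation significance. A
    segregating-cross simulator with planted modules supports calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
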