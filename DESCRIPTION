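Package: pangevo
Title: Pangenome Dynamics, Gene Gain/Loss Parsimony and Selection Metrics
    for Bacterial Genomic Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative evolutionary genomics for bacterial genera at the
    genomic-species level. Delineates species as Markov-cluster components of
    an average-nucleotide-identity (ANI) graph thresholded at the 95%
    intra-species boundary; partitions orthogroup matrices into core,
    soft-core, shell, cloud and unique pangenome fractions and fits the
    Heaps power law to permutation accumulation curves; reconstructs
    ancestral gene content on a fixed rooted species tree by Wagner
    parsimony with unit gain/loss penalties; computes per-orthogroup
    Tajima's D, pairwise Nei-Gojobori dN/dS and Tajima-Nei distances; and
    screens orthogroups for differential selection between species clusters
    with Mann-Whitney U tests and common-language effect sizes. A
    seed-deterministic simulation module generates every input the pipeline
    consumes (gene content evolved along a known tree, planted ANI cluster
    structure, neutral coalescent samples, codon pairs evolved at a known
    dN/dS) so all stages are testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
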