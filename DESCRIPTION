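Package: virocell
Title: Tri-Trophic Phage-Protist-Cyanobacteria Experiment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for controlled co-culture experiments in
    which a marine cyanobacterium (Synechococcus) is exposed to a lytic
    cyanophage and/or a heterotrophic protist. Provides multiplicity-of-
    infection and Poisson infection statistics, predator-prey encounter
    kernels, maximum-likelihood most-probable-number (MPN) titer estimation,
    fast repetition rate fluorometry (FRRf) induction-curve fitting and
    Fv/Fm comparison, time-matched differential analysis of metabolite
    feature tables (log10 fold change with Benjamini-Hochberg FDR) and of
    RNA-seq count matrices (log2RPKM), phage temporal-class assignment, and
    Venn partitioning of significant sets. A synthetic-data generator
    emulates the full factorial study design (4 treatments x 4 replicates x
    6 timepoints) with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
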