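Package: methyldose
Title: Dose-Resolved Differential DNA Methylation Analysis for
    Bisulfite-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing whole-genome bisulfite-sequencing
    methylomes from dose-structured stress experiments in plants.  Reads
    Bismark cytosine reports and coverage files, classifies CG/CHG/CHH
    sequence contexts from a reference, estimates bisulfite conversion
    efficiency from an unmethylated control contig, calls differentially
    methylated cytosines (Fisher's exact test, Benjamini-Hochberg q-values,
    percent-difference filter), builds differentially methylated regions by
    two independent callers (distance merging of DmCs and kernel-smoothed
    t-statistic regions filtered by areaStat), reconciles regions across
    doses, classifies each region's response as dose-independent, positive
    or inverse dose-dependent, associates regions with genes and
    transposable elements within a window, tests term enrichment and
    cross-stress gene-set overlap (expected counts and chi-squared
    independence tests).  A binomial methylome simulator with a planted
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
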