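Package: mircorr
Title: Expression-Correlation-Guided Consensus microRNA Target Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates microRNA target genes from matched miRNA/mRNA
    expression profiles by screening all marker-probe x miRNA Pearson
    correlations, keeping significant negatively correlated pairs, and
    intersecting them with sequence-based target predictions from several
    tools (TargetScan, PicTar, miRDB, microRNA.org), with annotation of
    experimentally validated interactions and 3'UTR binding-site filtering
    on mirSVR and PhastCons scores. Also implements the downstream wet-lab
    quantification arithmetic (2^-ddCt relative expression, densitometric
    relative protein levels, tumor-vs-normal fold changes with unpaired
    t-tests, and the confirmed-target decision rule) and a synthetic-cohort
    generator with planted miRNA->target repression so the operating
    characteristics of the whole screen can be measured without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
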