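Package: panelforge
Title: Rational Design and Evaluation of Cost-Effective Cancer Gene Panels
Version: 0.1.0
Authors@R:
    person("Panelforge", "Developers", email = "maintainer@panelforge.dev",
           role = c("aut", "cre"))
Description: Designs targeted cancer sequencing panels from somatic mutation
    cohorts. Detects mutational hotspots by iterative extraction of maximal
    mutation-count windows of bounded width, ranks candidate panel items
    (whole-gene exomes or hotspots) by greedy maximum marginal coverage of
    the cumulative mutational frequency (CMF), classifies items into three
    tiers by their contribution to the CMF slope, and evaluates designed or
    external panels for cost-effectiveness (cohort coverage versus targeted
    kilobases). Includes mutation and gene annotation against user-supplied
    catalogs, a synthetic-cohort simulator with known ground truth, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
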