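Package: retroburst
Title: LTR-Retrotransposon Detection, Dating and Amplification-Burst Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying long terminal repeat (LTR)
    retrotransposon driven genome expansion in fungi. Simulates genomes with
    LTR-retrotransposon insertions of known age, structurally detects
    full-length elements from terminal-repeat pairs with target-site
    duplications, classifies them into Gypsy/Copia superfamilies (flagging
    Chromoviridae by chromodomain position), dates each element from the
    Kimura two-parameter divergence of its LTR pair using a fungal
    substitution rate, builds amplification-burst age profiles, produces a
    family census (copies, full-length copies, genome coverage), infers a
    neighbor-joining phylogeny of reverse-transcriptase domains with
    bootstrap support, and tests gene-set GO-term enrichment with one-sided
    Fisher exact tests under Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
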