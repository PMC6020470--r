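Package: hmmplace
Title: Banded Profile-HMM Alignment, Phylogenetic Placement, and
    Phylogeny-Based OTU Picking for Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns 16S rRNA-like amplicon reads to a reference multiple
    alignment with a consensus-sequence FM-index (CSFM-index) banded plan7
    profile HMM, places each read on a fixed reference phylogeny with the
    Seed-Estimate-Place (SEP) local placement algorithm under GTR/TN93/HKY85
    substitution models with optional discrete-Gamma rate variation, assigns
    taxonomy with Q-scores, detects chimeric reads by segment-placement
    log-odds, and summarizes placements into phylogeny-based OTUs with
    Dirichlet-consensus representative sequences and a pruned OTU tree.
    Includes simulators for toy reference packages, reads, and chimeras,
    plus the matching evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
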