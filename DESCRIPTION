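Package: remodelscan
Title: Chromatin Remodeling Analysis for MNase-Seq and ChIP-Seq Cell-State
    Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the chromatin landscape of two cell states
    from aligned sequencing tags. Implements nucleosome calling from MNase-seq
    (Gaussian-smoothed dyad histograms with greedy exclusion), nucleosome
    dynamics classification (fixed/shift/loss/gain via one-to-one footprint
    matching), promoter nucleosome-depleted region quantification and its
    coupling to expression, histone-modification state calling in promoters
    (bimodal valley and k-means thresholds, state transitions, fold-change
    clustering, gain-mode classification), enhancer identification from
    H3K4me1 peaks with a two-Gaussian H3K4me3 filter and active/poised/off
    classification against random-background thresholds, enhancer NDR scanning
    with eviction/shift mode labeling, and a promoter-enhancer synergy
    analysis. Ships a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
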