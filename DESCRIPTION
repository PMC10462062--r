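Package: bundlemech
Title: Quantification of Force-Modulated Actin-Binding-Protein Engagement
    of Myosin-Tensed Actin Bundle Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for two-channel TIRF image stacks of
    micropatterned actin filament bundle networks under myosin-generated
    tension. Segments F-actin networks into debranched bundle segments
    (thresholding, skeletonization, 3x3 branch-point filtering, dilation
    to fixed-width masks), measures per-segment ratiometric statistics of
    an actin-binding protein (ABP) channel against the F-actin channel,
    and provides state-wise time averaging, quadrant/regression/Welch
    analyses, paired before/after-ATP comparisons, line-scan bundle
    counting, and paired-filament-complex census summaries. A synthetic
    scene generator embodies a per-filament-load binding model on stripe
    micropatterns and renders noisy two-channel stacks with known ground
    truth, so the whole pipeline is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    survival,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
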