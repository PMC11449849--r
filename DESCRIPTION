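Package: octaq
Title: Quantitative Assessment of Microvasculature in OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for optical coherence tomography
    angiography (OCTA) of soft tissue such as the oral mucosa. Turns
    repeated-frame 4D OCT acquisitions into angiography volumes with an
    eigen-decomposition clutter filter, selects superficial and deep
    depth-of-interest layers automatically from the depth intensity
    profile, binarizes and skeletonizes en face projections, and computes
    vessel area density (VAD), vessel skeleton density (VSD), vessel
    diameter index (VDI) and a diameter-weighted tortuosity index (WTI),
    together with local heatmaps, scan-rescan repeatability statistics and
    cohort summaries. Includes a synthetic vascular phantom generator with
    analytic ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
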