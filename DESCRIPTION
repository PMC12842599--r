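Package: uwbench
Title: Quality-Detection Benchmarking for Underwater Image Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how underwater image enhancement interacts
    with object detection. Implements four no-reference underwater image
    quality metrics (UIQM, UCIQE, CCF, grayscale entropy), a composite
    bounded quality index built by outlier removal, global min-max
    rescaling and equal-weight aggregation, a COCO-style per-image
    mAP 50:95 protocol with greedy IoU matching and 101-point
    precision-recall interpolation, an oracle mixed-set upper bound for
    selective enhancement, and a fully seeded synthetic scenario
    generator that emulates enhancement-detection interactions so the
    whole pipeline can be exercised without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
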