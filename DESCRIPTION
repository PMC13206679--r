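Package: sulba
Title: Cyclic-Shift Data Augmentation and Benchmark Ranking for Medical Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stepwise cyclic-shift data augmentation for 2D and 3D medical
    images: a parameter-free, perfectly reversible, dimension-agnostic index
    permutation along one data axis, with synchronized image/mask support for
    segmentation, probability-gated stochastic application, and lossless
    record/replay provenance. Also provides the benchmark scoring arithmetic
    used to compare augmentation strategies (cumulative scores, relative and
    percentage improvements, confidence intervals, coefficients of variation,
    paired t-tests, training-time overhead), task-standard classification and
    segmentation metrics, deterministic synthetic phantom and fixture
    generators, and a command-line interface with PNG/NIfTI/CSV/JSON I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
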