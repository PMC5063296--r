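Package: pethet
Title: Phantom-Based Selection of Reliable PET Texture Heterogeneity Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing which PET texture heterogeneity parameters are
    reliable enough for clinical radiomics. Simulates three classes of phantom
    experiments (a homogeneous cylinder, a replicated seven-syringe "Revolver"
    insert in a NEMA-IQ-like body, and a dual-isotope C-11/F-18 dynamic series),
    segments lesion-like volumes of interest by SUV thresholding, computes 27
    heterogeneity parameters from grey-level co-occurrence, run-length and
    size-zone matrices after fixed-bin-number resampling, and applies three
    selection criteria: volume independence on concentric spherical VOIs,
    test-retest reproducibility (replicate coefficient of variation) across
    acquisition times and reconstruction settings, and sensitivity to a
    controlled change in heterogeneity. Results are tidy tibbles with
    broom-style tidiers and ggplot2 plot methods.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
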