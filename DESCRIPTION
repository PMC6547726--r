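Package: fretquant
Title: Quantitative Three-Filter FRET Analysis of Protein Interactions in Living Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrated evaluation of sensitized-emission (3-filter) FRET
    measurements of cell populations. Converts background-corrected donor,
    raw-FRET and acceptor channel intensities into spectral
    bleed-through-corrected signals and normalized FRET measures (FRETc,
    FRETN, N_FRET and the calibrated apparent efficiency DFRET), derives the
    calibration factors C1/C2 from a tandem donor-acceptor construct of
    known transfer efficiency, computes acceptor-photobleaching FRET
    efficiencies with correction for donor co-bleaching, acceptor
    photoswitching and incomplete bleaching, simulates binding reactions by
    the law of mass action with an explicit stoichiometry factor, and
    retro-fits per-cell DFRET saturation data to the mass-action model to
    estimate the apparent affinity constant, complex stoichiometry and
    maximal transfer efficiency with standard errors and t statistics.
    Includes synthetic-population, bleach-series and image generators for
    end-to-end validation, pixelwise DFRET maps from multi-channel TIFF
    stacks, and a command-line interface.
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
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    minpack.lm,
    tiff
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
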