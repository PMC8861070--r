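Package: pvrclean
Title: Photovoltaic Artifact Management for Optogenetic Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing photovoltaic-response (PVR) light artifacts from
    multichannel extracellular recordings acquired during aligned optogenetic
    stimulation. Implements pulse detection from photodiode light logs,
    peri-pulse snippet extraction, per-pulse nearest-neighbour template
    subtraction of onset/offset transients, residual-artifact detection with
    blackout-interval bookkeeping, template-matching spike recovery inside
    stimulation windows, and blackout-aware weighted peri-stimulus time
    histograms. Also provides side-emitting fiber optics quantifications
    (Lambertian emission fits, cylindrical power densities, connector grid
    addressability, PVR-matched intensity ratios), bootstrap estimation of
    optogenetic inhibition latency, pre-inhibition split analyses, and a fully
    ground-truthed synthetic session generator for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
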