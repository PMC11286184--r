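Package: celltribo
Title: Friction and Damage Analysis for Cell Monolayers on Soft Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in-vitro friction-and-damage experiments on
    endothelial cell monolayers. Turns raw tribometer traces into slope-adjusted
    static and dynamic friction forces (correcting for sample misalignment and
    meniscus-shaped surfaces), quantifies monolayer damage from Hoechst/propidium
    iodide fluorescence image pairs as relative nuclei densities in the slide
    track versus flanking reference areas, and provides a Hertz-based
    monolayer-piercing contact model that explains near-constant track width
    across normal loads. Ships a synthetic-data generator (tribometer traces with
    tilt, meniscus, stick-slip and servo noise; two-channel nuclei micrographs
    with a damaged slide track) so the full pipeline is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
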