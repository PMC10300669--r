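Package: sightline
Title: Line-of-Sight and Viewshed Analysis for Receiver-Array Coverage
    Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes point-to-point line of sight and per-tower Boolean
    viewsheds over digital elevation models, with flat- and curved-Earth
    models, elevated targets, cumulative and subtractive viewshed algebra,
    and an aquatic mode over bathymetry with invalid-region masking.
    Designed for planning and diagnosing telemetry receiver arrays
    (reverse-GPS radio towers, submerged acoustic receivers) where tag
    detection requires simultaneous line of sight to several receivers.
    Reads and writes single-band GeoTIFF rasters and tower tables, exports
    KMZ ground overlays, and ships deterministic synthetic terrain
    generators so every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    geosphere,
    testthat (>= 3.0.0),
    tiff,
    withr,
    xml2
Config/testthat/edition: 3
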