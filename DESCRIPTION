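Package: vinelai
Title: Leaf Area Index Estimation for Vertically Trained Vineyards from
    Below-Canopy Images and NDVI Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates vineyard leaf area index (LAI) from below-canopy RGB
    images taken at the 57.5 degree view angle. Images are segmented into sky
    and vegetation in Hue-Saturation-Brightness space, the gap fraction is
    inverted through the Warren-Wilson light transmittance model, and
    replicate estimates are aggregated to vine and sampling-area level using
    the row geometry (device distance, row spacing, vine spacing). Includes
    the destructive reference computation from leaf fresh weight and specific
    leaf area, the standard agronomic agreement statistics (RRMSE, MAE,
    modelling efficiency, coefficient of residual mass), calibration of
    NDVI rasters into absolute LAI maps from a few in-situ estimates, and a
    Boolean leaf-disk scene generator that renders synthetic canopies with
    known true LAI for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jpeg,
    png,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
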