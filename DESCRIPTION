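Package: swinexpo
Title: Census-Tract Spatial Indices of Exposure to Swine Farming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes three census-tract-level spatial indices of community
    exposure to permitted swine feeding operations: the count of unique
    addresses within a one-mile buffer of any farm, a co-kriged surface of
    log permitted head count and manure-lagoon count summarised by the
    per-tract zonal maximum and normalised to percent of total, and
    permitted head per square mile of tract land area.  Includes ordinary
    co-kriging under a linear model of coregionalization with
    weighted-least-squares semivariogram fitting, planar geometry
    primitives over a GeoJSON/CSV interchange, a synthetic study-region
    generator with plantable spatial and rank-correlation structure, and
    urban/rural-stratified Spearman comparison of the indices against
    generalized vulnerability rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
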