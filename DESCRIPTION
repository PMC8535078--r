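Package: oatmet
Title: Stability Analysis of Multi-Environment Winter Oat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Genotype-by-environment analysis of multi-environment variety
    trials, centred on modified joint regression (Finlay-Wilkinson-type
    bilinear stability model with jointly estimated environmental indices,
    fitted by alternating least squares). Includes grain-quality trait
    derivation for oats (groat content, hullability, roundness, protein from
    nitrogen, grain number, moisture-adjusted yield), windowed aggregation of
    daily weather into seasonal covariates, trait-environment Pearson
    correlation grids with significance stars, principal-component trait
    biplots with per-variety convex hulls, and a seeded simulator of
    randomized-block trial data for calibration and parameter-recovery
    studies. Ships the summary tables of a published UK winter oat trial
    network (4 varieties x 22 environments, harvests 2011-2014) as worked
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
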