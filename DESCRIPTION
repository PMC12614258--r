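Package: ccfdgrid
Title: Longitudinal Grid-Box Quantification of Choriocapillaris Flow Deficits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow deficits (CCFD) on en face
    OCT angiography slabs and tracks them longitudinally with a registered
    grid-box strategy. Implements gamma-optimized attenuation compensation
    with hypertransmission-defect protection, fuzzy C-means global
    thresholding with physiological size filtering, translation
    registration of visits via retinal vasculature, grid tiling with box
    categorization and inclusion rules, minimal-detectable-change flagging,
    and nested random-intercept linear mixed models with Tukey-adjusted
    visit contrasts. Includes a synthetic longitudinal scan generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    png,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
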