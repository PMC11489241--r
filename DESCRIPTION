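Package: ataxcomp
Title: Responsiveness-Weighted Composite Endpoints for Ataxia Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives responsiveness-optimized composite clinical endpoints from
    longitudinal multi-scale item data for spinocerebellar ataxia (SCA) natural
    history cohorts and trials. Items standardized to a common 0-1 range are
    regressed on time from baseline with single-response partial least squares
    (PLS1); items are screened by Variable Importance in Projection (VIP) with a
    clinical-override rule and negative-coefficient removal, and the PLS
    coefficients become the composite weights. Responsiveness is summarized by
    the mean-to-standard-deviation ratio (MSDR) of change from baseline, and the
    composite is validated by weight interchange across cohorts and repeated
    k-fold cross-validation of MSDR bias. Treatment effects in two-arm trials are
    estimated with a mixed model for repeated measures (least-squares means,
    Cohen's d, percent progression avoided, delay in progression), and trial
    sample sizes are computed from MSDR responsiveness with exact noncentral-t
    power. A longitudinal cohort simulator with known latent progression supports
    end-to-end validation without access to restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    nlme,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
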