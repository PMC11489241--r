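# Published reference values from the natural-history derivations of the
# ataxia composite (CRC-SCA and EUROSCA cohorts, all-genotype and SCA3 models)
# and from the 48-week trial evaluation. These are external inputs: the
# patient-level data behind them are restricted, so the package uses them for
# arithmetic that depends only on the printed summaries (percent
# contributions, progression avoided, sample sizes).

reference_csv <- function(name) {
  path <- system.file("extdata", name, package = "ataxcomp", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published composite derivations (item MSDRs, VIPs, weights, contributions)
#'
#' One row per candidate item per derivation model (cohort x genotype group).
#' Items with zero weight were excluded during derivation; `pct_contribution`
#' is the published percent of the total composite weight.
#'
#' @return Data frame `cohort`, `group`, `item_id`, `msdr`, `vip`, `weight`,
#'   `pct_contribution`.
#' @export
reference_models <- function() reference_csv("reference_models.csv")

#' Published overall responsiveness (MSDR) of the composite and f-SARA
#'
#' @return Data frame `cohort`, `group`, `endpoint`, `msdr`.
#' @export
reference_overall_msdrs <- function() reference_csv("reference_overall_msdrs.csv")

#' Published 48-week least-squares mean changes from the trial evaluation
#'
#' Placebo and treated LSM change from baseline (and their difference) on each
#' composite model's scale.
#'
#' @return Data frame `model_cohort`, `model_group`, `quantity`, `lsm`, `se`,
#'   `p_value`.
#' @export
reference_trial_lsm <- function() reference_csv("reference_trial_lsm.csv")

#' Published per-arm sample sizes for f-SARA vs the composite
#'
#' @return Data frame `cohort`, `group`, `power`, `slowing`, `n_fsara`,
#'   `n_composite`.
#' @export
reference_sample_sizes <- function() reference_csv("reference_sample_sizes.csv")

#' Published composite weights for one derivation model
#'
#' Convenience accessor returning the positive published weights as a named
#' vector, ready for [composite_from_weights()].
#'
#' @param cohort `"CRC-SCA"` or `"EUROSCA"`.
#' @param group `"all"` or `"SCA3"`.
#' @return Named numeric weights.
#' @export
reference_weights <- function(cohort = c("CRC-SCA", "EUROSCA"),
                              group = c("all", "SCA3")) {
  cohort <- match.arg(cohort); group <- match.arg(group)
  m <- reference_models()
  m <- m[m$cohort == cohort & m$group == group & m$weight > 0, ]
  stats::setNames(m$weight, m$item_id)
}
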