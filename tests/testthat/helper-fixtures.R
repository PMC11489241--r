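# Small deterministic fixtures shared across test files.

tiny_config <- function() {
  scale_config(list(
    item_definition("fsara_gait", "fsara", 0, 4),
    item_definition("fsara_speech", "fsara", 0, 4, clinical_override = TRUE),
    item_definition("cgi", "cgi", 1, 7)
  ))
}

# hand-built 3-subject cohort on the tiny config: baseline + 12/24 months
tiny_cohort <- function() {
  obs <- expand.grid(subject_id = c("S1", "S2", "S3"),
                     visit_months = c(0, 12, 24),
                     item_id = c("fsara_gait", "fsara_speech", "cgi"),
                     stringsAsFactors = FALSE)
  obs$genotype <- "SCA3"
  base <- c(fsara_gait = 1, fsara_speech = 1, cgi = 4)
  slope <- c(fsara_gait = 1, fsara_speech = 0.5, cgi = 1)  # per 12 months
  subj_off <- c(S1 = 0, S2 = 1, S3 = 0)
  obs$raw_score <- round(base[obs$item_id] + subj_off[obs$subject_id] +
                           slope[obs$item_id] * obs$visit_months / 12)
  ataxia_cohort(obs, tiny_config(), label = "tiny")
}

# quick natural-history cohort + derived model, cached per test run
nh_model_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_natural_history(sim_params(n_subjects = 300, seed = 11))
      an <- filter_analytic_sample(co)
      cache <<- list(cohort = an, model = derive_composite(an))
    }
    cache
  }
})
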