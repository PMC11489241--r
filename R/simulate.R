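# Latent-progression simulator. Each subject carries a latent severity
#   z_i(t) = z_i0 + r_i * t,   r_i ~ N(r_genotype, rate_sd)
# and each scale item reads the latent state through a logistic link with its
# own sensitivity and measurement noise,
#   u_ij(t) = plogis(b_j + lambda_j * z_i(t) + e_ijt),
# discretized to the item's ordinal grid. CGI-I instead rates the change
# z_i(t) - z_i(0), mapped monotonically onto the 1-7 grid. Items therefore
# differ in responsiveness (lambda_j relative to noise_sd_j), which is exactly
# the property the downstream PLS derivation must detect.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default item measurement profiles for the simulator
#'
#' Per-item sensitivity (slope of the logistic link on the latent severity),
#' measurement noise SD, and intercept offset. Sensitivity/noise ratios are
#' well separated (sitting least responsive, CGI most) so that the composite
#' derivation has a true ranking to recover; offsets reproduce typical
#' ambulatory baseline severities.
#'
#' @return Data frame `item_id`, `sensitivity`, `noise_sd`, `offset`.
#' @export
default_item_profiles <- function() {
  data.frame(
    item_id = c("fsara_gait", "fsara_stance", "fsara_sitting", "fsara_speech",
                "fars_func", "cgi"),
    sensitivity = c(1.00, 0.90, 0.45, 0.70, 0.85, 1.30),
    noise_sd = c(0.28, 0.30, 0.40, 0.33, 0.25, 0.28),
    offset = c(-0.51, -0.73, -1.95, -1.55, -0.13, 0),
    stringsAsFactors = FALSE
  )
}

#' Parameters for natural-history cohort simulation
#'
#' Defaults emulate an observational SCA natural-history study: ~500 subjects
#' with a CRC-SCA-like genotype mix, annual visits to 24 months, approximately
#' linear latent decline with genotype-specific rates, and item responsiveness
#' spanning the range reported for f-SARA/FARS-FUNC/CGI items.
#'
#' @param n_subjects Number of subjects.
#' @param genotype_mix Named proportions per genotype (must sum to 1).
#' @param baseline_severity_mean,baseline_severity_sd Latent baseline
#'   distribution.
#' @param progression_rate_per_month Named latent progression rate per genotype
#'   (latent units/month, >= 0).
#' @param rate_sd_per_month Between-subject SD of the individual progression
#'   rate.
#' @param item_profiles Data frame `item_id`, `sensitivity`, `noise_sd`,
#'   `offset` for the non-CGI items plus a `cgi` row whose sensitivity scales
#'   the latent change onto the CGI grid.
#' @param visit_schedule_months Visit times in months (must include 0).
#' @param dropout_prob_per_visit Probability a post-baseline visit is missing
#'   (missing completely at random, per visit).
#' @param seed Integer seed; every generator call is a pure function of its
#'   parameters and this seed.
#' @param config Scale configuration (default [default_scale_config()]).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 500,
                       genotype_mix = c(SCA1 = 0.185, SCA2 = 0.20, SCA3 = 0.36,
                                        SCA6 = 0.225, SCA8 = 0.02, SCA10 = 0.01),
                       baseline_severity_mean = 0,
                       baseline_severity_sd = 1,
                       progression_rate_per_month = c(SCA1 = 0.055, SCA2 = 0.040,
                                                      SCA3 = 0.045, SCA6 = 0.026,
                                                      SCA7 = 0.042, SCA8 = 0.035,
                                                      SCA10 = 0.030),
                       rate_sd_per_month = 0.010,
                       item_profiles = default_item_profiles(),
                       visit_schedule_months = c(0, 12, 24),
                       dropout_prob_per_visit = 0.10,
                       seed = 1L,
                       config = default_scale_config()) {
  if (abs(sum(genotype_mix) - 1) > 1e-8 || any(genotype_mix < 0)) {
    stop("genotype_mix must be nonnegative proportions summing to 1", call. = FALSE)
  }
  if (any(progression_rate_per_month < 0)) {
    stop("progression rates must be >= 0", call. = FALSE)
  }
  if (any(item_profiles$noise_sd < 0) || any(item_profiles$sensitivity < 0)) {
    stop("item sensitivities and noise sds must be >= 0", call. = FALSE)
  }
  if (rate_sd_per_month < 0) stop("rate_sd_per_month must be >= 0", call. = FALSE)
  if (!0 %in% visit_schedule_months) {
    stop("visit_schedule_months must include baseline (0)", call. = FALSE)
  }
  if (dropout_prob_per_visit < 0 || dropout_prob_per_visit >= 1) {
    stop("dropout_prob_per_visit must be in [0, 1)", call. = FALSE)
  }
  miss <- setdiff(names(genotype_mix), names(progression_rate_per_month))
  if (length(miss)) {
    stop("no progression rate for genotype(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 genotype_mix = genotype_mix,
                 baseline_severity_mean = baseline_severity_mean,
                 baseline_severity_sd = baseline_severity_sd,
                 progression_rate_per_month = progression_rate_per_month,
                 rate_sd_per_month = rate_sd_per_month,
                 item_profiles = item_profiles,
                 visit_schedule_months = sort(unique(visit_schedule_months)),
                 dropout_prob_per_visit = dropout_prob_per_visit,
                 seed = as.integer(seed),
                 config = config),
            class = "sim_params")
}

#' Parameters for two-arm trial simulation
#'
#' Extends [sim_params()] with a treated arm whose latent progression slope is
#' `(1 - slowing_fraction)` times the placebo slope. The default visit schedule
#' follows a 48-week trial (baseline and weeks 8, 24, 48); weeks are converted
#' to months at 12/52 months per week. The default genotype is SCA3 alone,
#' matching the subgroup in which trial effects are evaluated.
#'
#' @inheritParams sim_params
#' @param n_per_arm Subjects per arm (1:1 allocation).
#' @param slowing_fraction Fraction s in `[0, 1]` by which treatment slows
#'   progression; s = 1 halts it.
#' @param visit_schedule_weeks Trial visit weeks (must include 0).
#' @param ... Passed to [sim_params()].
#' @return An object of class `trial_params` (inherits `sim_params`).
#' @export
trial_params <- function(n_per_arm = 100,
                         slowing_fraction = 0.5,
                         visit_schedule_weeks = c(0, 8, 24, 48),
                         genotype_mix = c(SCA3 = 1),
                         dropout_prob_per_visit = 0.05,
                         ...) {
  if (n_per_arm < 2) stop("n_per_arm must be at least 2", call. = FALSE)
  if (slowing_fraction < 0 || slowing_fraction > 1) {
    stop("slowing_fraction must be in [0, 1]", call. = FALSE)
  }
  p <- sim_params(n_subjects = 2L * n_per_arm, genotype_mix = genotype_mix,
                  visit_schedule_months = weeks_to_months(visit_schedule_weeks),
                  dropout_prob_per_visit = dropout_prob_per_visit, ...)
  p$n_per_arm <- as.integer(n_per_arm)
  p$slowing_fraction <- slowing_fraction
  p$visit_schedule_weeks <- sort(unique(visit_schedule_weeks))
  class(p) <- c("trial_params", "sim_params")
  p
}

#' Convert trial weeks to months
#'
#' Uses the 12/52 months-per-week convention, so week 48 is ~11.08 months.
#'
#' @param weeks Numeric vector of weeks.
#' @return Months.
#' @export
weeks_to_months <- function(weeks) weeks * 12 / 52

# Item scores for a block of subjects. latent: n x v matrix of z_i(t);
# returns long data.frame.
simulate_items <- function(subject_id, genotype, arm, latent, visit_months,
                           params) {
  prof <- params$item_profiles
  cfg <- params$config
  n <- nrow(latent); v <- ncol(latent)
  out <- vector("list", nrow(prof))
  for (j in seq_len(nrow(prof))) {
    id <- prof$item_id[j]
    it <- cfg$items[[id]]
    if (is.null(it)) stop("item profile '", id, "' not in scale config", call. = FALSE)
    steps <- it$max_score - it$min_score
    if (identical(it$scale_id, "cgi")) {
      # clinician-rated global change relative to baseline, midpoint = no change
      delta <- latent - latent[, 1L]
      eps <- matrix(stats::rnorm(n * v, 0, prof$noise_sd[j]), n, v)
      eps[, 1L] <- 0  # baseline CGI is the imputed no-change value exactly
      raw <- round(cfg$cgi_baseline_value + prof$sensitivity[j] * (delta + eps))
      raw <- pmin(pmax(raw, it$min_score), it$max_score)
    } else {
      eps <- matrix(stats::rnorm(n * v, 0, prof$noise_sd[j]), n, v)
      u <- stats::plogis(prof$offset[j] + prof$sensitivity[j] * latent + eps)
      raw <- it$min_score + round(u * steps)
    }
    out[[j]] <- data.frame(
      subject_id = rep(subject_id, v),
      genotype = rep(genotype, v),
      arm = rep(arm, v),
      visit_months = rep(visit_months, each = n),
      item_id = id,
      raw_score = as.vector(raw),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

apply_dropout <- function(obs, subject_id, visit_months, p) {
  if (p <= 0) return(obs)
  post <- visit_months[visit_months > 0]
  drop <- expand.grid(subject_id = subject_id, visit_months = post,
                      stringsAsFactors = FALSE)
  drop <- drop[stats::runif(nrow(drop)) < p, , drop = FALSE]
  if (!nrow(drop)) return(obs)
  key <- paste(obs$subject_id, obs$visit_months)
  obs[!key %in% paste(drop$subject_id, drop$visit_months), , drop = FALSE]
}

#' Simulate a natural-history cohort
#'
#' Generates item-level longitudinal observations under the latent linear
#' progression model described in [sim_params()]. Output is deterministic for a
#' fixed parameter set (including the seed).
#'
#' @param params A [sim_params()] object.
#' @return An [ataxia_cohort()] with `true_params` attached for
#'   parameter-recovery checks.
#' @export
generate_natural_history <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  run_with_seed(params$seed, {
    n <- params$n_subjects
    vm <- params$visit_schedule_months
    genotype <- sample(names(params$genotype_mix), n, replace = TRUE,
                       prob = params$genotype_mix)
    z0 <- stats::rnorm(n, params$baseline_severity_mean,
                       params$baseline_severity_sd)
    rate <- stats::rnorm(n, params$progression_rate_per_month[genotype],
                         params$rate_sd_per_month)
    latent <- z0 + outer(rate, vm)
    obs <- simulate_items(sprintf("NH%04d", seq_len(n)), genotype,
                          NA_character_, latent, vm, params)
    obs <- apply_dropout(obs, sprintf("NH%04d", seq_len(n)), vm,
                         params$dropout_prob_per_visit)
    out <- ataxia_cohort(obs, params$config, label = "synthetic natural history")
    out$true_params <- params
    out
  })
}

#' Simulate a two-arm randomized trial
#'
#' Placebo subjects progress at their genotype's natural-history rate; treated
#' subjects at `(1 - slowing_fraction)` times that rate. Arms are balanced and
#' the output is deterministic per seed.
#'
#' @param params A [trial_params()] object.
#' @return An [ataxia_cohort()] with `arm` labels (`"placebo"`, `"treated"`)
#'   and `true_params` attached.
#' @export
generate_trial <- function(params) {
  stopifnot(inherits(params, "trial_params"))
  run_with_seed(params$seed, {
    n <- 2L * params$n_per_arm
    vm <- params$visit_schedule_months
    genotype <- sample(names(params$genotype_mix), n, replace = TRUE,
                       prob = params$genotype_mix)
    arm <- rep(c("placebo", "treated"), each = params$n_per_arm)
    arm <- arm[sample.int(n)]  # randomized allocation, balanced
    z0 <- stats::rnorm(n, params$baseline_severity_mean,
                       params$baseline_severity_sd)
    rate <- stats::rnorm(n, params$progression_rate_per_month[genotype],
                         params$rate_sd_per_month)
    rate <- pmax(rate, 0) * ifelse(arm == "treated",
                                   1 - params$slowing_fraction, 1)
    latent <- z0 + outer(rate, vm)
    ids <- sprintf("TR%04d", seq_len(n))
    obs <- simulate_items(ids, genotype, arm, latent, vm, params)
    obs <- apply_dropout(obs, ids, vm, params$dropout_prob_per_visit)
    out <- ataxia_cohort(obs, params$config, label = "synthetic trial")
    out$true_params <- params
    out
  })
}
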