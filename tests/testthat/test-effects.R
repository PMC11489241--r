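test_that("progression avoided reproduces the published LSM arithmetic", {
  lsm <- reference_trial_lsm()
  pick <- function(cohort, group, what) {
    lsm$lsm[lsm$model_cohort == cohort & lsm$model_group == group &
              lsm$quantity == what]
  }
  expect_equal(round(progression_avoided(pick("CRC-SCA", "all", "placebo"),
                                         pick("CRC-SCA", "all", "treated"))), 75)
  expect_equal(round(progression_avoided(pick("EUROSCA", "all", "placebo"),
                                         pick("EUROSCA", "all", "treated"))), 82)
  expect_equal(round(progression_avoided(pick("CRC-SCA", "SCA3", "placebo"),
                                         pick("CRC-SCA", "SCA3", "treated"))), 80)
  expect_equal(round(progression_avoided(pick("EUROSCA", "SCA3", "placebo"),
                                         pick("EUROSCA", "SCA3", "treated"))), 87)
  expect_equal(progression_avoided(3.2, 0), 100)
  # scale invariance
  expect_equal(progression_avoided(7 * 3.6254, 7 * 0.9001),
               progression_avoided(3.6254, 0.9001))
  expect_error(progression_avoided(0, 1), "positive")
})

test_that("Cohen's d is the difference standardized by the change SD", {
  expect_equal(cohens_d(0, 2), 0)
  expect_equal(cohens_d(1, 2), 0.5)
  expect_error(cohens_d(1, 0), "positive")
})

test_that("delay in progression inverts the placebo trajectory", {
  # linear trajectory reaching 4 at 12 months; treated at 1 -> crossed at 3
  expect_equal(delay_in_progression(c(0, 12), c(0, 4), 1), 9)
  expect_equal(delay_in_progression(c(0, 12), c(0, 4), 4), 0)
  expect_equal(delay_in_progression(c(0, 12), c(0, 4), 0), 12)
  expect_warning(d <- delay_in_progression(c(0, 12), c(0, 4), 5), "beyond")
  expect_equal(d, 0)
  # convex trajectory: cross-check against dense-grid numeric inversion
  tt <- c(0, 1.85, 5.5, 11.1)
  yy <- c(0, 0.5, 1.5, 4)
  target <- 0.9
  grid <- seq(0, 11.1, by = 1e-4)
  t_star_grid <- grid[which(approx(tt, yy, xout = grid)$y >= target)[1]]
  expect_equal(delay_in_progression(tt, yy, target), 11.1 - t_star_grid,
               tolerance = 1e-3)
  # monotone: delay nonincreasing in the treated final value, bounded by follow-up
  finals <- seq(0, 4, by = 0.5)
  delays <- vapply(finals, function(f) delay_in_progression(tt, yy, f),
                   numeric(1))
  expect_true(all(diff(delays) <= 0))
  expect_true(all(delays >= 0 & delays <= 11.1))
  expect_error(delay_in_progression(c(0, 12), c(1, 4), 2), "zero change")
  expect_error(delay_in_progression(c(0, 6, 12), c(0, 3, 2), 2), "nondecreasing")
})

test_that("a deterministic trial yields the exact difference with zero SE", {
  cfg <- tiny_config()
  m <- composite_from_weights(c(fsara_gait = 4, fsara_speech = 4))
  # placebo worsens 0.25 units/visit on both items (composite CFB 2, 4, 6);
  # treated worsens half as fast on gait only at final (CFB ... treated flat)
  mk <- function(ids, arm, slope) {
    obs <- expand.grid(subject_id = ids, visit_months = c(0, 3, 6, 12),
                       item_id = c("fsara_gait", "fsara_speech"),
                       stringsAsFactors = FALSE)
    obs$genotype <- "SCA3"; obs$arm <- arm
    obs$raw_score <- obs$visit_months / 12 * slope * 4
    obs
  }
  obs <- rbind(mk(c("P1", "P2", "P3"), "placebo", 1),
               mk(c("T1", "T2", "T3"), "treated", 0.25))
  # raw scores on the 0-4 grid: placebo reaches 4 at 12m, treated 1
  obs$raw_score <- round(obs$raw_score, 6)
  tr <- ataxia_cohort(obs, cfg)
  eff <- suppressWarnings(estimate_effects(tr, m))
  # placebo composite CFB at 12m = 8 * 1 = 8 units... gait+speech both 0->4
  expect_equal(eff$difference, 6, tolerance = 1e-8)
  expect_equal(eff$se, 0, tolerance = 1e-8)
  expect_equal(eff$progression_avoided_pct, 75, tolerance = 1e-6)
})

test_that("treatment effects are recovered from simulated trials", {
  model <- nh_model_cache()$model
  tr <- generate_trial(trial_params(n_per_arm = 200, slowing_fraction = 0.5,
                                    seed = 42))
  eff <- estimate_effects(tr, model)
  expect_equal(eff$progression_avoided_pct / 100, 0.5, tolerance = 0.2)
  expect_lt(eff$p_value, 0.05)
  expect_gt(eff$cohens_d, 0)
  expect_equal(sort(unique(eff$lsm$visit_months)),
               weeks_to_months(c(8, 24, 48)))
  expect_true(eff$delay_months > 0 && eff$delay_months < eff$followup_months)
})

test_that("null trials show no systematic treatment effect", {
  model <- nh_model_cache()$model
  pvals <- vapply(1:25, function(s) {
    tr <- generate_trial(trial_params(n_per_arm = 50, slowing_fraction = 0,
                                      seed = 8000 + s))
    suppressWarnings(estimate_effects(tr, model)$p_value)
  }, numeric(1))
  # p-values roughly uniform: no more than a handful significant at 0.05
  expect_lte(sum(pvals < 0.05), 5)
  expect_gt(mean(pvals), 0.25)
})

test_that("single-arm input is rejected", {
  model <- nh_model_cache()$model
  tr <- generate_trial(trial_params(n_per_arm = 20, seed = 1))
  o <- tr$observations
  solo <- ataxia_cohort(o[o$arm == "placebo", ], tr$config)
  expect_error(estimate_effects(solo, model), "two arms")
})
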