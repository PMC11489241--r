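test_that("percent contributions reproduce published weight arithmetic", {
  w_crc <- c(5.0057, 8.7293, 4.7659, 3.8264, 11.4228)
  expect_equal(round(percent_contributions(w_crc), 2),
               c(14.83, 25.86, 14.12, 11.34, 33.85))
  w_eur <- c(6.1773, 8.3214, 5.2110, 3.9369, 26.7503)
  expect_equal(round(percent_contributions(w_eur)[5], 2), 53.08)
  expect_equal(percent_contributions(c(1, 1, 1, 1)), c(25, 25, 25, 25))
  expect_equal(sum(percent_contributions(runif(7, 0.1, 5))), 100)
  expect_error(percent_contributions(c(1, 0)), "positive")
  expect_error(percent_contributions(c(1, -2)), "positive")
})

test_that("composite scoring is the weighted sum of unit scores", {
  m <- composite_from_weights(c(fsara_gait = 5.0057, fars_func = 8.7293,
                                fsara_stance = 4.7659, fsara_speech = 3.8264,
                                cgi = 11.4228))
  u0 <- setNames(rep(0, 5), m$items)
  u1 <- setNames(rep(1, 5), m$items)
  uh <- setNames(rep(0.5, 5), m$items)
  expect_equal(score_composite(u0, m), 0)
  expect_equal(score_composite(u1, m), 33.7501)
  expect_equal(score_composite(uh, m), 33.7501 / 2)
  expect_error(score_composite(u1[-2], m), "fars_func")
  # matrix input, order-invariant
  mat <- rbind(u0, u1[sample(names(u1))])
  expect_equal(unname(score_composite(mat[, rev(m$items)], m)),
               c(0, 33.7501))
})

test_that("derivation retains the driving item and explains all removals", {
  cache <- nh_model_cache()
  m <- cache$model
  expect_true(all(m$weights > 0))
  expect_equal(sum(m$percent_contribution), 100, tolerance = 0.01)
  # every excluded candidate appears in the removal log
  candidates <- intersect(names(cache$cohort$config$items),
                          unique(cache$cohort$observations$item_id))
  excluded <- setdiff(candidates, m$items)
  expect_setequal(m$removal_log$item, excluded)
  expect_true(all(m$removal_log$reason %in%
                    c("negative_coefficient", "vip_below_threshold")))
  # CGI measures change directly, so it must dominate the weighting
  expect_identical(names(which.max(m$weights)), "cgi")
})

test_that("derivation is idempotent on its own retained set", {
  cache <- nh_model_cache()
  m <- cache$model
  m2 <- derive_composite(cache$cohort, candidates = m$items,
                         config = composite_config(a_fixed = m$n_components))
  expect_equal(m2$weights[m$items], m$weights, tolerance = 1e-10)
  expect_identical(nrow(m2$removal_log), 0L)
})

test_that("derived weights are invariant to candidate ordering", {
  cache <- nh_model_cache()
  candidates <- intersect(names(cache$cohort$config$items),
                          unique(cache$cohort$observations$item_id))
  m1 <- derive_composite(cache$cohort, candidates)
  m2 <- derive_composite(cache$cohort, rev(candidates))
  expect_equal(m2$weights[m1$items], m1$weights, tolerance = 1e-10)
})

test_that("near-threshold items survive only with the clinical override", {
  cache <- nh_model_cache()
  # raise the cutoff so mid-VIP items fall inside the near band, then check
  # that only override-flagged items with enough contribution survive
  m <- derive_composite(cache$cohort,
                        config = composite_config(vip_threshold = 0.9,
                                                  vip_near = 0.45))
  flagged <- names(which(vapply(cache$cohort$config$items, `[[`, logical(1),
                                "clinical_override")))
  low <- names(m$vip)[!is.na(m$vip) & m$vip <= 0.9]
  survivors <- intersect(low, m$items)
  expect_true(all(survivors %in% flagged))
  for (s in survivors) {
    expect_gte(m$vip[s], 0.45)
    expect_gt(m$percent_contribution[s], 5)
  }
  # without any override eligibility the same items are removed
  cfg2 <- cache$cohort$config
  for (i in seq_along(cfg2$items)) cfg2$items[[i]]$clinical_override <- FALSE
  co2 <- ataxia_cohort(cache$cohort$observations, cfg2, label = "no override")
  m2 <- derive_composite(co2, config = composite_config(vip_threshold = 0.9,
                                                        vip_near = 0.45))
  expect_length(intersect(survivors, m2$items), 0)
})

test_that("derivation recovers the true responsiveness ranking of items", {
  prof <- data.frame(item_id = c("fsara_gait", "fsara_speech", "fsara_sitting"),
                     sensitivity = c(1.3, 0.7, 0.25),
                     noise_sd = c(0.3, 0.3, 0.3),
                     offset = c(-0.5, -0.9, -1.3))
  cfg <- scale_config(list(
    item_definition("fsara_gait", "fsara", 0, 4),
    item_definition("fsara_speech", "fsara", 0, 4),
    item_definition("fsara_sitting", "fsara", 0, 4)))
  co <- generate_natural_history(sim_params(n_subjects = 400, seed = 301,
                                            item_profiles = prof, config = cfg,
                                            dropout_prob_per_visit = 0))
  m <- derive_composite(co, config = composite_config(vip_threshold = 0,
                                                      vip_near = 0))
  expect_identical(names(which.max(m$weights)), "fsara_gait")
})

test_that("composite models serialize to JSON and back", {
  m <- nh_model_cache()$model
  path <- withr::local_tempfile(fileext = ".json")
  write_composite_model(m, path)
  back <- read_composite_model(path)
  expect_equal(back$items, m$items)
  expect_equal(back$weights, m$weights)
  expect_equal(back$vip, m$vip)
  expect_equal(as.data.frame(back$removal_log), m$removal_log)
})

test_that("derivation fails loudly when all candidates are removed", {
  cache <- nh_model_cache()
  expect_error(derive_composite(cache$cohort,
                                config = composite_config(vip_threshold = 3,
                                                          vip_near = 3)),
               "all candidates removed")
  expect_error(derive_composite(cache$cohort, candidates = "cgi"),
               "at least 2")
})
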