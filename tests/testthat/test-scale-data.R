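test_that("standardize_item maps the score range affinely onto [0,1], worst = 1", {
  gait <- item_definition("fsara_gait", "fsara", 0, 4)
  cgi <- item_definition("cgi", "cgi", 1, 7)
  fars <- item_definition("fars_func", "fars_func", 0, 6)
  expect_equal(standardize_item(2, gait), 0.5)
  expect_equal(standardize_item(7, cgi), 1.0)
  expect_equal(standardize_item(0, fars), 0.0)
  # reversed-direction item: best raw (max) maps to 0
  rev <- item_definition("wellbeing", "misc", 0, 10, higher_is_worse = FALSE)
  expect_equal(standardize_item(10, rev), 0)
  expect_equal(standardize_item(0, rev), 1)
  # affine and strictly monotone across the grid
  u <- standardize_item(0:4, gait)
  expect_equal(u, seq(0, 1, by = 0.25))
  expect_true(all(diff(u) > 0))
  expect_error(standardize_item(5, gait), "fsara_gait.*5")
})

test_that("SARA to f-SARA mapping is monotone and preserves endpoints", {
  cfg <- default_scale_config()
  expect_identical(map_sara_to_fsara(0, "fsara_gait", cfg), 0L)
  expect_identical(map_sara_to_fsara(8, "fsara_gait", cfg), 4L)
  # proportional default table: 5 * 4/8 = 2.5 rounds up
  expect_identical(map_sara_to_fsara(5, "fsara_gait", cfg), 3L)
  expect_error(map_sara_to_fsara(2, "fars_func", cfg), "no SARA")
  expect_error(map_sara_to_fsara(9, "fsara_gait", cfg), "outside lookup range")
  # composition with standardization is monotone nondecreasing in raw SARA
  for (it in c("fsara_gait", "fsara_stance", "fsara_sitting", "fsara_speech")) {
    k <- length(cfg$sara_to_fsara[[it]]) - 1L
    u <- standardize_item(map_sara_to_fsara(0:k, it, cfg), cfg$items[[it]])
    expect_true(all(diff(u) >= 0), info = it)
  }
})

test_that("cohort files round-trip exactly and bad input is rejected", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, tiny_config())
  expect_equal(back$observations[, -2], co$observations[, -2])
  expect_equal(back$observations$genotype, co$observations$genotype)

  # unknown item id
  bad <- co$observations
  bad$item_id[1] <- "mystery"
  expect_error(ataxia_cohort(bad, tiny_config()), "mystery")

  # duplicate (subject, visit, item) key
  dup <- rbind(co$observations, co$observations[1, ])
  expect_error(ataxia_cohort(dup, tiny_config()), "duplicate")

  # malformed row reported with its line number
  lines <- readLines(path)
  lines[3] <- sub("^([^,]*),([^,]*),[^,]*", "\\1,\\2,not_a_number", lines[3])
  writeLines(lines, path)
  expect_error(read_cohort(path, tiny_config()), "line 3")
})

test_that("analytic-sample filter enforces gait window, baseline and follow-up completeness", {
  cfg <- tiny_config()
  mk <- function(subject, visits, gait0 = 2, drop_item_at = NULL) {
    obs <- expand.grid(subject_id = subject, visit_months = visits,
                       item_id = names(cfg$items), stringsAsFactors = FALSE)
    obs$genotype <- "SCA3"
    obs$raw_score <- ifelse(obs$item_id == "cgi", 4, 1)
    obs$raw_score[obs$item_id == "fsara_gait" & obs$visit_months == 0] <- gait0
    if (!is.null(drop_item_at)) {
      obs <- obs[!(obs$item_id == drop_item_at$item &
                     obs$visit_months == drop_item_at$visit), ]
    }
    obs
  }
  obs <- rbind(
    mk("ok",        c(0, 24), gait0 = 3),   # retained
    mk("gait0",     c(0, 24), gait0 = 0),   # dropped: baseline gait below window
    mk("base_only", 0),                     # dropped: no follow-up
    mk("incomplete", c(0, 12),              # dropped: missing item at follow-up
       drop_item_at = list(item = "fsara_speech", visit = 12))
  )
  co <- ataxia_cohort(obs, cfg)
  out <- filter_analytic_sample(co, gait_min = 1, gait_max = 7,
                                required_visits = c(12, 24))
  expect_identical(unique(out$observations$subject_id), "ok")
  expect_equal(unname(out$filter_counts), c(1L, 3L))

  no_gait <- ataxia_cohort(obs[obs$item_id != "fsara_gait", ],
                           scale_config(cfg$items[-1]))
  expect_error(filter_analytic_sample(no_gait), "gait")
})

test_that("scale configuration validates ranges and survives YAML round-trip", {
  expect_error(item_definition("x", "s", 4, 4), "max_score")
  expect_error(scale_config(list(item_definition("a", "s", 0, 1),
                                 item_definition("a", "s", 0, 2))),
               "duplicate")
  expect_error(scale_config(list(item_definition("cgi", "cgi", 1, 7)),
                            cgi_baseline_value = 9),
               "outside CGI range")
  expect_error(scale_config(list(item_definition("g", "fsara", 0, 4)),
                            sara_to_fsara = list(g = c(0, 2, 1))),
               "monotone")
  cfg <- default_scale_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scale_config(cfg, path)
  back <- read_scale_config(path)
  expect_equal(names(back$items), names(cfg$items))
  expect_equal(back$sara_to_fsara, lapply(cfg$sara_to_fsara, as.numeric))
  expect_equal(back$cgi_baseline_value, cfg$cgi_baseline_value)
})
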