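#' Percent of disease progression avoided by treatment
#'
#' Defined as `100 * (placebo LSM - treated LSM) / placebo LSM` at the final
#' visit, where the LSMs are least-squares mean changes from baseline. The
#' metric is invariant to rescaling both LSMs, so it does not depend on the
#' overall scale of the composite weights.
#'
#' @param lsm_placebo Placebo least-squares mean change from baseline (> 0).
#' @param lsm_treated Treated least-squares mean change from baseline.
#' @return Percentage.
#' @export
progression_avoided <- function(lsm_placebo, lsm_treated) {
  if (!is.finite(lsm_placebo) || lsm_placebo <= 0) {
    stop("progression avoided undefined: placebo LSM must be positive",
         call. = FALSE)
  }
  100 * (lsm_placebo - lsm_treated) / lsm_placebo
}

#' Cohen's d for a treatment difference
#'
#' @param lsm_difference Least-squares mean difference (placebo - treated).
#' @param sd_change Pooled standard deviation of the final-visit change from
#'   baseline across arms (> 0).
#' @return Standardized effect size d.
#' @export
cohens_d <- function(lsm_difference, sd_change) {
  if (!is.finite(sd_change) || sd_change <= 0) {
    stop("Cohen's d undefined: sd_change must be positive", call. = FALSE)
  }
  lsm_difference / sd_change
}

#' Delay in progression implied by a placebo trajectory
#'
#' Finds the earliest time at which the piecewise-linear placebo mean
#' trajectory reaches the treated arm's final change from baseline; the delay
#' is the follow-up duration minus that time. The trajectory must start at 0
#' change and be nondecreasing.
#'
#' @param placebo_times Visit times (months), starting at 0.
#' @param placebo_cfb Placebo LSM change from baseline at those times
#'   (`placebo_cfb[1] == 0`, nondecreasing).
#' @param treated_final Treated LSM change from baseline at the final visit.
#' @param followup_months Follow-up duration; defaults to the last placebo
#'   time.
#' @return Delay in months (0 with a warning when the treated arm progressed
#'   at least as much as placebo).
#' @export
delay_in_progression <- function(placebo_times, placebo_cfb, treated_final,
                                 followup_months = max(placebo_times)) {
  stopifnot(length(placebo_times) == length(placebo_cfb),
            length(placebo_times) >= 2L)
  ord <- order(placebo_times)
  placebo_times <- placebo_times[ord]; placebo_cfb <- placebo_cfb[ord]
  if (placebo_times[1L] != 0 || abs(placebo_cfb[1L]) > 1e-12) {
    stop("placebo trajectory must start at time 0 with zero change",
         call. = FALSE)
  }
  if (is.unsorted(placebo_cfb)) {
    stop("placebo trajectory must be nondecreasing", call. = FALSE)
  }
  if (treated_final > placebo_cfb[length(placebo_cfb)]) {
    warning("treated arm progressed beyond placebo; delay set to 0",
            call. = FALSE)
    return(0)
  }
  if (treated_final <= 0) return(followup_months)
  # earliest crossing of the piecewise-linear trajectory
  i <- which(placebo_cfb >= treated_final)[1L]
  t_star <- if (placebo_cfb[i] == treated_final && i > 1L &&
                placebo_cfb[i - 1L] == treated_final) {
    placebo_times[i - 1L]
  } else if (i == 1L) {
    placebo_times[1L]
  } else {
    t0 <- placebo_times[i - 1L]; t1 <- placebo_times[i]
    y0 <- placebo_cfb[i - 1L]; y1 <- placebo_cfb[i]
    t0 + (treated_final - y0) / (y1 - y0) * (t1 - t0)
  }
  unname(followup_months - t_star)
}

#' Estimate treatment effects on a composite endpoint
#'
#' Fits a mixed model for repeated measures (MMRM) to the composite change
#' from baseline at post-baseline visits: fixed effects for treatment arm,
#' visit, their interaction, and the baseline composite; within-subject
#' correlation across visits is modeled as unstructured with per-visit
#' variances, falling back to compound symmetry and finally to an independent
#' ordinary least squares fit when the covariance estimation does not
#' converge (e.g. tiny or degenerate samples). Least-squares means are
#' computed at the mean baseline; inference for the final-visit difference
#' uses a normal approximation.
#'
#' @param trial An arm-labelled [ataxia_cohort()] from [generate_trial()] or
#'   [read_cohort()] (arms `"placebo"` and one comparator).
#' @param model A [derive_composite()] composite model used for scoring.
#' @param reference_arm Arm treated as control (default `"placebo"`).
#' @return An object of class `effect_estimate`: `lsm` (per arm x visit LSM
#'   CFB with SE), `difference`, `se`, `ci`, `p_value` (final visit),
#'   `sd_change`, `cohens_d`, `progression_avoided_pct`, `delay_months`,
#'   `followup_months`, `covariance` (structure actually used), `n_per_arm`.
#' @export
estimate_effects <- function(trial, model, reference_arm = "placebo") {
  stopifnot(inherits(trial, "ataxia_cohort"), inherits(model, "composite_model"))
  comp <- composite_by_visit(trial, model)
  comp <- comp[!is.na(comp$composite), ]
  arms <- sort(unique(comp$arm[!is.na(comp$arm)]))
  if (length(arms) != 2L || !reference_arm %in% arms) {
    stop("trial must have exactly two arms including '", reference_arm, "'",
         call. = FALSE)
  }
  base <- comp[comp$visit_months == 0,
               c("subject_id", "composite")]
  names(base)[2L] <- "baseline"
  post <- comp[comp$visit_months > 0, ]
  d <- merge(post, base, by = "subject_id")
  d$cfb <- d$composite - d$baseline
  vis_levels <- sort(unique(d$visit_months))
  d$visit <- factor(d$visit_months, levels = vis_levels)
  d$arm <- factor(d$arm, levels = c(reference_arm,
                                    setdiff(arms, reference_arm)))
  d <- d[order(d$subject_id, d$visit_months), ]
  if (nlevels(d$visit) < 1L) stop("no post-baseline visits", call. = FALSE)

  form <- if (stats::var(d$baseline) > 1e-12) {
    cfb ~ baseline + arm * visit
  } else cfb ~ arm * visit  # degenerate: constant baseline carries no information
  fits <- list(
    unstructured = function() nlme::gls(
      form, data = d,
      correlation = nlme::corSymm(form = ~ as.integer(visit) | subject_id),
      weights = nlme::varIdent(form = ~ 1 | visit),
      na.action = stats::na.omit, control = nlme::glsControl(maxIter = 100)),
    compound_symmetry = function() nlme::gls(
      form, data = d,
      correlation = nlme::corCompSymm(form = ~ 1 | subject_id),
      na.action = stats::na.omit),
    independence = function() stats::lm(form, data = d)
  )
  fit <- NULL; structure_used <- NA_character_
  for (nm in names(fits)) {
    fit <- tryCatch(suppressWarnings(fits[[nm]]()), error = function(e) NULL)
    if (!is.null(fit)) { structure_used <- nm; break }
  }
  if (is.null(fit)) stop("MMRM fitting failed under all covariance structures",
                         call. = FALSE)
  if (structure_used != "unstructured") {
    warning("MMRM covariance fell back to ", structure_used, call. = FALSE)
  }
  em <- emmeans::emmeans(fit, ~ arm | visit, mode = "df.error", data = d)
  lsm <- as.data.frame(em)[, c("arm", "visit", "emmean", "SE")]
  names(lsm) <- c("arm", "visit", "lsm_cfb", "se")
  lsm$visit_months <- vis_levels[match(as.character(lsm$visit),
                                       as.character(vis_levels))]

  final_v <- max(lsm$visit_months)
  ctr <- as.data.frame(emmeans::contrast(em, method = "revpairwise",
                                         by = "visit"))
  # placebo - treated at each visit, sign such that positive favors treatment
  ctr$visit_months <- vis_levels[match(as.character(ctr$visit),
                                       as.character(vis_levels))]
  fin <- ctr[ctr$visit_months == final_v, ]
  diff_est <- -fin$estimate  # revpairwise gives treated - placebo
  diff_se <- fin$SE
  z <- diff_est / diff_se
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  ci <- diff_est + c(-1, 1) * stats::qnorm(0.975) * diff_se

  lsm_p <- lsm$lsm_cfb[lsm$arm == reference_arm]
  names(lsm_p) <- lsm$visit_months[lsm$arm == reference_arm]
  lsm_t_final <- lsm$lsm_cfb[lsm$arm != reference_arm &
                               lsm$visit_months == final_v]
  # pooled observed SD of final-visit CFB across arms
  fin_d <- d[d$visit_months == final_v, ]
  v_by_arm <- tapply(fin_d$cfb, fin_d$arm, stats::var)
  n_by_arm <- tapply(fin_d$cfb, fin_d$arm, length)
  sd_change <- sqrt(sum((n_by_arm - 1) * v_by_arm) / (sum(n_by_arm) - 2))

  lsm_p_final <- unname(lsm_p[as.character(final_v)])
  pa <- if (lsm_p_final > 0) progression_avoided(lsm_p_final, lsm_t_final)
        else NA_real_
  traj_t <- c(0, sort(unique(lsm$visit_months)))
  traj_y <- c(0, lsm_p[as.character(sort(unique(lsm$visit_months)))])
  delay <- if (!is.unsorted(traj_y)) {
    tryCatch(suppressWarnings(
      delay_in_progression(traj_t, traj_y, lsm_t_final)),
      error = function(e) NA_real_)
  } else NA_real_

  structure(list(lsm = lsm[, c("arm", "visit_months", "lsm_cfb", "se")],
                 difference = diff_est, se = diff_se, ci = ci, p_value = p,
                 sd_change = sd_change,
                 cohens_d = if (sd_change > 0) cohens_d(diff_est, sd_change)
                            else NA_real_,
                 progression_avoided_pct = pa,
                 delay_months = delay,
                 followup_months = final_v,
                 covariance = structure_used,
                 n_per_arm = stats::setNames(as.integer(n_by_arm),
                                             names(n_by_arm))),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate (MMRM, covariance:", x$covariance, ")>\n")
  print(transform(x$lsm, lsm_cfb = round(lsm_cfb, 4), se = round(se, 4)))
  cat(sprintf("final-visit difference %.4f (SE %.4f, 95%% CI %.4f to %.4f, p = %.4g)\n",
              x$difference, x$se, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("Cohen's d %.3f; progression avoided %.1f%%; delay %.1f months\n",
              x$cohens_d, x$progression_avoided_pct, x$delay_months))
  invisible(x)
}
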