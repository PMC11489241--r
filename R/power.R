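#' Exact two-sample t-test power
#'
#' Power of the two-sided, two-sample pooled t-test at equal allocation, from
#' the noncentral t distribution: with n per arm and standardized effect d the
#' noncentrality parameter is `d * sqrt(n / 2)` on `2n - 2` degrees of
#' freedom.
#'
#' @param n_per_arm Subjects per arm (>= 2); vectorized.
#' @param d Standardized effect size (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
ttest_power <- function(n_per_arm, d, alpha = 0.05) {
  if (any(n_per_arm < 2)) stop("n_per_arm must be at least 2", call. = FALSE)
  if (any(d <= 0)) stop("effect size d must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- 2 * n_per_arm - 2
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n_per_arm / 2)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Per-arm sample size from MSDR responsiveness and treatment slowing
#'
#' The detectable standardized effect of a disease-modifying treatment that
#' slows progression by a fraction s is `d = s * MSDR`: the mean change shrinks
#' by s x (placebo mean change) while the SD of change is unchanged. The
#' returned n per arm (1:1 allocation) is the smallest integer whose exact
#' noncentral-t power meets the target.
#'
#' @param msdr Mean-to-standard-deviation ratio of the endpoint's change from
#'   baseline (> 0).
#' @param slowing Fractional slowing of progression in (0, 1].
#' @param power Target power in (0, 1) (default 0.80).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer n per arm.
#' @export
sample_size_per_arm <- function(msdr, slowing, power = 0.80, alpha = 0.05) {
  if (msdr <= 0) stop("msdr must be positive", call. = FALSE)
  if (slowing <= 0 || slowing > 1) stop("slowing must be in (0, 1]", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  d <- slowing * msdr
  # normal-approximation start, then exact noncentral-t refinement
  n <- max(2, floor(2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / d^2) - 2)
  while (ttest_power(n, d, alpha) < power) n <- n + 1
  while (n > 2 && ttest_power(n - 1, d, alpha) >= power) n <- n - 1
  as.integer(n)
}

#' Sample-size grid over endpoints, slowing fractions and power targets
#'
#' @param msdrs Named numeric vector of endpoint MSDRs (names label the
#'   endpoints, e.g. `c(fsara = 0.4826, composite = 0.8276)`).
#' @param slowings Fractional slowings to tabulate (default 0.3 and 0.5).
#' @param powers Target powers (default 0.80 and 0.90).
#' @param alpha Two-sided significance level.
#' @return Data frame of class `power_table` with columns `endpoint`, `msdr`,
#'   `power`, `slowing`, `effect_size` (d), `n_per_arm`.
#' @export
power_table <- function(msdrs, slowings = c(0.3, 0.5), powers = c(0.80, 0.90),
                        alpha = 0.05) {
  if (!length(msdrs) || !length(slowings) || !length(powers)) {
    stop("power_table needs nonempty msdrs, slowings and powers", call. = FALSE)
  }
  if (is.null(names(msdrs))) names(msdrs) <- paste0("endpoint", seq_along(msdrs))
  g <- expand.grid(endpoint = names(msdrs), power = powers, slowing = slowings,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$msdr <- msdrs[g$endpoint]
  g$effect_size <- g$slowing * g$msdr
  g$n_per_arm <- mapply(sample_size_per_arm, g$msdr, g$slowing, g$power,
                        MoreArgs = list(alpha = alpha))
  g <- g[order(g$endpoint, g$power, g$slowing),
         c("endpoint", "msdr", "power", "slowing", "effect_size", "n_per_arm")]
  rownames(g) <- NULL
  class(g) <- c("power_table", "data.frame")
  attr(g, "alpha") <- alpha
  g
}

#' @export
print.power_table <- function(x, ...) {
  cat("Per-arm sample sizes (two-sided alpha ", attr(x, "alpha"),
      ", exact noncentral-t power; d = slowing x MSDR)\n", sep = "")
  print.data.frame(transform(as.data.frame(x),
                             effect_size = round(effect_size, 4)))
  invisible(x)
}
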