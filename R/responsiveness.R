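#' Change from baseline for an item or composite
#'
#' Computes per-subject change from baseline on the unit-score scale (single
#' item) or the composite scale. The follow-up value is, by default, the last
#' available among the configured follow-up visits; subjects without a
#' qualifying follow-up (or with incomplete composite items at it) are skipped
#' and counted.
#'
#' @param cohort An [ataxia_cohort()].
#' @param target An item id (string) or a [derive_composite()] model.
#' @param visits Numeric months that qualify as follow-up (default 12 and 24;
#'   for a 48-week trial use `weeks_to_months(48)`).
#' @param rule `"last_available"` (default) or `"fixed"` (only the single visit
#'   in `visits` qualifies).
#' @return Data frame `subject_id`, `genotype`, `arm`, `visit_months`
#'   (follow-up used), `baseline`, `followup`, `cfb`, with attribute
#'   `n_skipped`.
#' @export
change_from_baseline <- function(cohort, target, visits = c(12, 24),
                                 rule = c("last_available", "fixed")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "ataxia_cohort"))
  if (rule == "fixed" && length(visits) != 1L) {
    stop("rule = 'fixed' needs exactly one follow-up visit", call. = FALSE)
  }
  values <- if (is.character(target)) {
    stopifnot(length(target) == 1L)
    w <- unit_score_table(cohort, target)
    w$value <- w[[target]]
    w
  } else if (inherits(target, "composite_model")) {
    v <- composite_by_visit(cohort, target)
    v$value <- v$composite
    v
  } else {
    stop("target must be an item id or a composite_model", call. = FALSE)
  }
  values <- values[!is.na(values$value), ]
  base <- values[values$visit_months == 0, ]
  fu <- values[values$visit_months %in% visits, ]
  fu <- fu[order(fu$subject_id, -fu$visit_months), ]
  fu <- fu[!duplicated(fu$subject_id), ]  # last available qualifying visit
  m <- merge(base[, c("subject_id", "genotype", "arm", "value")],
             fu[, c("subject_id", "visit_months", "value")],
             by = "subject_id", suffixes = c("_base", "_fu"))
  out <- data.frame(subject_id = m$subject_id, genotype = m$genotype,
                    arm = m$arm, visit_months = m$visit_months,
                    baseline = m$value_base, followup = m$value_fu,
                    cfb = m$value_fu - m$value_base,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(unique(base$subject_id)) - nrow(out)
  out
}

#' Mean-to-standard-deviation ratio (MSDR) of change scores
#'
#' The MSDR is the mean change from baseline divided by the sample standard
#' deviation of the change — identical in form to the standardized response
#' mean, the classic responsiveness index for longitudinal rating scales. The
#' sign of the change is preserved, and the index is invariant to positive
#' rescaling of the measure (so a composite's MSDR does not depend on the
#' overall scale of its weights).
#'
#' @param cfb Numeric change-from-baseline values (or a data frame from
#'   [change_from_baseline()], whose `cfb` column is used), `n >= 2`.
#' @return The MSDR (scalar).
#' @export
msdr <- function(cfb) {
  if (is.data.frame(cfb)) cfb <- cfb$cfb
  cfb <- cfb[!is.na(cfb)]
  if (length(cfb) < 2L) {
    stop("MSDR requires at least 2 change scores", call. = FALSE)
  }
  s <- stats::sd(cfb)
  if (s == 0) stop("MSDR undefined: change scores have zero variance", call. = FALSE)
  mean(cfb) / s
}

#' Responsiveness report for items and a composite
#'
#' @param cohort An [ataxia_cohort()].
#' @param model Optional [derive_composite()] model; when supplied its
#'   composite MSDR (and per retained item) is reported.
#' @param items Item ids to report on; defaults to the model's items, or all
#'   items in the cohort.
#' @param visits,rule Passed to [change_from_baseline()].
#' @return Data frame of class `responsiveness_report` with columns `measure`,
#'   `msdr`, `n`.
#' @export
responsiveness_report <- function(cohort, model = NULL, items = NULL,
                                  visits = c(12, 24),
                                  rule = "last_available") {
  if (is.null(items)) {
    items <- if (!is.null(model)) model$items else
      sort(unique(cohort$observations$item_id))
  }
  one <- function(target, name) {
    cfb <- change_from_baseline(cohort, target, visits = visits, rule = rule)
    data.frame(measure = name,
               msdr = if (nrow(cfb) >= 2L && stats::sd(cfb$cfb) > 0)
                 msdr(cfb) else NA_real_,
               n = nrow(cfb), stringsAsFactors = FALSE)
  }
  rows <- lapply(items, function(it) one(it, it))
  if (!is.null(model)) rows <- c(rows, list(one(model, "composite")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "visits") <- visits
  attr(out, "rule") <- rule
  class(out) <- c("responsiveness_report", "data.frame")
  out
}

#' @export
print.responsiveness_report <- function(x, ...) {
  cat("Responsiveness (MSDR of change from baseline; follow-up: ",
      attr(x, "rule"), " of ", paste(attr(x, "visits"), collapse = "/"),
      " months)\n", sep = "")
  print.data.frame(transform(as.data.frame(x), msdr = round(msdr, 4)))
  invisible(x)
}
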