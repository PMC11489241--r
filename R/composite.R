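#' Derivation thresholds for composite selection
#'
#' @param vip_threshold Items with VIP at or below this are screened out
#'   (Wold-type cutoff; default 0.5).
#' @param vip_near Lower edge of the "approximately at threshold" band: an item
#'   failing the cutoff survives if it carries the clinical-override flag, its
#'   VIP is at least `vip_near`, and it contributes more than
#'   `contribution_min` percent of the total weight (default 0.45).
#' @param contribution_min Minimum percent contribution for override retention
#'   (default 5).
#' @param a_max Largest number of PLS components considered (default 3).
#' @param a_fixed Fix the number of components instead of selecting by
#'   cross-validated PRESS (`NULL` = select).
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(vip_threshold = 0.5, vip_near = 0.45,
                             contribution_min = 5, a_max = 3L,
                             a_fixed = NULL) {
  stopifnot(vip_near <= vip_threshold, contribution_min >= 0, a_max >= 1L)
  structure(list(vip_threshold = vip_threshold, vip_near = vip_near,
                 contribution_min = contribution_min, a_max = as.integer(a_max),
                 a_fixed = if (is.null(a_fixed)) NULL else as.integer(a_fixed)),
            class = "composite_config")
}

#' Percent contribution of each weight to the composite
#'
#' @param weights Positive numeric weights (PLS coefficients of the retained
#'   items).
#' @return Percentages summing to 100.
#' @export
percent_contributions <- function(weights) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("percent contributions require strictly positive weights", call. = FALSE)
  }
  100 * weights / sum(weights)
}

# design matrix for derivation: one row per complete subject-visit, response =
# months from baseline (all visits pooled, including baseline rows at t = 0)
pls_design <- function(cohort, candidates) {
  wide <- unit_score_table(cohort, candidates)
  ok <- !rowSums(is.na(wide[, candidates, drop = FALSE]))
  wide <- wide[ok, , drop = FALSE]
  list(X = as.matrix(wide[, candidates, drop = FALSE]),
       t = wide$visit_months, meta = wide[, 1:4])
}

#' Derive a weighted composite from a longitudinal cohort
#'
#' Runs the full selection loop on the analytic sample: fit PLS1 of time on the
#' candidate unit scores; while any coefficient is nonpositive, drop the most
#' negative item and refit; then screen by VIP, removing items at or below the
#' threshold unless the clinical override applies (flagged item, VIP within the
#' near band, contribution above the minimum); iterate until the retained set
#' is stable. The final PLS coefficients are the composite weights.
#'
#' @param cohort An [ataxia_cohort()], already restricted to the analytic
#'   sample where applicable.
#' @param candidates Character vector of candidate item ids (>= 2); defaults to
#'   every item present in the cohort.
#' @param config A [composite_config()].
#' @return An object of class `composite_model`: retained `items`, positive
#'   `weights`, `vip` for every candidate (at final fit, or at removal for
#'   removed items), `percent_contribution`, `removal_log` (data frame of item
#'   and reason), `n_components`, `config`, `label`, and the final `fit`.
#' @export
derive_composite <- function(cohort, candidates = NULL,
                             config = composite_config()) {
  stopifnot(inherits(cohort, "ataxia_cohort"), inherits(config, "composite_config"))
  if (is.null(candidates)) {
    candidates <- intersect(names(cohort$config$items),
                            unique(cohort$observations$item_id))
  }
  if (length(candidates) < 2L) {
    stop("composite derivation needs at least 2 candidate items", call. = FALSE)
  }
  d <- pls_design(cohort, candidates)
  if (nrow(d$X) < 10L) {
    stop("too few complete subject-visits (", nrow(d$X),
         ") for composite derivation", call. = FALSE)
  }
  override <- vapply(cohort$config$items[candidates], `[[`, logical(1),
                     "clinical_override")
  names(override) <- candidates
  selected <- candidates
  removal <- list()
  vip_all <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  fit <- NULL
  repeat {
    if (length(selected) == 0L) {
      stop("composite derivation failed: all candidates removed (",
           paste(vapply(removal, function(r) paste0(r$item, ":", r$reason),
                        character(1)), collapse = ", "), ")", call. = FALSE)
    }
    A <- if (!is.null(config$a_fixed)) {
      min(config$a_fixed, length(selected))
    } else if (length(selected) == 1L) 1L else {
      as.integer(select_components(d$X[, selected, drop = FALSE], d$t,
                                   A_max = min(config$a_max, length(selected))))
    }
    fit <- suppressWarnings(fit_pls1(d$X[, selected, drop = FALSE], d$t, A))
    beta <- fit$coefficients
    if (any(beta <= 0)) {
      worst <- names(beta)[which.min(beta)]
      vip_try <- tryCatch(compute_vip(fit), error = function(e) NULL)
      if (!is.null(vip_try)) vip_all[names(vip_try)] <- vip_try
      removal[[length(removal) + 1L]] <-
        list(item = worst, reason = "negative_coefficient")
      selected <- setdiff(selected, worst)
      next
    }
    vip <- compute_vip(fit)
    vip_all[names(vip)] <- vip
    contrib <- percent_contributions(beta)
    low <- names(vip)[vip <= config$vip_threshold]
    keep <- low[override[low] & vip[low] >= config$vip_near &
                  contrib[low] > config$contribution_min]
    drop_items <- setdiff(low, keep)
    if (!length(drop_items)) break
    for (it in drop_items) {
      removal[[length(removal) + 1L]] <-
        list(item = it, reason = "vip_below_threshold")
    }
    selected <- setdiff(selected, drop_items)
  }
  weights <- fit$coefficients
  removal_log <- if (length(removal)) {
    data.frame(item = vapply(removal, `[[`, character(1), "item"),
               reason = vapply(removal, `[[`, character(1), "reason"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(item = character(0), reason = character(0))
  }
  structure(list(items = names(weights),
                 weights = weights,
                 vip = vip_all,
                 percent_contribution = percent_contributions(weights),
                 removal_log = removal_log,
                 n_components = fit$A,
                 config = config,
                 label = cohort$label,
                 fit = fit),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model from '%s': %d items, %d PLS component(s)>\n",
              x$label, length(x$items), x$n_components))
  tab <- data.frame(item = x$items,
                    weight = round(x$weights, 4),
                    vip = round(x$vip[x$items], 4),
                    pct_contribution = round(x$percent_contribution, 2))
  rownames(tab) <- NULL
  print(tab)
  if (nrow(x$removal_log)) {
    cat("removed:", paste(x$removal_log$item, "(",
                          x$removal_log$reason, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score the composite for given unit scores
#'
#' The composite is the weighted sum of the retained items' unit scores, so it
#' ranges from 0 (best on every item) to the sum of the weights (worst).
#'
#' @param unit_scores Named numeric vector, or a data frame/matrix with one
#'   column per retained item.
#' @param model A [derive_composite()] result (or any list with `items` and
#'   `weights`).
#' @return Numeric composite score(s); `NA` where any retained item is `NA`.
#' @export
score_composite <- function(unit_scores, model) {
  w <- model$weights
  if (is.null(dim(unit_scores))) {
    miss <- setdiff(model$items, names(unit_scores))
    if (length(miss)) {
      stop("missing retained item(s) in unit_scores: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(sum(w * unit_scores[model$items]))
  }
  m <- as.matrix(as.data.frame(unit_scores))
  miss <- setdiff(model$items, colnames(m))
  if (length(miss)) {
    stop("missing retained item(s) in unit_scores: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  drop(m[, model$items, drop = FALSE] %*% w[model$items])
}

# per subject-visit composite scores (complete-case per visit)
composite_by_visit <- function(cohort, model) {
  wide <- unit_score_table(cohort, model$items)
  wide$composite <- score_composite(wide[, model$items, drop = FALSE], model)
  wide[, c("subject_id", "genotype", "arm", "visit_months", "composite")]
}

#' Write a composite model to JSON
#'
#' @param model A [derive_composite()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composite_model <- function(model, path) {
  out <- list(label = model$label,
              items = model$items,
              weights = as.list(model$weights),
              vip = as.list(model$vip),
              percent_contribution = as.list(model$percent_contribution),
              removal_log = model$removal_log,
              n_components = model$n_components,
              config = unclass(model$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a composite model from JSON
#'
#' @param path Path written by [write_composite_model()].
#' @return A `composite_model` (without the internal PLS fit).
#' @export
read_composite_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(label = raw$label,
                 items = raw$items,
                 weights = unlist(raw$weights),
                 vip = unlist(raw$vip),
                 percent_contribution = unlist(raw$percent_contribution),
                 removal_log = as.data.frame(raw$removal_log),
                 n_components = raw$n_components,
                 config = do.call(composite_config, raw$config[
                   c("vip_threshold", "vip_near", "contribution_min", "a_max")]),
                 fit = NULL),
            class = "composite_model")
}

#' Build a composite model from externally supplied weights
#'
#' Useful for scoring a cohort with published or foreign weights (e.g. during
#' weight-interchange validation).
#'
#' @param weights Named positive numeric vector (names are item ids).
#' @param label Provenance label.
#' @return A `composite_model`.
#' @export
composite_from_weights <- function(weights, label = "external weights") {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be named by item id", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  structure(list(items = names(weights),
                 weights = weights,
                 vip = stats::setNames(rep(NA_real_, length(weights)),
                                       names(weights)),
                 percent_contribution = percent_contributions(weights),
                 removal_log = data.frame(item = character(0),
                                          reason = character(0)),
                 n_components = NA_integer_,
                 config = composite_config(),
                 label = label,
                 fit = NULL),
            class = "composite_model")
}
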