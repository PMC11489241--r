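#' Insert a missing item into a weight set at a fixed share
#'
#' Augments a positive weight set with a new item whose percent contribution is
#' exactly `new_item_share`, leaving the existing weights (and hence their
#' relative proportions) unchanged: with total W, the new weight is
#' `W * c / (1 - c)`.
#'
#' @param weights Named positive weights.
#' @param new_item_share Target fractional share `c` in (0, 1).
#' @param new_item_id Name for the inserted item.
#' @return Augmented named weight vector.
#' @export
redistribute_weights <- function(weights, new_item_share,
                                 new_item_id = "new_item") {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (!is.numeric(new_item_share) || new_item_share <= 0 ||
      new_item_share >= 1) {
    stop("new_item_share must lie strictly between 0 and 1", call. = FALSE)
  }
  w_new <- sum(weights) * new_item_share / (1 - new_item_share)
  out <- c(weights, stats::setNames(w_new, new_item_id))
  out
}

#' Cross-validate a composite by interchanging weights between cohorts
#'
#' Scores a cohort with a composite model derived elsewhere and compares the
#' resulting MSDR with the cohort's own. When the foreign model contains an
#' item the cohort never measured, either drop that item's weight
#' (`policy = "drop_item"`) or, conversely, when the cohort measures an item
#' the foreign model lacks, insert it at a stated share
#' (`policy = "redistribute"`, via [redistribute_weights()]).
#'
#' @param model Foreign [derive_composite()] model whose weights are applied.
#' @param cohort Target [ataxia_cohort()].
#' @param policy `"drop_item"` or `"redistribute"`.
#' @param own_model Optional model derived on `cohort` itself; supplies the
#'   "original" MSDR for comparison.
#' @param insert_item,insert_share Under `"redistribute"`: the item to insert
#'   and its fractional share (e.g. the share it carried in the cohort's own
#'   model).
#' @param visits,rule Follow-up rule passed to [change_from_baseline()].
#' @return A list of class `interchange_result`: `policy`, `weights_used`,
#'   `original_msdr`, `crossvalidated_msdr`, `n`.
#' @export
interchange_weights <- function(model, cohort,
                                policy = c("drop_item", "redistribute"),
                                own_model = NULL,
                                insert_item = NULL, insert_share = NULL,
                                visits = c(12, 24), rule = "last_available") {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "composite_model"), inherits(cohort, "ataxia_cohort"))
  cohort_items <- unique(cohort$observations$item_id)
  w <- model$weights
  if (policy == "drop_item") {
    missing <- setdiff(names(w), cohort_items)
    w <- w[setdiff(names(w), missing)]
    if (!length(w)) stop("no model item measured in the cohort", call. = FALSE)
  } else {
    if (is.null(insert_item) || is.null(insert_share)) {
      stop("policy 'redistribute' needs insert_item and insert_share",
           call. = FALSE)
    }
    if (length(insert_item) != 1L) {
      stop("policy 'redistribute' supports exactly one inserted item",
           call. = FALSE)
    }
    leftover <- setdiff(names(w), cohort_items)
    if (length(leftover)) {
      stop("model item(s) not measured in the cohort under 'redistribute': ",
           paste(leftover, collapse = ", "), call. = FALSE)
    }
    w <- redistribute_weights(w, insert_share, insert_item)
  }
  applied <- composite_from_weights(w, label = paste0(model$label,
                                                      " weights on ",
                                                      cohort$label))
  cv <- msdr(change_from_baseline(cohort, applied, visits = visits, rule = rule))
  orig <- if (!is.null(own_model)) {
    msdr(change_from_baseline(cohort, own_model, visits = visits, rule = rule))
  } else NA_real_
  n <- nrow(change_from_baseline(cohort, applied, visits = visits, rule = rule))
  structure(list(source_model = model$label, target_cohort = cohort$label,
                 policy = policy, weights_used = w,
                 original_msdr = orig, crossvalidated_msdr = cv, n = n),
            class = "interchange_result")
}

#' @export
print.interchange_result <- function(x, ...) {
  cat(sprintf("<interchange: '%s' weights on '%s' (%s)>\n", x$source_model,
              x$target_cohort, x$policy))
  cat(sprintf("  original MSDR %.4f, cross-validated MSDR %.4f (n = %d)\n",
              x$original_msdr, x$crossvalidated_msdr, x$n))
  invisible(x)
}

#' Repeated k-fold cross-validation of composite MSDR bias
#'
#' Repeatedly partitions subjects into k folds; for every fold, the composite
#' is re-derived from scratch (full selection loop) on the other k-1 folds and
#' its MSDR computed on both the training and the held-out subjects. The
#' percent bias of an estimate is `100 * (test - train) / train`, so negative
#' values mean the composite is less responsive out of sample.
#'
#' @param cohort An [ataxia_cohort()].
#' @param candidates,config Passed to [derive_composite()].
#' @param k Number of folds (default 5).
#' @param iterations Number of random re-partitions (default 40, giving
#'   `k * iterations` estimates).
#' @param seed Integer seed for the fold allocation.
#' @param visits,rule Follow-up rule for the MSDRs.
#' @return A list of class `kfold_result`: `estimates` (data frame iteration,
#'   fold, n_test, train_msdr, test_msdr, percent_bias), `average_percent_bias`,
#'   `n_failed` (folds where derivation failed, excluded), `k`, `iterations`.
#' @export
kfold_bias <- function(cohort, candidates = NULL, config = composite_config(),
                       k = 5L, iterations = 40L, seed = 1L,
                       visits = c(12, 24), rule = "last_available") {
  stopifnot(inherits(cohort, "ataxia_cohort"), k >= 2L, iterations >= 1L)
  subjects <- unique(cohort$observations$subject_id)
  if (length(subjects) < 2L * k) {
    stop("cohort too small for ", k, "-fold derivation", call. = FALSE)
  }
  o <- cohort$observations
  run_with_seed(seed, {
    rows <- list(); failed <- 0L
    for (it in seq_len(iterations)) {
      fold <- sample(rep_len(seq_len(k), length(subjects)))
      names(fold) <- subjects
      for (f in seq_len(k)) {
        test_subj <- subjects[fold == f]
        train <- ataxia_cohort(o[!o$subject_id %in% test_subj, , drop = FALSE],
                               cohort$config, label = "train")
        test <- ataxia_cohort(o[o$subject_id %in% test_subj, , drop = FALSE],
                              cohort$config, label = "test")
        est <- tryCatch({
          m <- derive_composite(train, candidates, config)
          tr <- msdr(change_from_baseline(train, m, visits = visits, rule = rule))
          te_cfb <- change_from_baseline(test, m, visits = visits, rule = rule)
          te <- msdr(te_cfb)
          data.frame(iteration = it, fold = f, n_test = nrow(te_cfb),
                     train_msdr = tr, test_msdr = te,
                     percent_bias = 100 * (te - tr) / tr)
        }, error = function(e) NULL)
        if (is.null(est)) failed <- failed + 1L else {
          rows[[length(rows) + 1L]] <- est
        }
      }
    }
    estimates <- do.call(rbind, rows)
    structure(list(estimates = estimates,
                   average_percent_bias = mean(estimates$percent_bias),
                   n_failed = failed, k = as.integer(k),
                   iterations = as.integer(iterations)),
              class = "kfold_result")
  })
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("<kfold_result: %d x %d-fold, %d estimates (%d failed)>\n",
              x$iterations, x$k, nrow(x$estimates), x$n_failed))
  cat(sprintf("  average percent bias: %.4f\n", x$average_percent_bias))
  invisible(x)
}
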