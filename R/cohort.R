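#' Construct a longitudinal cohort
#'
#' A cohort holds item-level observations (one row per subject, visit and item)
#' together with the scale configuration used to standardize them. Unit scores
#' are computed from the raw scores via [standardize_item()] unless already
#' supplied.
#'
#' @param observations Data frame with columns `subject_id`, `genotype`,
#'   `visit_months`, `item_id`, `raw_score`, and optionally `arm` (trial arm
#'   label; `NA` for natural-history data) and `unit_score`.
#' @param config A [scale_config()] resolving every `item_id`.
#' @param label Cohort label used in reports.
#' @return An object of class `ataxia_cohort`: a list with elements
#'   `observations`, `config`, `label`.
#' @export
ataxia_cohort <- function(observations, config, label = "cohort") {
  stopifnot(is.data.frame(observations), inherits(config, "scale_config"))
  req <- c("subject_id", "genotype", "visit_months", "item_id", "raw_score")
  miss <- setdiff(req, names(observations))
  if (length(miss)) {
    stop("observations missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  obs$subject_id <- as.character(obs$subject_id)
  obs$genotype <- as.character(obs$genotype)
  obs$item_id <- as.character(obs$item_id)
  obs$visit_months <- as.numeric(obs$visit_months)
  obs$raw_score <- as.numeric(obs$raw_score)
  if (is.null(obs$arm)) obs$arm <- NA_character_
  if (any(!is.finite(obs$visit_months)) || any(obs$visit_months < 0)) {
    stop("visit_months must be finite and >= 0", call. = FALSE)
  }
  unknown <- setdiff(unique(obs$item_id), names(config$items))
  if (length(unknown)) {
    stop("item_id not in scale configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(obs$subject_id, obs$visit_months, obs$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- obs[duplicated(key), , drop = FALSE]
    stop("duplicate (subject, visit, item) observation(s), e.g. subject '",
         d$subject_id[1L], "' visit ", d$visit_months[1L], " item '",
         d$item_id[1L], "'", call. = FALSE)
  }
  if (is.null(obs$unit_score)) {
    obs$unit_score <- NA_real_
    for (id in unique(obs$item_id)) {
      sel <- obs$item_id == id
      obs$unit_score[sel] <- standardize_item(obs$raw_score[sel], config$items[[id]])
    }
  }
  if (any(obs$unit_score < -1e-12 | obs$unit_score > 1 + 1e-12, na.rm = TRUE)) {
    stop("unit_score outside [0, 1]", call. = FALSE)
  }
  cols <- c("subject_id", "genotype", "arm", "visit_months", "item_id",
            "raw_score", "unit_score")
  obs <- obs[order(obs$subject_id, obs$visit_months, obs$item_id), cols]
  rownames(obs) <- NULL
  structure(list(observations = obs, config = config, label = label),
            class = "ataxia_cohort")
}

#' @export
print.ataxia_cohort <- function(x, ...) {
  o <- x$observations
  arms <- unique(o$arm[!is.na(o$arm)])
  cat(sprintf("<ataxia_cohort '%s': %d subjects, %d observations, items: %s>\n",
              x$label, length(unique(o$subject_id)), nrow(o),
              paste(sort(unique(o$item_id)), collapse = ", ")))
  if (length(arms)) cat("  arms:", paste(arms, collapse = ", "), "\n")
  cat("  visits (months):", paste(sort(unique(o$visit_months)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with header
#' `subject_id,genotype,visit_months,item_id,score` and optionally an `arm`
#' column. Scores are standardized on read; malformed rows are reported with
#' their line number and duplicate (subject, visit, item) rows are rejected.
#'
#' @param path Input file path.
#' @param config A [scale_config()].
#' @param label Cohort label; defaults to the file name.
#' @return An [ataxia_cohort()].
#' @export
read_cohort <- function(path, config, label = basename(path)) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("subject_id", "genotype", "visit_months", "item_id", "score")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vm <- suppressWarnings(as.numeric(df$visit_months))
  sc <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(vm) | is.na(sc) | !nzchar(df$subject_id) | !nzchar(df$item_id))
  if (length(bad)) {
    stop("malformed cohort row at line ", bad[1L] + 1L, " of ", path,
         " (non-numeric score/visit or empty key)", call. = FALSE)
  }
  obs <- data.frame(subject_id = df$subject_id, genotype = df$genotype,
                    visit_months = vm, item_id = df$item_id, raw_score = sc,
                    stringsAsFactors = FALSE)
  if (!is.null(df$arm)) obs$arm <- ifelse(nzchar(df$arm), df$arm, NA_character_)
  ataxia_cohort(obs, config, label = label)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: raw scores are written; unit scores are
#' recomputed on read.
#'
#' @param cohort An [ataxia_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ataxia_cohort"))
  o <- cohort$observations
  out <- data.frame(subject_id = o$subject_id, genotype = o$genotype,
                    visit_months = o$visit_months, item_id = o$item_id,
                    score = o$raw_score, arm = ifelse(is.na(o$arm), "", o$arm),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wide unit-score matrix for a cohort
#'
#' Reshapes the long observation table into one row per subject-visit with one
#' column per item (NA where an item was not observed at that visit).
#'
#' @param cohort An [ataxia_cohort()].
#' @param items Character vector of item ids to include; defaults to all items
#'   present in the cohort.
#' @return Data frame with columns `subject_id`, `genotype`, `arm`,
#'   `visit_months`, then one numeric column per item.
#' @export
unit_score_table <- function(cohort, items = NULL) {
  stopifnot(inherits(cohort, "ataxia_cohort"))
  o <- cohort$observations
  if (is.null(items)) items <- sort(unique(o$item_id))
  o <- o[o$item_id %in% items, , drop = FALSE]
  key <- interaction(o$subject_id, o$visit_months, drop = TRUE, lex.order = TRUE)
  wide <- o[!duplicated(key),
            c("subject_id", "genotype", "arm", "visit_months"), drop = FALSE]
  rownames(wide) <- as.character(key[!duplicated(key)])
  for (it in items) {
    sel <- o$item_id == it
    wide[[it]] <- NA_real_
    wide[as.character(key[sel]), it] <- o$unit_score[sel]
  }
  wide <- wide[order(wide$subject_id, wide$visit_months), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' Restrict a cohort to the analytic sample
#'
#' Applies trial-alignment filters before composite derivation: subjects must
#' have a baseline gait severity within the stated raw-score window, complete
#' data on the candidate items at baseline, and complete data at one or more of
#' the required follow-up visits. Subject-visits with any missing candidate item
#' do not count as complete (complete-case per visit).
#'
#' @param cohort An [ataxia_cohort()].
#' @param gait_min,gait_max Inclusive raw-score bounds on the baseline gait item
#'   (defaults 1 and 7, the trial inclusion window on the SARA gait scale; on
#'   the 0-4 f-SARA grid the upper bound is not binding).
#' @param required_visits Numeric months; subjects need complete data at
#'   baseline and at least one of these visits (default 12 and 24).
#' @param items Item ids that must be complete; defaults to every item in the
#'   cohort's configuration.
#' @param gait_item Item id used for the gait restriction; defaults to the first
#'   configured item whose id contains "gait".
#' @return The filtered [ataxia_cohort()], with a `filter_counts` element
#'   recording subjects retained and dropped.
#' @export
filter_analytic_sample <- function(cohort, gait_min = 1, gait_max = 7,
                                   required_visits = c(12, 24),
                                   items = NULL, gait_item = NULL) {
  stopifnot(inherits(cohort, "ataxia_cohort"))
  o <- cohort$observations
  if (is.null(items)) items <- names(cohort$config$items)
  items <- intersect(items, unique(o$item_id))
  if (is.null(gait_item)) {
    gait_item <- grep("gait", names(cohort$config$items), value = TRUE)[1L]
  }
  if (is.na(gait_item) || !gait_item %in% unique(o$item_id)) {
    stop("cohort has no gait item for the analytic-sample restriction",
         call. = FALSE)
  }
  base_gait <- o[o$item_id == gait_item & o$visit_months == 0, ]
  gait_ok <- base_gait$subject_id[base_gait$raw_score >= gait_min &
                                    base_gait$raw_score <= gait_max]
  wide <- unit_score_table(cohort, items)
  complete <- !rowSums(is.na(wide[, items, drop = FALSE]))
  base_ok <- wide$subject_id[complete & wide$visit_months == 0]
  fu_ok <- unique(wide$subject_id[complete & wide$visit_months %in% required_visits])
  keep <- intersect(intersect(gait_ok, base_ok), fu_ok)
  all_subj <- unique(o$subject_id)
  out <- ataxia_cohort(o[o$subject_id %in% keep, , drop = FALSE],
                       cohort$config,
                       label = paste0(cohort$label, " (analytic)"))
  out$filter_counts <- c(retained = length(keep),
                         dropped = length(all_subj) - length(keep))
  out
}
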