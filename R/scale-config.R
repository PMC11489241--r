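#' Define a single rating-scale item
#'
#' An item definition records the scoring range and direction of one item of a
#' clinical rating scale, plus whether the item is eligible for the clinical
#' override used during composite derivation (retention despite a Variable
#' Importance in Projection score just below the cutoff).
#'
#' @param item_id Short unique identifier, e.g. `"fsara_gait"`.
#' @param scale_id Identifier of the parent scale, e.g. `"fsara"`, `"fars_func"`,
#'   `"cgi"`.
#' @param min_score,max_score Integer bounds of the raw score range
#'   (`max_score > min_score`).
#' @param higher_is_worse Logical; `TRUE` when a higher raw score indicates more
#'   severe disease (the usual convention for ataxia scales).
#' @param clinical_override Logical; `TRUE` when the item may be retained under
#'   the near-threshold VIP rule because it is considered clinically essential.
#'
#' @return An object of class `item_definition`.
#' @seealso [scale_config()], [standardize_item()]
#' @export
item_definition <- function(item_id, scale_id, min_score, max_score,
                            higher_is_worse = TRUE, clinical_override = FALSE) {
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id),
            is.character(scale_id), length(scale_id) == 1L,
            is.numeric(min_score), is.numeric(max_score),
            is.logical(higher_is_worse), is.logical(clinical_override))
  if (max_score <= min_score) {
    stop("item '", item_id, "': max_score must exceed min_score", call. = FALSE)
  }
  structure(
    list(item_id = item_id, scale_id = scale_id,
         min_score = as.numeric(min_score), max_score = as.numeric(max_score),
         higher_is_worse = isTRUE(higher_is_worse),
         clinical_override = isTRUE(clinical_override)),
    class = "item_definition"
  )
}

#' @export
print.item_definition <- function(x, ...) {
  cat(sprintf("<item %s (%s): %g-%g, %s%s>\n", x$item_id, x$scale_id,
              x$min_score, x$max_score,
              if (x$higher_is_worse) "higher worse" else "higher better",
              if (x$clinical_override) ", clinical override" else ""))
  invisible(x)
}

#' Assemble a scale configuration
#'
#' A scale configuration collects the item definitions used by a cohort, the
#' per-item lookup tables that rescale raw SARA items onto the 5-point f-SARA
#' grid, and the raw CGI-I value imputed at baseline (CGI-I measures change and
#' has no observed baseline; the "no change" midpoint is the default).
#'
#' @param items List of [item_definition()] objects with unique `item_id`s.
#' @param sara_to_fsara Named list; each element is an integer vector giving the
#'   f-SARA value for SARA raw scores `0:k` of the corresponding f-SARA item.
#'   Each table must be monotone nondecreasing and map into 0-4.
#' @param cgi_baseline_value Integer raw CGI-I score imputed at baseline;
#'   must lie inside the CGI item range when a CGI item is configured.
#'
#' @return An object of class `scale_config`.
#' @export
scale_config <- function(items, sara_to_fsara = list(), cgi_baseline_value = 4L) {
  stopifnot(is.list(items), length(items) >= 1L)
  ok <- vapply(items, inherits, logical(1), "item_definition")
  if (!all(ok)) stop("items must all be item_definition objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) {
    stop("duplicate item_id in configuration: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(items) <- ids
  for (nm in names(sara_to_fsara)) {
    tab <- sara_to_fsara[[nm]]
    if (!is.numeric(tab) || any(is.na(tab))) {
      stop("sara_to_fsara table for '", nm, "' must be numeric and complete",
           call. = FALSE)
    }
    if (is.unsorted(tab)) {
      stop("sara_to_fsara table for '", nm, "' must be monotone nondecreasing",
           call. = FALSE)
    }
    if (any(tab < 0 | tab > 4) || any(tab != round(tab))) {
      stop("sara_to_fsara table for '", nm, "' must map into integers 0-4",
           call. = FALSE)
    }
  }
  cgi <- ids[vapply(items, function(it) identical(it$scale_id, "cgi"), logical(1))]
  if (length(cgi)) {
    it <- items[[cgi[1L]]]
    if (cgi_baseline_value < it$min_score || cgi_baseline_value > it$max_score) {
      stop("cgi_baseline_value ", cgi_baseline_value,
           " outside CGI range [", it$min_score, ", ", it$max_score, "]",
           call. = FALSE)
    }
  }
  structure(list(items = items, sara_to_fsara = sara_to_fsara,
                 cgi_baseline_value = as.integer(cgi_baseline_value)),
            class = "scale_config")
}

#' @export
print.scale_config <- function(x, ...) {
  cat(sprintf("<scale_config: %d items (%s); %d SARA->f-SARA tables; baseline CGI %d>\n",
              length(x$items), paste(names(x$items), collapse = ", "),
              length(x$sara_to_fsara), x$cgi_baseline_value))
  invisible(x)
}

# Proportional SARA -> f-SARA rescaling: round(raw * 4 / sara_max), halves
# rounded up so the map is strictly proportional-monotone. A documented stand-in
# for the published supplementary mapping, which is not reproduced here.
proportional_sara_table <- function(sara_max) {
  as.integer(floor((0:sara_max) * 4 / sara_max + 0.5))
}

#' Default f-SARA / FARS-FUNC / CGI scale configuration
#'
#' The shipped configuration covers the four f-SARA items (gait, stance,
#' sitting, speech; 0-4 each), the FARS functional stage (0-6), and CGI-I
#' (1-7). FARS-FUNC and f-SARA speech carry the clinical-override flag, the two
#' items for which near-threshold retention arises in practice. The SARA to
#' f-SARA mapping defaults to proportional rounding per item
#' (`round(raw * 4 / sara_max)`, SARA gait/stance 0-8, sitting/speech 0-6).
#'
#' @return A [scale_config()] object.
#' @export
default_scale_config <- function() {
  items <- list(
    item_definition("fsara_gait",    "fsara",     0, 4),
    item_definition("fsara_stance",  "fsara",     0, 4),
    item_definition("fsara_sitting", "fsara",     0, 4),
    item_definition("fsara_speech",  "fsara",     0, 4, clinical_override = TRUE),
    item_definition("fars_func",     "fars_func", 0, 6, clinical_override = TRUE),
    item_definition("cgi",           "cgi",       1, 7)
  )
  scale_config(
    items,
    sara_to_fsara = list(
      fsara_gait    = proportional_sara_table(8),
      fsara_stance  = proportional_sara_table(8),
      fsara_sitting = proportional_sara_table(6),
      fsara_speech  = proportional_sara_table(6)
    ),
    cgi_baseline_value = 4L
  )
}

#' Read a scale configuration from YAML or JSON
#'
#' The file holds an `items` list (fields `item_id`, `scale_id`, `min_score`,
#' `max_score`, `higher_is_worse`, `clinical_override`), an optional
#' `sara_to_fsara` mapping of item_id to lookup vector, and an optional
#' `cgi_baseline_value`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scale_config()] object.
#' @export
read_scale_config <- function(path) {
  if (!file.exists(path)) stop("scale config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$items)) stop("scale config must contain an 'items' list", call. = FALSE)
  items <- lapply(raw$items, function(it) {
    item_definition(
      item_id = it$item_id, scale_id = it$scale_id,
      min_score = it$min_score, max_score = it$max_score,
      higher_is_worse = if (is.null(it$higher_is_worse)) TRUE else it$higher_is_worse,
      clinical_override = isTRUE(it$clinical_override)
    )
  })
  scale_config(
    items,
    sara_to_fsara = lapply(raw$sara_to_fsara %||% list(), as.numeric),
    cgi_baseline_value = raw$cgi_baseline_value %||% 4L
  )
}

#' Write a scale configuration to YAML
#'
#' @param config A [scale_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale_config <- function(config, path) {
  stopifnot(inherits(config, "scale_config"))
  out <- list(
    items = lapply(unname(config$items), function(it) {
      list(item_id = it$item_id, scale_id = it$scale_id,
           min_score = it$min_score, max_score = it$max_score,
           higher_is_worse = it$higher_is_worse,
           clinical_override = it$clinical_override)
    }),
    sara_to_fsara = config$sara_to_fsara,
    cgi_baseline_value = config$cgi_baseline_value
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a raw item score to the unit interval
#'
#' Raw scores are mapped affinely onto 0-1 so that 0 is always the best possible
#' state and 1 the worst, regardless of the item's native direction. This puts
#' all candidate items on a common range before PLS regression, so the PLS
#' coefficients are comparable as weights.
#'
#' @param raw_score Numeric vector of raw scores.
#' @param item An [item_definition()].
#' @return Numeric vector of unit scores in `[0, 1]`.
#' @examples
#' gait <- item_definition("fsara_gait", "fsara", 0, 4)
#' standardize_item(2, gait)   # 0.5
#' @export
standardize_item <- function(raw_score, item) {
  stopifnot(inherits(item, "item_definition"), is.numeric(raw_score))
  bad <- !is.na(raw_score) &
    (raw_score < item$min_score | raw_score > item$max_score)
  if (any(bad)) {
    stop("raw score out of range for item '", item$item_id, "': ",
         paste(unique(raw_score[bad]), collapse = ", "),
         " (allowed ", item$min_score, "-", item$max_score, ")", call. = FALSE)
  }
  u <- (raw_score - item$min_score) / (item$max_score - item$min_score)
  if (item$higher_is_worse) u else 1 - u
}

#' Map a raw SARA item score onto the f-SARA grid
#'
#' Looks up the configured per-item rescaling table that carries the first four
#' SARA items (gait, stance, sitting, speech) onto the 5-point f-SARA scoring.
#'
#' @param raw_sara Numeric vector of raw SARA scores (integers within the SARA
#'   item's range).
#' @param item_id f-SARA item identifier with a configured lookup table.
#' @param config A [scale_config()].
#' @return Integer f-SARA scores in 0-4.
#' @export
map_sara_to_fsara <- function(raw_sara, item_id, config) {
  stopifnot(inherits(config, "scale_config"))
  tab <- config$sara_to_fsara[[item_id]]
  if (is.null(tab)) {
    stop("no SARA->f-SARA lookup configured for item '", item_id, "'",
         call. = FALSE)
  }
  bad <- !is.na(raw_sara) &
    (raw_sara < 0 | raw_sara > length(tab) - 1L | raw_sara != round(raw_sara))
  if (any(bad)) {
    stop("SARA raw score outside lookup range for '", item_id, "': ",
         paste(unique(raw_sara[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(tab[raw_sara + 1L])
}
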