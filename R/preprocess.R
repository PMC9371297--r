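#' Item-to-factor mapping with scale bounds
#'
#' @param items Named character vector or list mapping each item column
#'   name to its factor name.
#' @param bounds Data frame with columns `factor`, `scale_min`,
#'   `scale_max`, one row per factor appearing in `items`.
#' @return Object of class `factor_mapping`.
#' @export
factor_mapping <- function(items, bounds) {
  items <- unlist(items)
  if (is.null(names(items)) || any(names(items) == "")) {
    stop("every item must be named")
  }
  if (anyDuplicated(names(items))) stop("items mapped more than once")
  bounds <- as.data.frame(bounds)
  stopifnot(all(c("factor", "scale_min", "scale_max") %in% names(bounds)))
  missing <- setdiff(unique(items), bounds$factor)
  if (length(missing) > 0) {
    stop("no scale bounds for factor(s): ", paste(missing, collapse = ", "))
  }
  structure(list(items = items, bounds = bounds),
            class = "factor_mapping")
}

#' Derive the item-to-factor mapping from a ground-truth spec
#'
#' @param spec A `ground_truth_spec`.
#' @return A `factor_mapping` covering every simulated item column.
#' @export
factor_mapping_from_spec <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  items <- unlist(unname(lapply(spec$item_models, function(m)
    stats::setNames(rep(m$factor, m$n_items),
                    paste0(m$factor, "_", seq_len(m$n_items))))))
  bounds <- do.call(rbind, lapply(spec$item_models, function(m)
    data.frame(factor = m$factor, scale_min = m$scale_min,
               scale_max = m$scale_max, stringsAsFactors = FALSE)))
  rownames(bounds) <- NULL
  factor_mapping(items, bounds)
}

#' Aggregate item responses into factor scores
#'
#' A factor score is the arithmetic mean of the factor's item responses,
#' per respondent. Responses are checked against the instrument's scale
#' bounds; out-of-range values are reported with the item and row.
#' Respondents with a missing value on any mapped item are dropped with a
#' message.
#'
#' @param items Data frame of integer item responses.
#' @param mapping A `factor_mapping`.
#' @return Data frame of factor scores, one column per factor.
#' @export
aggregate_factors <- function(items, mapping) {
  stopifnot(inherits(mapping, "factor_mapping"))
  needed <- names(mapping$items)
  absent <- setdiff(needed, names(items))
  if (length(absent) > 0) {
    stop("missing item column(s): ", paste(absent, collapse = ", "))
  }
  items <- items[needed]
  for (it in needed) {
    f <- mapping$items[[it]]
    b <- mapping$bounds[mapping$bounds$factor == f, ]
    bad <- which(!is.na(items[[it]]) &
                   (items[[it]] < b$scale_min | items[[it]] > b$scale_max))
    if (length(bad) > 0) {
      stop("response out of range [", b$scale_min, ", ", b$scale_max,
           "] for item ", it, " at row ", bad[1])
    }
  }
  keep <- stats::complete.cases(items)
  if (any(!keep)) {
    message("dropping ", sum(!keep),
            " respondent(s) with missing item responses")
    items <- items[keep, , drop = FALSE]
  }
  factors <- unique(unname(mapping$items))
  out <- lapply(factors, function(f) {
    rowMeans(items[, names(mapping$items)[mapping$items == f],
                   drop = FALSE])
  })
  names(out) <- factors
  as.data.frame(out, check.names = FALSE)
}

#' Midpoint thresholds for a mapping's factors
#'
#' @param mapping A `factor_mapping`.
#' @return Named numeric vector of per-factor scale midpoints
#'   `(scale_min + scale_max) / 2`.
#' @export
midpoint_thresholds <- function(mapping) {
  stopifnot(inherits(mapping, "factor_mapping"))
  with(mapping$bounds,
       stats::setNames((scale_min + scale_max) / 2, factor))
}

#' Discretize factor scores into Low/High
#'
#' Scores strictly above the factor's threshold become `"High"`, scores
#' strictly below become `"Low"`, and exact ties go to `tie_rule`
#' (default `"low"`, conservative for negatively-valenced variables).
#'
#' @param scores Data frame of factor scores.
#' @param thresholds Named numeric vector of per-factor cut values; must
#'   cover every score column.
#' @param tie_rule `"low"` or `"high"`: level assigned when a score
#'   equals its threshold.
#' @param bounds Optional data frame (`factor`, `scale_min`,
#'   `scale_max`); when given, thresholds outside a factor's scale range
#'   raise an error.
#' @return Data frame of `"Low"`/`"High"` values, same shape and row
#'   order as `scores`.
#' @export
discretize_scores <- function(scores, thresholds,
                              tie_rule = c("low", "high"),
                              bounds = NULL) {
  tie_rule <- match.arg(tie_rule)
  absent <- setdiff(names(scores), names(thresholds))
  if (length(absent) > 0) {
    stop("no threshold for factor(s): ", paste(absent, collapse = ", "))
  }
  if (!is.null(bounds)) {
    for (f in names(scores)) {
      b <- bounds[bounds$factor == f, ]
      if (nrow(b) == 1 &&
          (thresholds[[f]] < b$scale_min || thresholds[[f]] > b$scale_max)) {
        stop("threshold for ", f, " outside its scale range [",
             b$scale_min, ", ", b$scale_max, "]")
      }
    }
  }
  tie_level <- if (tie_rule == "low") "Low" else "High"
  out <- lapply(names(scores), function(f) {
    s <- scores[[f]]
    ifelse(s > thresholds[[f]], "High",
           ifelse(s < thresholds[[f]], "Low", tie_level))
  })
  names(out) <- names(scores)
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Items-to-network dataset in one step
#'
#' Convenience wrapper: aggregate items into factor scores, then
#' discretize at the scale midpoints (or supplied thresholds).
#'
#' @param items Data frame of item responses.
#' @param mapping A `factor_mapping`.
#' @param thresholds Optional named numeric vector; defaults to
#'   [midpoint_thresholds()].
#' @param tie_rule Passed to [discretize_scores()].
#' @return List with elements `scores`, `discrete` and `thresholds`.
#' @export
prepare_factor_dataset <- function(items, mapping, thresholds = NULL,
                                   tie_rule = "low") {
  if (is.null(thresholds)) thresholds <- midpoint_thresholds(mapping)
  scores <- aggregate_factors(items, mapping)
  discrete <- discretize_scores(scores, thresholds, tie_rule,
                                bounds = mapping$bounds)
  list(scores = scores, discrete = discrete, thresholds = thresholds)
}
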