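#' Build mid-parent predictors for hybrids
#'
#' The predictive profile of each hybrid is the arithmetic mean of its
#' two parents' replicate-averaged analyte profiles, so reciprocal
#' hybrids share identical predictors.
#'
#' @param parents A [feature_table()] of parental profiles.
#' @param pedigree Data frame with `hybrid_id`, `female_id`, `male_id`
#'   (and usually `population`).
#' @return Numeric matrix, hybrids x analytes, hybrid ids as row names.
#' @export
build_predictors <- function(parents, pedigree) {
  line_means <- if (inherits(parents, "feature_table"))
    average_replicates(parents) else as.matrix(parents)
  for (col in c("female_id", "male_id")) {
    missing <- !(pedigree[[col]] %in% rownames(line_means))
    if (any(missing)) {
      i <- which(missing)[1L]
      stop(sprintf("hybrid '%s': no profile for %s parent '%s'",
                   pedigree$hybrid_id[i], sub("_id$", "", col),
                   pedigree[[col]][i]), call. = FALSE)
    }
  }
  out <- (line_means[pedigree$female_id, , drop = FALSE] +
            line_means[pedigree$male_id, , drop = FALSE]) / 2
  rownames(out) <- pedigree$hybrid_id
  out
}

#' Assign hybrids to trait subgroups
#'
#' Splits hybrids into `large` (TGW strictly above `high`), `small`
#' (strictly below `low`) and `medium` (everything between, boundaries
#' included) subgroups, the extremes of which drive marker screening.
#'
#' @param phenotypes Data frame with `hybrid_id` and `tgw`.
#' @param low,high Boundaries in g/1000 grains (defaults 24 and 27).
#' @return Data frame `hybrid_id`, `tgw`, `subgroup` (factor
#'   small/medium/large). Hybrids with missing TGW are dropped with a
#'   warning.
#' @export
assign_subgroups <- function(phenotypes, low = 24, high = 27) {
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  miss <- is.na(phenotypes$tgw)
  if (any(miss)) {
    warning(sprintf("dropping %d hybrid(s) with missing TGW", sum(miss)))
    phenotypes <- phenotypes[!miss, , drop = FALSE]
  }
  subgroup <- ifelse(phenotypes$tgw > high, "large",
                     ifelse(phenotypes$tgw < low, "small", "medium"))
  data.frame(hybrid_id = phenotypes$hybrid_id, tgw = phenotypes$tgw,
             subgroup = factor(subgroup,
                               levels = c("small", "medium", "large")),
             stringsAsFactors = FALSE)
}

#' Select metabolic markers by PLS-DA Component-1 VIP
#'
#' Fits a PLS-DA model contrasting the large- and small-trait hybrids
#' (medium hybrids are excluded) on autoscaled mid-parent predictors
#' and returns the analytes whose Component-1 VIP strictly exceeds
#' `vip_threshold`.
#'
#' @param predictors Mid-parent predictor matrix from
#'   [build_predictors()].
#' @param subgroups Data frame from [assign_subgroups()].
#' @param vip_threshold Strict VIP cutoff (default 1.5, a stringent
#'   level; 1.0 is the conventional one).
#' @param ncomp PLS-DA components to fit (default 4); VIP is taken
#'   from Component 1 only.
#' @param cv_seed Seed for the Q2 cross-validation folds.
#' @return A `marker_set`: `analyte_ids`, `vip_threshold`, `vip` (all
#'   analytes' Component-1 VIP), and the fitted `plsda` object.
#' @export
select_markers <- function(predictors, subgroups, vip_threshold = 1.5,
                           ncomp = 4L, cv_seed = 1L) {
  extremes <- subgroups[subgroups$subgroup %in% c("small", "large"), ]
  extremes <- extremes[extremes$hybrid_id %in% rownames(predictors), ]
  counts <- table(factor(extremes$subgroup,
                         levels = c("small", "large")))
  if (any(counts < 3L))
    stop(sprintf(
      "need at least 3 hybrids per extreme subgroup (got small = %d, large = %d)",
      counts[["small"]], counts[["large"]]), call. = FALSE)
  x <- autoscale(predictors[extremes$hybrid_id, , drop = FALSE])
  da <- fit_plsda(x, droplevels(extremes$subgroup), ncomp = ncomp,
                  cv_seed = cv_seed)
  v <- da$component1_vip
  structure(list(analyte_ids = colnames(predictors)[v > vip_threshold],
                 vip_threshold = vip_threshold, vip = v, plsda = da),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d analyte(s) with VIP > %g\n",
              length(x$analyte_ids), x$vip_threshold))
  invisible(x)
}

#' Refilter a marker set on a fitted PLS regression model
#'
#' After a regression model has been fitted on the current markers,
#' low-contribution analytes can be removed by recomputing VIP over
#' all fitted components and keeping analytes with VIP strictly above
#' the threshold. Increasing thresholds yield nested sets.
#'
#' @param model A `pls_model` fitted on exactly the analytes of
#'   `current` (same ids, same order).
#' @param current A `marker_set` (or character vector of analyte ids).
#' @param vip_threshold Strict VIP cutoff.
#' @return A new `marker_set` restricted to the surviving analytes.
#' @export
refilter_markers <- function(model, current, vip_threshold) {
  ids <- if (inherits(current, "marker_set")) current$analyte_ids
  else as.character(current)
  if (!identical(model$analyte_ids, ids))
    stop("model analytes do not match the current marker set",
         call. = FALSE)
  v <- vip(model)
  structure(list(analyte_ids = ids[v > vip_threshold],
                 vip_threshold = vip_threshold, vip = v),
            class = "marker_set")
}

#' Marker counts along a VIP-threshold sweep
#'
#' @param vip Named vector of VIP values (one per analyte).
#' @param thresholds Numeric thresholds (sorted increasing).
#' @return Data frame with `threshold` and `n_markers` (strict `>`
#'   rule, hence non-increasing in the threshold).
#' @export
threshold_sweep <- function(vip, thresholds) {
  thresholds <- sort(as.numeric(thresholds))
  data.frame(threshold = thresholds,
             n_markers = vapply(thresholds,
                                function(t) sum(vip > t), integer(1L)))
}
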