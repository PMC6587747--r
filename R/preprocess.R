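#' Retain analytes measured in at least one group
#'
#' Keeps analyte j iff there is a group g in which strictly more than
#' `min_nonzero_fraction` of the samples have a nonzero value for j
#' (the standard untargeted LC-MS retention rule). Column order of the
#' survivors is preserved; the operation is idempotent.
#'
#' @param table A [feature_table()] with group labels, or a numeric
#'   matrix (then `groups` is required).
#' @param min_nonzero_fraction Fraction in `[0, 1]`; strict `>` rule
#'   (default 0.5).
#' @param groups Group label per sample (matrix input only).
#' @param ... Passed between methods.
#' @return Object of the same type with the retained analyte columns.
#' @export
retain_features <- function(table, min_nonzero_fraction = 0.5, ...) {
  UseMethod("retain_features")
}

#' @rdname retain_features
#' @export
retain_features.matrix <- function(table, min_nonzero_fraction = 0.5,
                                   groups = NULL, ...) {
  if (is.null(groups) || anyNA(groups))
    stop("group labels are required to retain features", call. = FALSE)
  if (length(groups) != nrow(table))
    stop("`groups` must have one label per sample", call. = FALSE)
  if (min_nonzero_fraction < 0 || min_nonzero_fraction > 1)
    stop("`min_nonzero_fraction` must be in [0, 1]", call. = FALSE)
  f <- factor(groups)
  frac <- rowsum((table != 0) + 0, f) / as.vector(table(f))
  keep <- apply(frac, 2L, max) > min_nonzero_fraction
  table[, keep, drop = FALSE]
}

#' @rdname retain_features
#' @export
retain_features.feature_table <- function(table,
                                          min_nonzero_fraction = 0.5,
                                          ...) {
  values <- retain_features(table$values, min_nonzero_fraction,
                            groups = table$samples$group)
  feature_table(values, line_ids = table$samples$line_id,
                groups = table$samples$group)
}

#' Quality-control relative standard deviation summary
#'
#' Computes the per-analyte relative standard deviation
#' (sample sd / mean, n-1 denominator) over the quality-control
#' samples and the fraction of analytes with RSD below `threshold`.
#' Analytes with QC mean zero have undefined RSD and are excluded from
#' the fraction's denominator.
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param qc_sample_ids Row (sample) ids of the QC injections; at
#'   least two required.
#' @param threshold RSD threshold (default 0.2).
#' @return A `qc_summary` list: `rsd` (named, `NA` where undefined),
#'   `fraction_below_threshold`, `threshold`, `n_defined`.
#' @export
qc_rsd <- function(table, qc_sample_ids, threshold = 0.2) {
  values <- if (inherits(table, "feature_table")) table$values else
    as.matrix(table)
  missing <- setdiff(qc_sample_ids, rownames(values))
  if (length(missing) > 0L)
    stop(sprintf("unknown QC sample id '%s'", missing[1L]), call. = FALSE)
  if (length(qc_sample_ids) < 2L)
    stop("at least two QC samples are required", call. = FALSE)
  x <- values[qc_sample_ids, , drop = FALSE]
  m <- colMeans(x)
  s <- apply(x, 2L, sd)
  rsd <- ifelse(m == 0, NA_real_, s / m)
  defined <- !is.na(rsd)
  structure(list(
    rsd = rsd,
    fraction_below_threshold =
      if (any(defined)) mean(rsd[defined] < threshold) else NA_real_,
    threshold = threshold,
    n_defined = sum(defined)
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> %.2f%% of %d analytes with RSD < %g\n",
              100 * x$fraction_below_threshold, x$n_defined,
              x$threshold))
  invisible(x)
}

#' Sum-normalize sample rows
#'
#' Divides each sample row by its total signal and multiplies by a
#' common constant (default: the mean of the original row sums), the
#' standard correction for per-sample loading differences.
#'
#' @param x Numeric matrix (samples x analytes, non-negative).
#' @param constant Target row sum; defaults to the mean original row
#'   sum. Supplying a fixed constant makes the step exactly invariant
#'   to per-sample rescaling.
#' @return Matrix of the same shape, with attribute `"constant"`.
#' @export
sum_normalize <- function(x, constant = NULL) {
  x <- as.matrix(x)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[which(rs == 0)[1L]]
    stop(sprintf("sample '%s' has an all-zero row; cannot sum-normalize",
                 if (is.null(bad)) as.character(which(rs == 0)[1L]) else bad),
         call. = FALSE)
  }
  if (is.null(constant)) constant <- mean(rs)
  out <- x * (constant / rs)
  attr(out, "constant") <- constant
  out
}

#' Autoscale analyte columns
#'
#' Centres each column to mean zero and scales to unit sample standard
#' deviation (n-1 denominator). Constant columns are centred and left
#' unscaled (divisor 1) and flagged. When `center`/`scale` are
#' supplied, they are re-applied unchanged — used to project validation
#' predictors onto a training-set scaling without information leakage.
#'
#' @param x Numeric matrix.
#' @param center,scale Optional parameter vectors learned elsewhere.
#' @return Scaled matrix with attributes `"center"`, `"scale"` and
#'   `"constant_columns"` (logical, only when learned here).
#' @export
autoscale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  learned <- is.null(center) || is.null(scale)
  if (is.null(center)) center <- colMeans(x)
  constant <- NULL
  if (is.null(scale)) {
    scale <- apply(x, 2L, sd)
    constant <- scale == 0
    scale[constant] <- 1
  }
  out <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  if (learned) attr(out, "constant_columns") <- constant
  out
}

#' Standard parental preprocessing for predictor construction
#'
#' Applies the sample-level steps that precede mid-parent predictor
#' construction: feature retention by the per-group nonzero rule and
#' sum normalization of each sample row. Autoscaling is deliberately
#' left to the modelling stage, where its parameters are learned on
#' training hybrids only.
#'
#' @param parents A [feature_table()] of parental profiles with group
#'   labels.
#' @param min_nonzero_fraction Retention threshold (default 0.5).
#' @return A [feature_table()] with retained, sum-normalized values.
#' @export
preprocess_parents <- function(parents, min_nonzero_fraction = 0.5) {
  out <- retain_features(parents, min_nonzero_fraction)
  out$values <- sum_normalize(out$values)
  out
}

#' Normalization stack: sum normalization, no transformation, autoscaling
#'
#' Applies the full preprocessing stack used throughout the pipeline:
#' each sample row is sum-normalized to the mean original row sum, no
#' transformation is applied, and each analyte column is autoscaled
#' (mean 0, sd 1). Because of the autoscaling step, downstream results
#' are invariant to the choice of the sum-normalization constant.
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param ... Passed between methods.
#' @return Same type as the input; the value matrix carries the
#'   `"constant"`, `"center"`, `"scale"` attributes of the two steps.
#' @export
normalize_features <- function(table, ...) UseMethod("normalize_features")

#' @rdname normalize_features
#' @export
normalize_features.matrix <- function(table, ...) {
  sn <- sum_normalize(table)
  out <- autoscale(sn)
  attr(out, "constant") <- attr(sn, "constant")
  out
}

#' @rdname normalize_features
#' @export
normalize_features.feature_table <- function(table, ...) {
  values <- normalize_features(table$values)
  out <- feature_table(values, line_ids = table$samples$line_id,
                       groups = table$samples$group)
  attributes(out$values)[c("constant", "center", "scale",
                           "constant_columns")] <-
    attributes(values)[c("constant", "center", "scale",
                         "constant_columns")]
  out
}
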