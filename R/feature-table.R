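#' Construct a metabolite feature table
#'
#' A feature table holds one row per biological sample and one column
#' per analyte (relative abundances in arbitrary instrument units),
#' together with the line each sample belongs to and an optional group
#' label (used by [retain_features()]).
#'
#' @param values Numeric matrix, samples x analytes, with row names
#'   (sample ids) and column names (analyte ids). All values must be
#'   finite.
#' @param line_ids Character vector mapping each sample (row) to a
#'   parental line id. Defaults to the row names (one sample per line).
#' @param groups Optional character vector of group labels per sample
#'   (e.g. the population a line belongs to).
#' @return An object of class `feature_table`: a list with elements
#'   `values` (the matrix) and `samples` (a data frame with columns
#'   `sample_id`, `line_id`, `group`).
#' @export
feature_table <- function(values, line_ids = rownames(values),
                          groups = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as row names and analyte ids as column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in feature table", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop(sprintf("duplicate analyte column: '%s'",
                 colnames(values)[duplicated(colnames(values))][1L]),
         call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite abundance at sample '%s', analyte '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  if (length(line_ids) != nrow(values))
    stop("`line_ids` must have one entry per sample", call. = FALSE)
  if (!is.null(groups) && length(groups) != nrow(values))
    stop("`groups` must have one entry per sample", call. = FALSE)
  samples <- data.frame(
    sample_id = rownames(values),
    line_id = as.character(line_ids),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d analytes, %d lines\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$line_id))))
  if (!all(is.na(x$samples$group))) {
    tab <- table(x$samples$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Average replicate samples per line
#'
#' Collapses a feature table to one profile per parental line by
#' averaging its replicate samples.
#'
#' @param table A [feature_table()].
#' @return Numeric matrix, lines x analytes, with line ids as row names.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  f <- factor(table$samples$line_id,
              levels = unique(table$samples$line_id))
  sums <- rowsum(table$values, f)
  sums / as.vector(table(f))
}
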