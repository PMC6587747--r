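#' Read a feature table from delimited text
#'
#' Expects a header row and the columns `sample_id`, `line_id`,
#' `group`, followed by one numeric column per analyte. Duplicate
#' sample ids or analyte columns, and non-numeric or missing cells,
#' raise errors naming the offending row/column.
#'
#' @param path Path to a comma- (default) or tab-delimited file.
#' @param sep Field separator.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, sep = ",") {
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  dup_hdr <- header[duplicated(header)]
  if (length(dup_hdr) > 0L)
    stop(sprintf("duplicate analyte column: '%s'", dup_hdr[1L]),
         call. = FALSE)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  required <- c("sample_id", "line_id", "group")
  if (!all(required %in% names(df)))
    stop(sprintf("feature table must have columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  analyte_cols <- setdiff(names(df), required)
  if (length(analyte_cols) == 0L)
    stop("feature table has no analyte columns", call. = FALSE)
  dup <- analyte_cols[duplicated(analyte_cols)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate analyte column: '%s'", dup[1L]),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop(sprintf("duplicate sample id: '%s'",
                 df$sample_id[duplicated(df$sample_id)][1L]),
         call. = FALSE)
  values <- as.matrix(df[, analyte_cols, drop = FALSE])
  suppressWarnings(storage.mode(values) <- "double")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-numeric or missing value at sample '%s' (row %d), analyte '%s'",
      df$sample_id[bad[1L, 1L]], bad[1L, 1L], analyte_cols[bad[1L, 2L]]),
      call. = FALSE)
  rownames(values) <- df$sample_id
  feature_table(values, line_ids = df$line_id, groups = df$group)
}

#' Write a feature table to delimited text
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$samples, as.data.frame(table$values))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pedigree table
#'
#' Columns `hybrid_id`, `female_id`, `male_id`, `population`.
#' Duplicate hybrid ids are rejected; when `known_lines` is given,
#' pedigrees referencing unknown parents fail at load time.
#'
#' @param path Input path.
#' @param known_lines Optional character vector of valid parental line
#'   ids.
#' @param sep Field separator.
#' @return Pedigree data frame.
#' @export
read_pedigree <- function(path, known_lines = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("hybrid_id", "female_id", "male_id", "population")
  if (!all(required %in% names(df)))
    stop(sprintf("pedigree must have columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$hybrid_id))
    stop(sprintf("duplicate hybrid id: '%s'",
                 df$hybrid_id[duplicated(df$hybrid_id)][1L]),
         call. = FALSE)
  if (!is.null(known_lines)) {
    parents <- c(df$female_id, df$male_id)
    unknown <- setdiff(parents, known_lines)
    if (length(unknown) > 0L)
      stop(sprintf("pedigree references unknown parent id '%s'",
                   unknown[1L]), call. = FALSE)
  }
  df[, required]
}

#' Read a phenotype table
#'
#' Columns `hybrid_id` and `tgw` (g/1000 grains, strictly positive).
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return Data frame `hybrid_id`, `tgw`.
#' @export
read_phenotypes <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("hybrid_id", "tgw") %in% names(df)))
    stop("phenotype table must have columns hybrid_id, tgw",
         call. = FALSE)
  tgw <- suppressWarnings(as.numeric(df$tgw))
  bad <- which(!is.finite(tgw) | tgw <= 0)
  if (length(bad) > 0L)
    stop(sprintf("invalid TGW for hybrid '%s' (must be a positive number)",
                 df$hybrid_id[bad[1L]]), call. = FALSE)
  data.frame(hybrid_id = df$hybrid_id, tgw = tgw,
             stringsAsFactors = FALSE)
}

#' Write / read a per-hybrid prediction report
#'
#' The per-hybrid table is written with 15 significant digits so that
#' a write-read round trip preserves at least 12.
#'
#' @param report A `prediction_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  df <- report$hybrids
  df$observed <- formatC(df$observed, digits = 15, format = "g")
  df$predicted <- formatC(df$predicted, digits = 15, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("hybrid_id", "population", "role", "observed",
                "predicted")
  if (!all(required %in% names(df)))
    stop(sprintf("report must have columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  df$observed <- as.numeric(df$observed)
  df$predicted <- as.numeric(df$predicted)
  df
}

#' Write a simulated scenario to a directory of plain-text files
#'
#' Writes `features.csv`, `pedigree.csv`, `phenotypes.csv` and a
#' `truth.json` sidecar (causal analyte ids, effects, intercept,
#' environment offsets) for downstream use outside R.
#'
#' @param scenario A `corehyb_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "corehyb_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(scenario$parents, file.path(dir, "features.csv"))
  write.csv(scenario$pedigree, file.path(dir, "pedigree.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(scenario$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(causal_analyte_ids = scenario$truth$causal_analyte_ids,
         causal_effects = scenario$truth$causal_effects,
         intercept = scenario$truth$intercept,
         env_offsets = as.list(scenario$truth$env_offsets)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
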