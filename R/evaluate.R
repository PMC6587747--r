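#' Fit the prediction equation on a training split and evaluate
#'
#' Restricts the mid-parent predictors to the marker analytes, learns
#' autoscaling parameters on the training hybrids only, picks the
#' number of latent factors by peak adjusted R-squared on the training
#' set, fits the final PLS model, predicts validation hybrids through
#' the coefficient equation `b0 + x %*% B`, and reports per-population
#' predictability: the Pearson correlation between observed and
#' predicted trait values over each population's validation hybrids
#' (two-sided t-approximation p-value). Populations with fewer than 3
#' validation hybrids are reported as undefined (`NA`).
#'
#' @param predictors Mid-parent predictor matrix (all hybrids).
#' @param phenotypes Data frame `hybrid_id`, `tgw`.
#' @param markers A `marker_set` or character vector of analyte ids.
#' @param split A `training_composition`.
#' @param ncomp_max Largest latent-factor count considered (default
#'   30; additionally capped at `n_train - 1` and the marker count).
#' @param ncomp Optional fixed latent-factor count. When `NULL` (the
#'   default) the count is chosen by the peak of the training adjusted
#'   R-squared; supplying an integer reproduces the two-stage
#'   procedure in which the count is determined once on a reference
#'   model and then held fixed across training compositions.
#' @return A `prediction_report`: `hybrids` (per-hybrid data frame with
#'   `observed`, `predicted`, `population`, `role`), `populations`
#'   (per-population `n_validation`, `r`, `p_value`),
#'   `composition_name`, `n_markers`, `ncomp`, and the fitted `model`.
#' @export
train_and_predict <- function(predictors, phenotypes, markers, split,
                              ncomp_max = 30L, ncomp = NULL) {
  ids <- if (inherits(markers, "marker_set")) markers$analyte_ids
  else as.character(markers)
  if (length(ids) == 0L)
    stop("the marker set is empty", call. = FALSE)
  missing <- setdiff(ids, colnames(predictors))
  if (length(missing) > 0L)
    stop(sprintf("marker analyte '%s' is not in the predictor table",
                 missing[1L]), call. = FALSE)
  stopifnot(inherits(split, "training_composition"))
  tgw <- stats::setNames(phenotypes$tgw, phenotypes$hybrid_id)
  all_ids <- c(split$train_ids, split$validation_ids)
  if (!all(all_ids %in% rownames(predictors)))
    stop("split references hybrids absent from the predictor table",
         call. = FALSE)
  if (!all(all_ids %in% names(tgw)))
    stop("split references hybrids absent from the phenotype table",
         call. = FALSE)
  x <- predictors[, ids, drop = FALSE]
  xtr <- autoscale(x[split$train_ids, , drop = FALSE])
  xval <- autoscale(x[split$validation_ids, , drop = FALSE],
                    center = attr(xtr, "center"),
                    scale = attr(xtr, "scale"))
  ytr <- tgw[split$train_ids]
  cap <- min(ncomp_max, length(ytr) - 1L, length(ids))
  if (is.null(ncomp)) {
    sel <- select_n_components(xtr, ytr, cap)
    model <- sel$model
    ncomp_used <- sel$ncomp
  } else {
    extractable <- .pls_max_components(xtr, ytr, cap)
    ncomp_used <- min(.assert_count(ncomp, "ncomp"), cap, extractable)
    model <- if (ncomp_used >= 1L) fit_pls(xtr, ytr, ncomp_used)
    else select_n_components(xtr, ytr, 1L)$model
    ncomp_used <- max(ncomp_used, 1L)
  }
  pred_tr <- predict(model, xtr)
  pred_val <- predict(model, xval)
  hybrids <- rbind(
    data.frame(hybrid_id = split$train_ids, role = "train",
               observed = as.numeric(ytr),
               predicted = as.numeric(pred_tr),
               stringsAsFactors = FALSE),
    data.frame(hybrid_id = split$validation_ids, role = "validation",
               observed = as.numeric(tgw[split$validation_ids]),
               predicted = as.numeric(pred_val),
               stringsAsFactors = FALSE)
  )
  popmap <- stats::setNames(split$assignments$population,
                            split$assignments$hybrid_id)
  hybrids$population <- as.character(popmap[hybrids$hybrid_id])
  hybrids <- hybrids[, c("hybrid_id", "population", "role",
                         "observed", "predicted")]
  pops <- sort(unique(split$assignments$population))
  populations <- do.call(rbind, lapply(pops, function(pp) {
    v <- hybrids[hybrids$role == "validation" &
                   hybrids$population == pp, ]
    if (nrow(v) < 3L || sd(v$observed) == 0 || sd(v$predicted) == 0) {
      data.frame(population = pp, n_validation = nrow(v),
                 r = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      ct <- cor.test(v$observed, v$predicted, method = "pearson")
      data.frame(population = pp, n_validation = nrow(v),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 stringsAsFactors = FALSE)
    }
  }))
  structure(list(hybrids = hybrids, populations = populations,
                 composition_name = split$name,
                 n_markers = length(ids), ncomp = ncomp_used,
                 model = model),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s: %d marker(s), %d latent factor(s)\n",
              x$composition_name, x$n_markers, x$ncomp))
  for (i in seq_len(nrow(x$populations))) {
    p <- x$populations[i, ]
    if (is.na(p$r))
      cat(sprintf("  %s: predictability undefined (n = %d)\n",
                  p$population, p$n_validation))
    else
      cat(sprintf("  %s: r = %.3f (p = %.3g, n = %d)\n", p$population,
                  p$r, p$p_value, p$n_validation))
  }
  invisible(x)
}

#' Run a grid of training compositions
#'
#' Evaluates [train_and_predict()] for each composition and collects
#' the per-population predictabilities into one table.
#'
#' @param predictors Mid-parent predictor matrix.
#' @param phenotypes Data frame `hybrid_id`, `tgw`.
#' @param markers Marker set shared by all compositions.
#' @param compositions List of `training_composition` objects.
#' @param ncomp_max,ncomp As in [train_and_predict()].
#' @return Data frame with one row per composition: `name`, `n_train`,
#'   `ncomp`, and `r_<population>` / `p_<population>` columns.
#' @export
experiment_grid <- function(predictors, phenotypes, markers,
                            compositions, ncomp_max = 30L,
                            ncomp = NULL) {
  rows <- lapply(compositions, function(split) {
    rep <- train_and_predict(predictors, phenotypes, markers, split,
                             ncomp_max = ncomp_max, ncomp = ncomp)
    row <- data.frame(name = rep$composition_name,
                      n_train = length(split$train_ids),
                      ncomp = rep$ncomp, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rep$populations))) {
      p <- rep$populations[i, ]
      row[[paste0("r_", p$population)]] <- p$r
      row[[paste0("p_", p$population)]] <- p$p_value
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predictability as a function of the marker count
#'
#' For each VIP threshold, selects the analytes with VIP strictly
#' above it, reruns [train_and_predict()] on the same split, and
#' tabulates marker counts against per-population predictability.
#' Thresholds that exclude every analyte give an `NA` row.
#'
#' @param predictors Mid-parent predictor matrix.
#' @param phenotypes Data frame `hybrid_id`, `tgw`.
#' @param vip Named vector of VIP values per analyte.
#' @param split A `training_composition`.
#' @param thresholds Numeric VIP thresholds.
#' @param ncomp_max,ncomp As in [train_and_predict()].
#' @return Data frame `threshold`, `n_markers`, plus
#'   `r_<population>` / `p_<population>` columns.
#' @export
marker_count_sweep <- function(predictors, phenotypes, vip, split,
                               thresholds, ncomp_max = 30L,
                               ncomp = NULL) {
  if (is.null(names(vip)))
    stop("`vip` must be named by analyte id", call. = FALSE)
  thresholds <- sort(as.numeric(thresholds))
  pops <- sort(unique(split$assignments$population))
  rows <- lapply(thresholds, function(t) {
    ids <- names(vip)[vip > t]
    row <- data.frame(threshold = t, n_markers = length(ids))
    if (length(ids) == 0L) {
      for (pp in pops) {
        row[[paste0("r_", pp)]] <- NA_real_
        row[[paste0("p_", pp)]] <- NA_real_
      }
      return(row)
    }
    rep <- train_and_predict(predictors, phenotypes, ids, split,
                             ncomp_max = ncomp_max, ncomp = ncomp)
    for (i in seq_len(nrow(rep$populations))) {
      p <- rep$populations[i, ]
      row[[paste0("r_", p$population)]] <- p$r
      row[[paste0("p_", p$population)]] <- p$p_value
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
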