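#' Run the full prediction pipeline on a scenario
#'
#' Executes the whole analysis end to end on a (simulated or loaded)
#' two-population study: feature retention, sum normalization of the
#' parental samples, mid-parent predictor construction, PLS-DA marker
#' screening on the population-1 trait extremes, PC1-based core
#' selection in both populations, and PLS evaluation of one training
#' composition. The latent-factor count is determined once, at the
#' adjusted R-squared peak of a reference model trained on the whole
#' environment-1 population, and then held fixed for the evaluated
#' composition (the two-stage procedure; see the methods vignette).
#'
#' By default, marker screening uses the published procedure: the
#' large/small extremes of population 1 regardless of the split
#' (leakage-safe for population-2 validation only). With
#' `strict_selection = TRUE`, screening is restricted to training
#' hybrids.
#'
#' @param scenario A `corehyb_scenario` (or a list with `parents`,
#'   `pedigree`, `phenotypes`).
#' @param N_pop1,N_pop2 Core-sampling intervals for the two
#'   populations; `NA` for `N_pop1` means "All" (the whole population
#'   trains).
#' @param vip_threshold VIP cutoff for marker screening (default 1.5).
#' @param subgroup_low,subgroup_high TGW subgroup boundaries in g/1000
#'   grains (defaults 24 and 27).
#' @param min_nonzero_fraction Feature-retention threshold.
#' @param ncomp_max Largest latent-factor count for the final model.
#' @param orientation PC1 orientation for core selection (see
#'   [pc1_scores()]).
#' @param strict_selection Restrict marker screening to training
#'   hybrids.
#' @param cv_seed Seed for PLS-DA cross-validation folds.
#' @return A list: `report` (the `prediction_report`), `markers`,
#'   `split`, `cores`, `predictors`, `pc1`, `ncomp` (the fixed
#'   latent-factor count) and `reference` (the reference-model
#'   selection from [select_n_components()]).
#' @export
run_pipeline <- function(scenario, N_pop1 = 3L, N_pop2 = 2L,
                         vip_threshold = 1.5, subgroup_low = 24,
                         subgroup_high = 27,
                         min_nonzero_fraction = 0.5, ncomp_max = 30L,
                         orientation = c("fixed", "flipped"),
                         strict_selection = FALSE, cv_seed = 1L) {
  orientation <- match.arg(orientation)
  parents <- preprocess_parents(scenario$parents, min_nonzero_fraction)
  pedigree <- scenario$pedigree
  predictors <- build_predictors(parents, pedigree)
  pops <- unique(pedigree$population)
  if (length(pops) != 2L)
    stop("the pipeline expects exactly two populations", call. = FALSE)

  pc1 <- pc1_scores(predictors, orientation = orientation)
  cores <- list(
    pop1 = if (is.na(N_pop1)) core_all(pedigree, pops[1L])
    else select_core(pc1[pedigree$hybrid_id[pedigree$population == pops[1L]]],
                     N_pop1, population = pops[1L]),
    pop2 = select_core(pc1[pedigree$hybrid_id[pedigree$population == pops[2L]]],
                       N_pop2, population = pops[2L])
  )
  split <- compose_training(cores$pop1, cores$pop2, pedigree)

  subgroups <- assign_subgroups(scenario$phenotypes, subgroup_low,
                                subgroup_high)
  pop1_ids <- pedigree$hybrid_id[pedigree$population == pops[1L]]
  pool <- if (strict_selection) intersect(pop1_ids, split$train_ids)
  else pop1_ids
  markers <- select_markers(predictors[pool, , drop = FALSE],
                            subgroups[subgroups$hybrid_id %in% pool, ],
                            vip_threshold = vip_threshold,
                            cv_seed = cv_seed)

  # two-stage latent-factor choice: the count is determined once, at
  # the adjusted R-squared peak of the reference model trained on the
  # whole environment-1 population, and then held fixed for every
  # training composition
  tgw <- stats::setNames(scenario$phenotypes$tgw,
                         scenario$phenotypes$hybrid_id)
  ref_ids <- intersect(pop1_ids, names(tgw))
  x_ref <- autoscale(predictors[ref_ids, markers$analyte_ids,
                                drop = FALSE])
  ref <- select_n_components(x_ref, tgw[ref_ids],
                             min(ncomp_max, length(ref_ids) - 1L,
                                 length(markers$analyte_ids)))

  report <- train_and_predict(predictors, scenario$phenotypes, markers,
                              split, ncomp_max = ncomp_max,
                              ncomp = ref$ncomp)
  list(report = report, markers = markers, split = split,
       cores = cores, predictors = predictors, pc1 = pc1,
       ncomp = ref$ncomp, reference = ref)
}
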