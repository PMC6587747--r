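#' PC1 scores of hybrids for core selection
#'
#' Runs PCA on the autoscaled mid-parent predictor table of the
#' combined populations and returns each hybrid's score on the first
#' principal component. The PCA sign convention (largest-magnitude
#' loading entry positive) makes the ranking reproducible; because the
#' orientation of a principal axis is arbitrary, `orientation =
#' "flipped"` negates the scores so both block-leader orderings can be
#' examined.
#'
#' @param predictors Mid-parent predictor matrix.
#' @param orientation `"fixed"` (default) or `"flipped"`.
#' @return Named numeric vector of PC1 scores.
#' @export
pc1_scores <- function(predictors, orientation = c("fixed", "flipped")) {
  orientation <- match.arg(orientation)
  pc <- fit_pca(autoscale(predictors))
  s <- pc$scores[, 1L]
  if (orientation == "flipped") s <- -s
  s
}

#' Select core hybrids by PC1-ranked interval sampling
#'
#' Orders hybrids by decreasing score (ties broken lexicographically by
#' hybrid id) and keeps the leader of every consecutive block of `N`
#' ranks — positions 1, N+1, 2N+1, ... — yielding exactly
#' `ceiling(n / N)` hybrids, approximately one `N`-th of the
#' population, spread across its whole PC1 range.
#'
#' @param scores Named numeric vector of PC1 scores for one
#'   population's hybrids.
#' @param N Sampling interval, an integer >= 2 (the "2N"/"3N"/"4N"
#'   sets use 2, 3 and 4).
#' @param population Optional population label carried into the name
#'   of training compositions.
#' @return A `core_set`: `selected_ids`, `N`, `label` (e.g. `"3N"`),
#'   `population`, `scores`.
#' @export
select_core <- function(scores, N, population = NA_character_) {
  N <- .assert_count(N, "N", 2L)
  if (is.null(names(scores)) || anyNA(names(scores)))
    stop("`scores` must be named by hybrid id", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("`scores` must be finite", call. = FALSE)
  n <- length(scores)
  if (N > n) {
    warning("interval exceeds the population size; selecting only the top-ranked hybrid")
  }
  ord <- order(-scores, names(scores))
  selected <- names(scores)[ord][seq(1L, n, by = N)]
  structure(list(selected_ids = selected, N = N,
                 label = paste0(N, "N"),
                 population = as.character(population),
                 scores = scores),
            class = "core_set")
}

#' All hybrids of a population as a pseudo core set
#'
#' Used for the "All" training compositions where one population
#' enters the training set in full.
#'
#' @param pedigree Pedigree data frame.
#' @param population Population label to take entirely.
#' @return A `core_set` with label `"All"`.
#' @export
core_all <- function(pedigree, population) {
  ids <- pedigree$hybrid_id[pedigree$population == population]
  if (length(ids) == 0L)
    stop(sprintf("no hybrids in population '%s'", population),
         call. = FALSE)
  structure(list(selected_ids = ids, N = NA_integer_, label = "All",
                 population = as.character(population), scores = NULL),
            class = "core_set")
}

#' A seeded random half of a population as a pseudo core set
#'
#' @param pedigree Pedigree data frame.
#' @param population Population label to sample from.
#' @param seed Seed for the draw.
#' @param fraction Fraction to select (default 0.5; `ceiling(n *
#'   fraction)` hybrids).
#' @return A `core_set` with label `"Random-half"` (or
#'   `"Random-<fraction>"`).
#' @export
core_random <- function(pedigree, population, seed,
                        fraction = 0.5) {
  ids <- pedigree$hybrid_id[pedigree$population == population]
  if (length(ids) == 0L)
    stop(sprintf("no hybrids in population '%s'", population),
         call. = FALSE)
  sel <- with_seed(seed, sample(ids, ceiling(length(ids) * fraction)))
  structure(list(selected_ids = sort(sel), N = NA_integer_,
                 label = if (fraction == 0.5) "Random-half"
                         else paste0("Random-", fraction),
                 population = as.character(population), scores = NULL),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %s_%s: %d hybrid(s)\n", x$label,
              x$population, length(x$selected_ids)))
  invisible(x)
}

#' Compose a cross-population training/validation split
#'
#' The training set is the union of the given core sets (one per
#' population); every remaining hybrid of both populations goes to the
#' validation set. The composition name follows the
#' `"<label>_<pop> & <label>_<pop>"` convention (e.g.
#' `"3N_2012 & 2N_2015"`).
#'
#' @param core_pop1 A `core_set` for the first population, or `NULL`
#'   to contribute nothing from it to the training set.
#' @param core_pop2 A `core_set` for the second population, or `NULL`.
#' @param pedigree Pedigree data frame covering both populations.
#' @return A `training_composition`: `name`, `train_ids`,
#'   `validation_ids`, and `assignments` (data frame `hybrid_id`,
#'   `population`, `role`).
#' @export
compose_training <- function(core_pop1, core_pop2, pedigree) {
  cores <- Filter(Negate(is.null), list(core_pop1, core_pop2))
  if (length(cores) == 0L)
    stop("at least one core set is required", call. = FALSE)
  pops <- vapply(cores, function(cs) cs$population, character(1L))
  if (anyDuplicated(pops))
    stop("core sets must come from distinct populations", call. = FALSE)
  ids <- lapply(cores, function(cs) cs$selected_ids)
  if (length(ids) == 2L && length(intersect(ids[[1L]], ids[[2L]])) > 0L)
    stop("core sets share hybrid ids across populations", call. = FALSE)
  train <- unlist(ids, use.names = FALSE)
  unknown <- setdiff(train, pedigree$hybrid_id)
  if (length(unknown) > 0L)
    stop(sprintf("core hybrid '%s' is not in the pedigree", unknown[1L]),
         call. = FALSE)
  validation <- setdiff(pedigree$hybrid_id, train)
  name <- paste(vapply(cores, function(cs)
    paste0(cs$label, "_", cs$population), character(1L)),
    collapse = " & ")
  assignments <- data.frame(
    hybrid_id = pedigree$hybrid_id,
    population = pedigree$population,
    role = ifelse(pedigree$hybrid_id %in% train, "train", "validation"),
    stringsAsFactors = FALSE
  )
  structure(list(name = name, train_ids = train,
                 validation_ids = validation,
                 assignments = assignments),
            class = "training_composition")
}

#' @export
print.training_composition <- function(x, ...) {
  cat(sprintf("<training_composition> %s: %d train / %d validation\n",
              x$name, length(x$train_ids), length(x$validation_ids)))
  invisible(x)
}
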