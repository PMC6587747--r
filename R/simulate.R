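#' Configure a synthetic two-population hybrid study
#'
#' Defines the generative model for a synthetic study with two hybrid
#' populations that mirror the designs the pipeline targets:
#' population 1 is a complete diallel among `n_parents_pop1` inbred
#' lines (reciprocals included, selfs excluded), grown/phenotyped in
#' one environment; population 2 crosses a single cytoplasmic male
#' sterile (CMS) female to `n_males_pop2` recombinant inbred line (RIL)
#' males, phenotyped in a second environment. Parental metabolomes
#' follow a low-rank latent factor model; population 2 lines receive an
#' additive shift in latent space so the two populations are
#' metabolically distinct. The trait (thousand grain weight, TGW, in
#' g/1000 grains) is linear in the mid-parent abundances of a causal
#' analyte subset, plus a population-2 environment offset and Gaussian
#' noise.
#'
#' The two populations' genetic group means are matched exactly (when
#' `n_causal >= 2`), so the environment offset is identifiable from
#' observed group means and parameter-recovery tests are meaningful.
#'
#' @param n_parents_pop1 Number of diallel parents (default 18).
#' @param n_males_pop2 Number of RIL male parents (default 106).
#' @param n_analytes Number of metabolite features (default 800).
#' @param n_latent Rank of the latent metabolite covariance (default 6).
#' @param n_causal Number of causal analytes (default 60; 0 allowed for
#'   a no-signal scenario).
#' @param effect_sd Standard deviation of the genetic (causal) component
#'   of TGW across all hybrids, g/1000 grains (default 2.5).
#' @param noise_sd Residual TGW noise sd, g/1000 grains (default 2.2,
#'   i.e. roughly as large as the genetic signal, so that about half
#'   the trait variance is metabolome-predictable).
#' @param ril_latent_var Latent variance of the RIL male parents
#'   (default 2): recombinants from wide crosses segregate
#'   transgressively, giving population 2 a predictor spread comparable
#'   to the diallel population despite the shared female.
#' @param trait_latent_share Fraction of the genetic trait variance
#'   flowing through the shared latent metabolome axes (default 0.5);
#'   the remainder acts through the causal analytes' own line-specific
#'   variation. High values make the trait strongly aligned with major
#'   metabolome axes, which is what a near-perfect large/small PLS-DA
#'   separation on real data implies.
#' @param env_effect_cor Cross-environment correlation of the
#'   analyte-specific causal effects (default 0.6): the latent-mediated
#'   trait component is conserved across environments, but the
#'   individual metabolite effects acting on population-2 hybrids
#'   (phenotyped in the second environment) are only correlated
#'   `env_effect_cor` with the population-1 effects. Values below 1
#'   model genotype-by-environment interaction on the metabolite-trait
#'   map, one mechanism by which environmental discrepancy erodes
#'   cross-environment predictability; an additive offset alone cannot,
#'   since Pearson correlation is translation invariant.
#' @param env_offset_pop2 Additive TGW offset for population-2 hybrids,
#'   g/1000 grains (default 2.5).
#' @param pop_shift_magnitude Magnitude (in latent sd units) of the
#'   additive latent shift applied to population-2 parents (default 4).
#' @param n_nuisance_latent Number of population-2-specific background
#'   latent axes (default 4): co-regulation structure contributed by
#'   the RILs' wider genetic background, absent among the diallel
#'   parents.
#' @param background_trait_share Fraction of the population-2 genetic
#'   trait variance flowing through the background axes (default
#'   0.35). A population-1 training set cannot see these axes at all,
#'   so this is the structural component of cross-environment
#'   predictability loss that adding population-2 hybrids to the
#'   training set recovers. Forced to 0 when `n_nuisance_latent = 0`.
#' @param replicates_per_parent Replicate metabolome samples per
#'   population-1 parent (default 2); population-2 lines contribute one
#'   sample each.
#' @param line_noise_sd Sd of the line-specific, analyte-specific
#'   biological component on the standardized latent scale (default
#'   1.2). This is the part of a line's metabolome not explained by the
#'   shared latent factors; without it every analyte would be a pure
#'   proxy of the latent state and individual metabolic markers would
#'   carry no information of their own.
#' @param replicate_noise_sd Per-sample measurement noise sd, on the
#'   standardized latent scale (default 0.15).
#' @param intercept Mean TGW of population-1 hybrids, g/1000 grains
#'   (default 25.5); the realized regression intercept absorbs the mean
#'   genetic value and is recorded in the truth object.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of
#'   per-analyte baseline abundances.
#' @param analyte_cv Coefficient of variation linking the latent scale
#'   to abundance units (per-analyte sd = `analyte_cv` * baseline).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param pop_labels Length-2 character vector naming the populations
#'   (default `c("2012", "2015")`).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_parents_pop1 = 18L, n_males_pop2 = 106L,
                            n_analytes = 800L, n_latent = 6L,
                            n_causal = 60L, effect_sd = 2.5,
                            noise_sd = 2.2, ril_latent_var = 2,
                            trait_latent_share = 0.5,
                            env_effect_cor = 0.6,
                            env_offset_pop2 = 2.5,
                            pop_shift_magnitude = 4,
                            n_nuisance_latent = 4L,
                            background_trait_share = 0.35,
                            replicates_per_parent = 2L,
                            line_noise_sd = 1.2,
                            replicate_noise_sd = 0.15,
                            intercept = 25.5,
                            abundance_meanlog = log(100),
                            abundance_sdlog = 0.8,
                            analyte_cv = 0.2,
                            seed = 1L,
                            pop_labels = c("2012", "2015")) {
  cfg <- list(
    n_parents_pop1 = .assert_count(n_parents_pop1, "n_parents_pop1", 2L),
    n_males_pop2 = .assert_count(n_males_pop2, "n_males_pop2"),
    n_analytes = .assert_count(n_analytes, "n_analytes"),
    n_latent = .assert_count(n_latent, "n_latent"),
    n_causal = .assert_count(n_causal, "n_causal", 0L),
    effect_sd = .assert_nonneg(effect_sd, "effect_sd"),
    noise_sd = .assert_nonneg(noise_sd, "noise_sd"),
    ril_latent_var = .assert_nonneg(ril_latent_var, "ril_latent_var"),
    trait_latent_share = .assert_nonneg(trait_latent_share,
                                        "trait_latent_share"),
    env_effect_cor = as.numeric(env_effect_cor),
    env_offset_pop2 = as.numeric(env_offset_pop2),
    pop_shift_magnitude = .assert_nonneg(pop_shift_magnitude,
                                         "pop_shift_magnitude"),
    n_nuisance_latent = .assert_count(n_nuisance_latent,
                                      "n_nuisance_latent", 0L),
    background_trait_share = .assert_nonneg(background_trait_share,
                                            "background_trait_share"),
    replicates_per_parent = .assert_count(replicates_per_parent,
                                          "replicates_per_parent"),
    line_noise_sd = .assert_nonneg(line_noise_sd, "line_noise_sd"),
    replicate_noise_sd = .assert_nonneg(replicate_noise_sd,
                                        "replicate_noise_sd"),
    intercept = as.numeric(intercept),
    abundance_meanlog = as.numeric(abundance_meanlog),
    abundance_sdlog = .assert_nonneg(abundance_sdlog, "abundance_sdlog"),
    analyte_cv = .assert_nonneg(analyte_cv, "analyte_cv"),
    seed = .assert_count(seed, "seed", 0L),
    pop_labels = as.character(pop_labels)
  )
  if (cfg$trait_latent_share > 1)
    stop("`trait_latent_share` must be in [0, 1]", call. = FALSE)
  if (cfg$background_trait_share > 1)
    stop("`background_trait_share` must be in [0, 1]", call. = FALSE)
  if (cfg$n_nuisance_latent == 0L) cfg$background_trait_share <- 0
  if (!is.finite(cfg$env_effect_cor) || abs(cfg$env_effect_cor) > 1)
    stop("`env_effect_cor` must be in [-1, 1]", call. = FALSE)
  if (cfg$n_causal > cfg$n_analytes)
    stop("`n_causal` must not exceed `n_analytes`", call. = FALSE)
  if (cfg$n_latent > cfg$n_analytes)
    stop("`n_latent` must not exceed `n_analytes`", call. = FALSE)
  if (length(cfg$pop_labels) != 2L || anyDuplicated(cfg$pop_labels))
    stop("`pop_labels` must be two distinct labels", call. = FALSE)
  structure(cfg, class = "scenario_config")
}

# Canonical line ids shared between the parent simulator and the
# pedigree builder.
.scenario_lines <- function(config) {
  list(
    pop1 = sprintf("P%02d", seq_len(config$n_parents_pop1)),
    female = "CMS-F",
    males = sprintf("M%03d", seq_len(config$n_males_pop2))
  )
}

# Fixed structural parameters of a scenario (baseline abundances,
# latent loadings, population shift direction), regenerated
# deterministically from the seed so the parent simulator and the
# phenotype simulator agree on them.
.scenario_structure <- function(config) {
  with_seed(config$seed, {
    p <- config$n_analytes
    k <- config$n_latent
    mu <- rlnorm(p, config$abundance_meanlog, config$abundance_sdlog)
    sig <- config$analyte_cv * mu
    # analytes differ in how strongly they are tied to the shared
    # latent axes (communality); most untargeted features are largely
    # idiosyncratic while a minority is strongly co-regulated, which is
    # what makes feature filtering worthwhile. lambda ~ sqrt(5)*U(0,1)^2
    # is skewed toward zero and keeps the mean latent variance at 1.
    comm <- runif(p)
    lambda <- sqrt(5) * comm^2
    loadings <- lambda * matrix(rnorm(p * k), p, k) / sqrt(k)
    u <- rnorm(k)
    shift_dir <- u / sqrt(sum(u^2))
    # population-2-specific co-regulation axes: the RIL males (and the
    # CMS female) descend partly from cultivars outside the diallel
    # panel, whose segregating backgrounds add latent axes that do not
    # vary among the 18 diallel parents. Strongly co-regulated
    # metabolites are strongly co-regulated in both respects, so the
    # background loading strength scales with the shared communality
    # (total background variance comparable to the shared axes).
    m <- config$n_nuisance_latent
    background_loadings <- if (m > 0L) {
      (sqrt(2) * lambda) * matrix(rnorm(p * m), p, m) / sqrt(m)
    } else matrix(0, p, 0L)
    list(mu = mu, sig = sig, lambda = lambda, loadings = loadings,
         background_loadings = background_loadings,
         shift = config$pop_shift_magnitude * shift_dir,
         shift_dir = shift_dir)
  })
}

#' Simulate parental metabolite profiles
#'
#' Draws one latent vector per parental line; a line's analyte profile
#' is `baseline + sd * (loadings %*% latent + line-specific biological
#' component + per-sample measurement noise)`, clamped at zero. Population-2 lines (the CMS female and the RIL
#' males) receive an additive latent shift of magnitude
#' `pop_shift_magnitude` along a fixed random direction, and each RIL
#' latent is a mixture of a random population-1 parent latent and a
#' fresh draw (RILs descend from crosses involving the diallel
#' parents). Population-1 parents contribute `replicates_per_parent`
#' replicate samples; population-2 lines one sample each.
#'
#' @param config A [scenario_config()].
#' @return A [feature_table()] with `group` set to the population label.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  s <- .scenario_structure(config)
  with_seed(config$seed + 1L, {
    p <- config$n_analytes
    k <- config$n_latent
    lines <- .scenario_lines(config)
    n1 <- length(lines$pop1)
    nm <- length(lines$males)

    mu <- s$mu
    sig <- s$sig
    loadings <- s$loadings
    shift <- s$shift

    z1 <- matrix(rnorm(n1 * k), n1, k)
    zf <- rnorm(k) + shift
    # RIL latent = mix * donor diallel parent + fresh segregation,
    # totalling `ril_latent_var` per latent dimension
    mix <- min(0.7, sqrt(config$ril_latent_var))
    fresh_sd <- sqrt(max(config$ril_latent_var - mix^2, 0))
    donors <- sample.int(n1, nm, replace = TRUE)
    zm <- mix * z1[donors, , drop = FALSE] +
      fresh_sd * matrix(rnorm(nm * k), nm, k)
    zm <- sweep(zm, 2L, shift, "+")

    line_ids <- c(rep(lines$pop1, each = config$replicates_per_parent),
                  lines$female, lines$males)
    rep_no <- c(rep(seq_len(config$replicates_per_parent), times = n1),
                rep(1L, 1L + nm))
    n_lines <- n1 + 1L + nm
    # line-level profile: shared latent structure plus an
    # analyte-specific biological component of each line
    z_lines <- rbind(z1, matrix(zf, 1L, k), zm)
    line_part <- z_lines %*% t(loadings) +
      matrix(rnorm(n_lines * p, sd = config$line_noise_sd), n_lines, p)
    m <- config$n_nuisance_latent
    if (m > 0L) {
      # population-2 lines only: background co-regulation axes
      z_nu <- matrix(rnorm((1L + nm) * m), 1L + nm, m)
      line_part[(n1 + 1L):n_lines, ] <-
        line_part[(n1 + 1L):n_lines, , drop = FALSE] +
        z_nu %*% t(s$background_loadings)
    }
    sample_of_line <- c(rep(seq_len(n1),
                            each = config$replicates_per_parent),
                        (n1 + 1L):n_lines)
    ns <- length(sample_of_line)
    eps <- matrix(rnorm(ns * p, sd = config$replicate_noise_sd), ns, p)
    values <- sweep(sweep(line_part[sample_of_line, , drop = FALSE] +
                            eps, 2L, sig, "*"), 2L, mu, "+")
    values <- pmax(values, 0)
    rownames(values) <- sprintf("%s_r%d", line_ids, rep_no)
    colnames(values) <- sprintf("A%04d", seq_len(p))
    groups <- c(rep(config$pop_labels[1L],
                    n1 * config$replicates_per_parent),
                rep(config$pop_labels[2L], 1L + nm))
    feature_table(values, line_ids = line_ids, groups = groups)
  })
}

#' Build the two-population pedigree
#'
#' Population 1 is the complete diallel of the population-1 parents:
#' all ordered pairs (female, male) with distinct parents, so
#' reciprocals are included and selfs excluded, giving
#' `n_parents_pop1 * (n_parents_pop1 - 1)` hybrids. Population 2
#' crosses the single CMS female to each RIL male.
#'
#' @param config A [scenario_config()].
#' @return Data frame with columns `hybrid_id`, `female_id`, `male_id`,
#'   `population`.
#' @export
build_pedigree <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lines <- .scenario_lines(config)
  pairs <- expand.grid(male_id = lines$pop1, female_id = lines$pop1,
                       stringsAsFactors = FALSE)[, c("female_id", "male_id")]
  pairs <- pairs[pairs$female_id != pairs$male_id, , drop = FALSE]
  ped1 <- data.frame(
    hybrid_id = paste0(pairs$female_id, "x", pairs$male_id),
    female_id = pairs$female_id, male_id = pairs$male_id,
    population = config$pop_labels[1L], stringsAsFactors = FALSE
  )
  ped2 <- data.frame(
    hybrid_id = paste0(lines$female, "x", lines$males),
    female_id = lines$female, male_id = lines$males,
    population = config$pop_labels[2L], stringsAsFactors = FALSE
  )
  ped <- rbind(ped1, ped2)
  rownames(ped) <- NULL
  ped
}

#' Simulate hybrid phenotypes from parental profiles
#'
#' TGW of hybrid h is
#' `intercept + sum_j effect_j(pop(h)) * midparent_hj +
#' env_offset(pop(h)) + N(0, noise_sd)`, with mid-parent values
#' computed exactly as in
#' [build_predictors()] (replicate-averaged parents, arithmetic mean of
#' the two parents). Effects on a random causal analyte subset are a
#' mixture of a component aligned with the latent loadings (fraction
#' `trait_latent_share` of the genetic variance flows through the
#' shared metabolome axes, so correlated non-causal analytes are
#' informative proxies) and an analyte-specific component. The latent
#' trait direction is drawn orthogonal to the population shift, the
#' effect vector is projected orthogonal to the between-population mean
#' difference of the causal predictors, and everything is rescaled so
#' the genetic component has standard deviation `effect_sd` across all
#' hybrids.
#'
#' @param parents A [feature_table()] of parental profiles.
#' @param pedigree Pedigree data frame as from [build_pedigree()].
#' @param config A [scenario_config()].
#' @return List with `phenotypes` (data frame `hybrid_id`, `tgw`) and
#'   `truth` (class `synthetic_truth`: causal analyte ids, one effect
#'   vector per population, intercept, per-population environment
#'   offsets, and the cross-environment effect correlation).
#' @export
simulate_phenotypes <- function(parents, pedigree, config) {
  stopifnot(inherits(config, "scenario_config"))
  predictors <- build_predictors(parents, pedigree)
  s <- .scenario_structure(config)
  with_seed(config$seed + 2L, {
    # trait-causal metabolites are drawn preferentially from the
    # strongly co-regulated part of the metabolome (weight ~ communality
    # + a floor), reflecting that causal metabolites of a complex trait
    # tend to sit in trait-relevant co-regulation modules
    canonical <- sprintf("A%04d", seq_len(config$n_analytes))
    weights <- if (identical(sort(colnames(predictors)), canonical))
      (s$lambda^2 + 0.1)[match(colnames(predictors), canonical)]
    else rep(1, ncol(predictors))
    causal <- sort(sample(colnames(predictors), config$n_causal,
                          prob = weights))
    if (config$n_causal > 0L) {
      # analyte positions in the canonical scenario structure; a custom
      # parent table falls back to analyte-independent effects
      causal_idx <- match(causal,
                          sprintf("A%04d", seq_len(config$n_analytes)))
      k <- config$n_latent
      # one shared latent trait axis (orthogonal to the population
      # shift) plus analyte-specific effects; genotype-by-environment
      # interaction acts on the analyte-specific effects, which are
      # correlated env_effect_cor across the two environments, while
      # the latent-mediated component is conserved
      v <- rnorm(k)
      if (k > 1L) {
        v <- v - sum(v * s$shift_dir) * s$shift_dir
        if (sum(v^2) < 1e-12) v <- rnorm(k)
      }
      v <- v / sqrt(sum(v^2))
      if (anyNA(causal_idx)) {
        aligned <- rep(0, config$n_causal)
      } else {
        aligned <- drop(s$loadings[causal_idx, , drop = FALSE] %*% v)
        a_scale <- sqrt(mean(aligned^2))
        if (a_scale > 0) aligned <- aligned / a_scale
      }
      # analyte-specific effects scale with the analyte's centrality in
      # the trait-relevant module (its trait-axis alignment), so the
      # causal signal is concentrated where a discriminant screen can
      # see it
      draw_own <- function() {
        own <- rnorm(config$n_causal)
        if (!anyNA(causal_idx)) {
          own <- own * pmax(abs(aligned), 0.3)
          o_scale <- sqrt(mean(own^2))
          if (o_scale > 0) own <- own / o_scale
        }
        own
      }
      w <- if (anyNA(causal_idx)) 0 else config$trait_latent_share
      own1 <- draw_own()
      rho <- config$env_effect_cor
      own2 <- rho * own1 + sqrt(1 - rho^2) * draw_own()
      b1 <- sqrt(w) * aligned + sqrt(1 - w) * own1
      # in environment 2 part of the trait additionally flows through
      # the population-2-specific background axes, which a
      # population-1-only training set cannot observe
      w_bg <- if (anyNA(causal_idx)) 0 else config$background_trait_share
      if (w_bg > 0 && config$n_nuisance_latent > 0L) {
        v_bg <- rnorm(config$n_nuisance_latent)
        v_bg <- v_bg / sqrt(sum(v_bg^2))
        a_bg <- drop(s$background_loadings[causal_idx, ,
                                           drop = FALSE] %*% v_bg)
        bg_scale <- sqrt(mean(a_bg^2))
        if (bg_scale > 0) a_bg <- a_bg / bg_scale
      } else {
        a_bg <- rep(0, config$n_causal)
        w_bg <- 0
      }
      b2 <- sqrt(1 - w_bg) * (sqrt(w) * aligned + sqrt(1 - w) * own2) +
        sqrt(w_bg) * a_bg
      sig_c <- if (anyNA(causal_idx)) rep(1, config$n_causal)
      else s$sig[causal_idx]
      beta1 <- b1 / sig_c
      beta2 <- b2 / sig_c
      pc <- predictors[, causal, drop = FALSE]
      is2 <- pedigree$population == config$pop_labels[2L]
      if (config$n_causal >= 2L && any(is2) && any(!is2)) {
        # match the group genetic means so the environment offset is
        # identifiable from the observed group means
        m2 <- colMeans(pc[is2, , drop = FALSE])
        t1 <- mean(pc[!is2, , drop = FALSE] %*% beta1)
        d2 <- sum(m2^2)
        if (d2 > 0) beta2 <- beta2 + (t1 - sum(m2 * beta2)) / d2 * m2
      }
      g <- numeric(nrow(pc))
      g[!is2] <- pc[!is2, , drop = FALSE] %*% beta1
      g[is2] <- pc[is2, , drop = FALSE] %*% beta2
      sg <- sd(g)
      scale <- if (is.finite(sg) && sg > 0) config$effect_sd / sg else 0
      beta1 <- beta1 * scale
      beta2 <- beta2 * scale
      g <- g * scale
    } else {
      beta1 <- beta2 <- numeric(0)
      g <- rep(0, nrow(predictors))
    }
    # absorb the mean genetic value into the baseline so the population
    # mean sits at the configured intercept; the linear truth formula
    # tgw = intercept + sum(effects * midparent) + offset stays exact
    intercept <- config$intercept - mean(g)
    offsets <- c(0, config$env_offset_pop2)
    names(offsets) <- config$pop_labels
    tgw <- intercept + g + offsets[pedigree$population] +
      rnorm(nrow(pedigree), sd = config$noise_sd)
    phenotypes <- data.frame(hybrid_id = pedigree$hybrid_id,
                             tgw = as.numeric(tgw),
                             stringsAsFactors = FALSE)
    causal_effects <- stats::setNames(
      list(beta1, beta2), config$pop_labels)
    truth <- structure(
      list(causal_analyte_ids = causal, causal_effects = causal_effects,
           intercept = intercept, env_offsets = offsets,
           env_effect_cor = config$env_effect_cor),
      class = "synthetic_truth"
    )
    list(phenotypes = phenotypes, truth = truth)
  })
}

#' Simulate a complete two-population study
#'
#' Convenience wrapper running [simulate_parents()], [build_pedigree()]
#' and [simulate_phenotypes()] under one configuration.
#'
#' @param config A [scenario_config()].
#' @return A `corehyb_scenario` list: `parents`, `pedigree`,
#'   `phenotypes`, `truth`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  parents <- simulate_parents(config)
  pedigree <- build_pedigree(config)
  ph <- simulate_phenotypes(parents, pedigree, config)
  structure(list(parents = parents, pedigree = pedigree,
                 phenotypes = ph$phenotypes, truth = ph$truth,
                 config = config),
            class = "corehyb_scenario")
}

#' @export
print.corehyb_scenario <- function(x, ...) {
  tab <- table(x$pedigree$population)
  cat(sprintf("<corehyb_scenario> %s hybrids (%s), %d analytes, %d causal\n",
              paste(tab, collapse = " + "),
              paste(names(tab), collapse = " / "),
              x$config$n_analytes,
              length(x$truth$causal_analyte_ids)))
  invisible(x)
}
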