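test_that("mid-parent predictors are arithmetic parent means", {
  vals <- rbind(P1_r1 = c(2, 10), P2_r1 = c(4, 20), P3_r1 = c(6, 60))
  colnames(vals) <- c("a", "b")
  parents <- feature_table(vals, line_ids = c("P1", "P2", "P3"))
  ped <- expand.grid(female_id = c("P1", "P2", "P3"),
                     male_id = c("P1", "P2", "P3"),
                     stringsAsFactors = FALSE)
  ped <- ped[ped$female_id != ped$male_id, ]
  ped$hybrid_id <- paste0(ped$female_id, "x", ped$male_id)
  ped$population <- "pop"
  P <- build_predictors(parents, ped)
  expect_equal(P["P1xP2", ], c(a = 3, b = 15))
  expect_equal(P["P1xP3", ], c(a = 4, b = 35))
  expect_equal(P["P2xP3", ], c(a = 5, b = 40))
  # symmetric in parent order: the full diallel collapses to 3 rows
  expect_equal(P["P2xP1", ], P["P1xP2", ])
  expect_equal(P["P3xP1", ], P["P1xP3", ])
  expect_equal(P["P3xP2", ], P["P2xP3", ])
})

test_that("subgroup boundaries are strict and the interval is closed", {
  ph <- data.frame(hybrid_id = paste0("h", 1:5),
                   tgw = c(28, 27, 24, 23.9, 25.5))
  sg <- assign_subgroups(ph)
  expect_equal(as.character(sg$subgroup),
               c("large", "medium", "medium", "small", "medium"))
  ph$tgw[2] <- NA
  expect_warning(sg2 <- assign_subgroups(ph), "missing TGW")
  expect_equal(nrow(sg2), 4L)
  expect_error(assign_subgroups(ph, low = 27, high = 24), "below")
})

test_that("marker selection is deterministic, monotone, and total at threshold 0", {
  sc <- simulate_scenario(tiny_config())
  P <- build_predictors(preprocess_parents(sc$parents), sc$pedigree)
  id1 <- sc$pedigree$hybrid_id[sc$pedigree$population == "2012"]
  sg <- assign_subgroups(sc$phenotypes,
                         low = quantile(sc$phenotypes$tgw, 1 / 3),
                         high = quantile(sc$phenotypes$tgw, 2 / 3))
  sg1 <- sg[sg$hybrid_id %in% id1, ]
  mk0 <- select_markers(P[id1, ], sg1, vip_threshold = 0)
  expect_setequal(mk0$analyte_ids, colnames(P))
  sets <- lapply(c(0.5, 1.0, 1.5), function(t)
    select_markers(P[id1, ], sg1, vip_threshold = t)$analyte_ids)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  mk_again <- select_markers(P[id1, ], sg1, vip_threshold = 0)
  expect_identical(mk0$vip, mk_again$vip)
})

test_that("marker selection refuses undersized extreme groups", {
  sc <- simulate_scenario(tiny_config())
  P <- build_predictors(preprocess_parents(sc$parents), sc$pedigree)
  sg <- data.frame(hybrid_id = rownames(P)[1:4],
                   tgw = c(30, 30, 20, 20),
                   subgroup = factor(c("large", "large", "small", "small"),
                                     levels = c("small", "medium", "large")))
  expect_error(select_markers(P, sg, 1.5), "at least 3")
})

test_that("causal analytes carry more VIP than non-causal ones when identifiable", {
  # strong per-analyte signal: few causal analytes, low phenotype noise
  cfg <- scenario_config(n_parents_pop1 = 12L, n_males_pop2 = 10L,
                         n_analytes = 200L, n_latent = 4L,
                         n_causal = 12L, noise_sd = 0.8,
                         trait_latent_share = 0.4,
                         n_nuisance_latent = 2L, seed = 42L)
  sc <- simulate_scenario(cfg)
  P <- build_predictors(preprocess_parents(sc$parents), sc$pedigree)
  id1 <- sc$pedigree$hybrid_id[sc$pedigree$population == "2012"]
  sg <- assign_subgroups(sc$phenotypes,
                         low = quantile(sc$phenotypes$tgw[
                           sc$pedigree$population == "2012"], 1 / 3),
                         high = quantile(sc$phenotypes$tgw[
                           sc$pedigree$population == "2012"], 2 / 3))
  mk <- select_markers(P[id1, ], sg[sg$hybrid_id %in% id1, ],
                       vip_threshold = 0)
  causal <- sc$truth$causal_analyte_ids
  expect_gt(mean(mk$vip[causal]),
            mean(mk$vip[setdiff(names(mk$vip), causal)]))
})

test_that("refiltering recomputes VIP on the regression model and nests", {
  sc <- simulate_scenario(tiny_config())
  P <- build_predictors(preprocess_parents(sc$parents), sc$pedigree)
  ids <- colnames(P)[1:20]
  tgw <- stats::setNames(sc$phenotypes$tgw, sc$phenotypes$hybrid_id)
  x <- autoscale(P[, ids])
  model <- fit_pls(x, tgw[rownames(P)], 4)
  current <- structure(list(analyte_ids = ids, vip_threshold = 0,
                            vip = NULL), class = "marker_set")
  # threshold 0 is the identity
  expect_identical(refilter_markers(model, current, 0)$analyte_ids, ids)
  # increasing thresholds give nested sets
  s1 <- refilter_markers(model, current, 0.8)$analyte_ids
  s2 <- refilter_markers(model, current, 1.2)$analyte_ids
  expect_true(all(s2 %in% s1))
  # survivors match an independent VIP computation from model pieces
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  v_oracle <- sqrt(length(ids) *
                     drop(model$weights^2 %*% ssy) / sum(ssy))
  expect_setequal(s1, ids[v_oracle > 0.8])
  # analyte mismatch is rejected
  expect_error(refilter_markers(model, ids[1:10], 0.5), "match")
})

test_that("threshold sweeps report non-increasing marker counts", {
  vip <- stats::setNames(c(0.2, 0.8, 1.1, 1.6, 2.3), paste0("a", 1:5))
  sw <- threshold_sweep(vip, c(0, 1, 1.5, 2, 3))
  expect_equal(sw$n_markers, c(5L, 3L, 2L, 1L, 0L))
  expect_true(all(diff(sw$n_markers) <= 0))
  sw2 <- threshold_sweep(vip, c(Inf, -1))
  expect_equal(sw2$n_markers, c(5L, 0L))  # sorted to (-1, Inf)
})
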