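make_eval_fixture <- function(...) {
  sc <- simulate_scenario(tiny_config(...))
  ped <- sc$pedigree
  P <- build_predictors(preprocess_parents(sc$parents), ped)
  pc1 <- pc1_scores(P)
  pops <- unique(ped$population)
  id1 <- ped$hybrid_id[ped$population == pops[1]]
  id2 <- ped$hybrid_id[ped$population == pops[2]]
  split <- compose_training(select_core(pc1[id1], 3, pops[1]),
                            select_core(pc1[id2], 2, pops[2]), ped)
  list(sc = sc, ped = ped, P = P, split = split, pops = pops,
       id1 = id1, id2 = id2)
}

test_that("training and prediction produce a coherent report", {
  f <- make_eval_fixture()
  rep <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:15],
                           f$split, ncomp_max = 10)
  expect_s3_class(rep, "prediction_report")
  expect_setequal(rep$hybrids$hybrid_id, f$ped$hybrid_id)
  expect_equal(sum(rep$hybrids$role == "train"),
               length(f$split$train_ids))
  expect_true(all(rep$populations$r >= -1 & rep$populations$r <= 1,
                  na.rm = TRUE))
  expect_equal(rep$n_markers, 15L)
  # deterministic
  rep2 <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:15],
                            f$split, ncomp_max = 10)
  expect_identical(rep$hybrids, rep2$hybrids)
})

test_that("validation phenotypes never influence the fitted predictions", {
  f <- make_eval_fixture()
  markers <- colnames(f$P)[1:20]
  rep <- train_and_predict(f$P, f$sc$phenotypes, markers, f$split)
  ph_perm <- f$sc$phenotypes
  is_val <- ph_perm$hybrid_id %in% f$split$validation_ids
  set.seed(1)
  ph_perm$tgw[is_val] <- sample(ph_perm$tgw[is_val])
  rep_perm <- train_and_predict(f$P, ph_perm, markers, f$split)
  # identical predictions, different correlations
  expect_identical(rep$hybrids$predicted, rep_perm$hybrids$predicted)
  expect_false(isTRUE(all.equal(rep$populations$r,
                                rep_perm$populations$r)))
})

test_that("a fixed latent-factor count is honored and capped", {
  f <- make_eval_fixture()
  rep <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:10],
                           f$split, ncomp = 3)
  expect_equal(rep$ncomp, 3L)
  rep_cap <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:2],
                               f$split, ncomp = 8)
  expect_lte(rep_cap$ncomp, 2L)
})

test_that("undersized validation populations are reported as undefined", {
  f <- make_eval_fixture()
  ped <- f$ped
  # train on everything except two population-2 hybrids
  keep_out <- f$id2[1:2]
  cs1 <- core_all(ped, f$pops[1])
  cs2 <- structure(list(selected_ids = setdiff(f$id2, keep_out),
                        N = NA_integer_, label = "All",
                        population = f$pops[2], scores = NULL),
                   class = "core_set")
  split <- compose_training(cs1, cs2, ped)
  rep <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:10],
                           split)
  row2 <- rep$populations[rep$populations$population == f$pops[2], ]
  expect_true(is.na(row2$r))
  expect_equal(row2$n_validation, 2L)
})

test_that("the experiment grid is one deterministic row per composition", {
  f <- make_eval_fixture()
  pc1 <- pc1_scores(f$P)
  comps <- list(
    compose_training(core_all(f$ped, f$pops[1]),
                     select_core(pc1[f$id2], 2, f$pops[2]), f$ped),
    f$split,
    f$split  # duplicated on purpose
  )
  grid <- experiment_grid(f$P, f$sc$phenotypes, colnames(f$P)[1:12],
                          comps, ncomp_max = 8)
  expect_equal(nrow(grid), 3L)
  expect_equal(grid[2, ], grid[3, ], ignore_attr = TRUE)
  expect_true(all(c(paste0("r_", f$pops), "n_train") %in% names(grid)))
})

test_that("marker-count sweeps align with single calls and handle empty sets", {
  f <- make_eval_fixture()
  vip <- stats::setNames(seq_len(ncol(f$P)) / ncol(f$P), colnames(f$P))
  sw <- marker_count_sweep(f$P, f$sc$phenotypes, vip, f$split,
                           thresholds = c(0.5, 2), ncomp_max = 8)
  expect_equal(sw$n_markers, c(sum(vip > 0.5), 0L))
  expect_true(all(is.na(sw[sw$n_markers == 0,
                           paste0("r_", f$pops)])))
  single <- train_and_predict(f$P, f$sc$phenotypes,
                              names(vip)[vip > 0.5], f$split,
                              ncomp_max = 8)
  for (pp in f$pops) {
    expect_equal(sw[[paste0("r_", pp)]][1],
                 single$populations$r[single$populations$population == pp])
  }
})

test_that("predictability is the Pearson correlation over validation hybrids", {
  f <- make_eval_fixture()
  rep <- train_and_predict(f$P, f$sc$phenotypes, colnames(f$P)[1:15],
                           f$split, ncomp_max = 8)
  v <- rep$hybrids[rep$hybrids$role == "validation" &
                     rep$hybrids$population == f$pops[2], ]
  expect_equal(
    rep$populations$r[rep$populations$population == f$pops[2]],
    cor(v$observed, v$predicted))
})

test_that("the full pipeline runs end to end and is reproducible", {
  sc <- simulate_scenario(tiny_config())
  a <- run_pipeline(sc, N_pop1 = 3, N_pop2 = 2, vip_threshold = 1.0,
                    subgroup_low = quantile(sc$phenotypes$tgw, 1 / 3),
                    subgroup_high = quantile(sc$phenotypes$tgw, 2 / 3))
  b <- run_pipeline(sc, N_pop1 = 3, N_pop2 = 2, vip_threshold = 1.0,
                    subgroup_low = quantile(sc$phenotypes$tgw, 1 / 3),
                    subgroup_high = quantile(sc$phenotypes$tgw, 2 / 3))
  expect_identical(a$report$hybrids, b$report$hybrids)
  expect_identical(a$markers$analyte_ids, b$markers$analyte_ids)
  expect_s3_class(a$report, "prediction_report")
  expect_true(a$ncomp >= 1L)
})
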