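test_that("PCA matches a brute-force eigendecomposition oracle", {
  x <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                5, 5, 1, 2), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
  pc <- fit_pca(x)
  ev <- eigen(cov(x))
  xc <- scale(x, center = TRUE, scale = FALSE)
  oracle_scores <- xc %*% ev$vectors
  for (a in 1:2) {
    ratio <- unname(pc$scores[, a] / oracle_scores[, a])
    expect_equal(abs(ratio), rep(1, 4), tolerance = 1e-8)
  }
  # explained variance from eigenvalues
  expect_equal(pc$explained_variance[1],
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  # loadings orthonormal
  g <- crossprod(pc$loadings)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA degenerate and symmetry cases behave", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(2, 4))
  rownames(x) <- paste0("s", 1:4)
  pc <- fit_pca(x)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)
  # duplicating samples leaves loadings unchanged
  pc2 <- fit_pca(rbind(x, x))
  expect_equal(abs(pc$loadings[, 1]), abs(pc2$loadings[, 1]),
               tolerance = 1e-10)
  expect_error(fit_pca(x[1, , drop = FALSE]), "2 samples")
})

test_that("PLS1 with a single predictor collapses to simple regression", {
  set.seed(11)
  x <- matrix(rnorm(15), 15, 1, dimnames = list(NULL, "x"))
  y <- 2 + 3 * x[, 1] + rnorm(15, sd = 0.3)
  m <- fit_pls(x, y, 1)
  ols <- lm(y ~ x[, 1])
  expect_equal(unname(m$coefficients), unname(coef(ols)[2]),
               tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("full-component PLS equals ordinary least squares on full-rank data", {
  for (seed in 1:5) {
    x <- rand_matrix(10, 3, seed = seed)
    set.seed(seed + 100)
    y <- drop(x %*% c(1, -2, 0.5)) + rnorm(10)
    m <- fit_pls(x, y, 3)
    xc <- cbind(1, x)
    b_ols <- solve(crossprod(xc), crossprod(xc, y))  # normal equations
    expect_equal(unname(m$coefficients), unname(b_ols[-1]),
                 tolerance = 1e-6)
    expect_equal(m$intercept, unname(b_ols[1]), tolerance = 1e-6)
  }
})

test_that("PLS scores are orthogonal and both prediction forms agree", {
  x <- rand_matrix(20, 8, seed = 12)
  set.seed(13)
  y <- rnorm(20)
  m <- fit_pls(x, y, 4)
  g <- crossprod(m$scores)
  off <- g - diag(diag(g))
  expect_true(max(abs(off)) < 1e-8 * max(diag(g)))
  # factor-form reconstruction: y_hat = y_center + T q
  yhat_factor <- unname(m$y_center + drop(m$scores %*% m$y_loadings))
  yhat_coef <- unname(predict(m, x))
  expect_equal(yhat_factor, yhat_coef, tolerance = 1e-8)
})

test_that("a response orthogonal to the predictors gives near-zero r2", {
  set.seed(17)
  x <- scale(rand_matrix(12, 3, seed = 17), scale = FALSE)
  y0 <- rnorm(12)
  y0 <- y0 - mean(y0)
  y <- y0 - drop(x %*% solve(crossprod(x), crossprod(x, y0)))
  y <- y + 1e-6 * rnorm(12)  # keep one component extractable
  m <- fit_pls(x, y, 1)
  expect_lt(m$r2, 1e-6)
})

test_that("requesting more factors than extractable reports the maximum", {
  x <- rand_matrix(6, 2, seed = 14)
  set.seed(15)
  y <- rnorm(6)
  expect_error(fit_pls(x, y, 5), "no more than 2 latent factor")
})

test_that("adjusted R2 follows its closed form and guards its domain", {
  expect_equal(adjusted_r2(1, 50, 5), 1)
  expect_equal(adjusted_r2(0.5, 101, 5), 1 - 0.5 * 100 / 95,
               tolerance = 1e-12)
  expect_equal(adjusted_r2(0.3, 20, 0), 0.3)
  expect_error(adjusted_r2(0.5, 6, 5), "n > k")
})

test_that("factor-count selection finds the generating rank", {
  set.seed(16)
  n <- 60; p <- 20
  t1 <- rnorm(n); t2 <- rnorm(n)
  x <- outer(t1, rnorm(p)) + outer(t2, rnorm(p))
  colnames(x) <- paste0("a", seq_len(p))
  y <- 2 * t1 - t2                    # exactly rank-2 signal
  sel <- select_n_components(x, y, 8)
  expect_equal(sel$ncomp, 2L)
  expect_equal(max(sel$r2_path), 1, tolerance = 1e-8)
  # training r2 path never decreases
  expect_true(all(diff(sel$r2_path) > -1e-10))
  # constant response: tie rule returns 1
  selc <- select_n_components(x, rep(3, n), 5)
  expect_equal(selc$ncomp, 1L)
  # A_max = 1
  expect_equal(select_n_components(x, y, 1)$ncomp, 1L)
})

test_that("VIP satisfies its normalization identity and hand-computed case", {
  # identity: mean VIP^2 = 1 over predictors, any model
  for (seed in 1:6) {
    x <- rand_matrix(15, 7, seed = seed)
    set.seed(seed + 50)
    y <- rnorm(15)
    m <- fit_pls(x, y, 3)
    for (a in 1:3) expect_equal(mean(vip(m, a)^2), 1, tolerance = 1e-8)
  }
  # single predictor: VIP exactly 1
  m1 <- fit_pls(matrix(rnorm(10), 10, 1), rnorm(10), 1)
  expect_equal(unname(m1$vip), 1)
  # six analytes, first weight vector proportional to (1,1,0,0,0,0):
  # component-1 VIP must be (sqrt(3), sqrt(3), 0, 0, 0, 0)
  set.seed(60)
  zc <- scale(rnorm(12), scale = FALSE)[, 1]
  noise <- scale(matrix(rnorm(12 * 4), 12, 4), scale = FALSE)
  noise <- noise - (zc %o% drop(crossprod(noise, zc))) / sum(zc^2)
  x <- cbind(zc, zc, noise)
  colnames(x) <- paste0("a", 1:6)
  m <- fit_pls(x, zc, 1)
  expect_equal(unname(vip(m, 1)), c(sqrt(3), sqrt(3), 0, 0, 0, 0),
               tolerance = 1e-8)
  expect_error(vip(m, 2), "only 1 component")
})

test_that("PLS-DA separates well-separated classes and honors symmetry", {
  set.seed(21)
  n <- 20
  x <- cbind(sep = c(rnorm(n / 2), rnorm(n / 2) + 10),
             matrix(rnorm(n * 5), n, 5))
  colnames(x) <- paste0("a", 1:6)
  labels <- rep(c("low", "high"), each = n / 2)
  da <- fit_plsda(x, labels, ncomp = 2, cv_seed = 7)
  expect_gt(da$q2, 0.9)
  expect_lte(da$q2, da$model$r2 + 1e-8)
  # flipping the class coding leaves VIP unchanged
  da_flip <- fit_plsda(x, rev(labels), ncomp = 2, cv_seed = 7)
  expect_equal(da$component1_vip, da_flip$component1_vip,
               tolerance = 1e-8)
  expect_error(fit_plsda(x, rep("one", n), 2), "two classes")
  expect_error(fit_plsda(x[1:4, ], c("a", "a", "b", "b"), 1),
               "at least 3")
})

test_that("PLS-DA Q2 stays low under the null", {
  set.seed(22)
  hits <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    x <- matrix(rnorm(20 * 8), 20, 8)
    colnames(x) <- paste0("a", 1:8)
    labels <- sample(rep(c("u", "v"), each = 10))
    da <- fit_plsda(x, labels, ncomp = 2, cv_seed = i)
    if (da$q2 <= 0.2) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("permutation p-values hit their floor and the add-one formula", {
  set.seed(23)
  x <- cbind(sep = c(rnorm(10), rnorm(10) + 8),
             matrix(rnorm(20 * 3), 20, 3))
  labels <- rep(c("s", "l"), each = 10)
  p19 <- permutation_test(x, labels, ncomp = 2, n_perm = 19, seed = 1)
  expect_equal(as.numeric(p19), 1 / 20)
  p1999 <- permutation_test(x, labels, ncomp = 2, n_perm = 1999,
                            seed = 1)
  expect_equal(as.numeric(p1999), 5e-4)
  expect_error(permutation_test(x, labels, ncomp = 2, n_perm = 10),
               "at least 19")
})

test_that("PLS predictions are invariant to analyte reordering", {
  x <- rand_matrix(15, 6, seed = 31)
  set.seed(32)
  y <- rnorm(15)
  m <- fit_pls(x, y, 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- fit_pls(x[, perm], y, 3)
  expect_equal(predict(m, x), predict(m2, x[, perm]), tolerance = 1e-10)
})
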