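#' Principal component analysis by singular value decomposition
#'
#' Centres the matrix, takes the SVD, and returns scores (`U %*% S`),
#' orthonormal loadings and per-component explained-variance
#' proportions. To make score orderings reproducible, each loading
#' column is flipped so that its largest-magnitude entry is positive.
#'
#' @param x Numeric matrix, samples x variables (at least 2 samples).
#' @return A `pca_result` list: `scores`, `loadings`,
#'   `explained_variance`, `center`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  sv <- svd(xc)
  d2 <- sv$d^2
  flip <- vapply(seq_along(sv$d), function(a) {
    v <- sv$v[, a]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1L))
  sv$v[, flip] <- -sv$v[, flip, drop = FALSE]
  sv$u[, flip] <- -sv$u[, flip, drop = FALSE]
  scores <- sweep(sv$u, 2L, sv$d, "*")
  rownames(scores) <- rownames(x)
  rownames(sv$v) <- colnames(x)
  colnames(scores) <- colnames(sv$v) <- paste0("PC", seq_along(sv$d))
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance = if (sum(d2) > 0) d2 / sum(d2)
                                      else rep(0, length(d2)),
                 center = center),
            class = "pca_result")
}

# NIPALS PLS1 on a centred predictor matrix and centred response.
# Extracts up to `ncomp` components, stopping early when the weight
# vector or score norm collapses (rank exhausted / response fully
# deflated). Weight columns have unit norm.
.nipals_pls1 <- function(xc, yc, ncomp) {
  n <- nrow(xc); p <- ncol(xc)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0); Q <- numeric(0)
  x_ref <- sum(xc^2); y_ref <- sum(yc^2)
  tol <- 1e-12
  # weight collapse is judged against rounding noise (|w| ~ eps*|X||y|),
  # not against the typical correlated scale, so genuinely weak but
  # real covariance still yields a component
  for (a in seq_len(ncomp)) {
    w <- crossprod(xc, yc)
    wn2 <- sum(w^2)
    if (!is.finite(wn2) || wn2 <= 1e-24 * max(x_ref * y_ref, 1e-300))
      break
    w <- w / sqrt(wn2)
    t <- xc %*% w
    tt <- sum(t^2)
    if (tt <= tol * max(x_ref, 1e-300)) break
    pv <- crossprod(xc, t) / tt
    q <- sum(yc * t) / tt
    xc <- xc - tcrossprod(t, pv)
    yc <- yc - q * t
    W <- cbind(W, w); P <- cbind(P, pv)
    Tm <- cbind(Tm, t); Q <- c(Q, q)
  }
  list(W = W, P = P, T = Tm, Q = Q, extracted = ncol(W))
}

# Regression coefficients (original predictor scale) from NIPALS
# factors: B = W (P'W)^{-1} q.
.pls_coef <- function(W, P, Q) {
  if (ncol(W) == 0L) return(numeric(nrow(W)))
  drop(W %*% solve(crossprod(P, W), Q))
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Classical NIPALS partial least squares with a single response:
#' repeatedly sets the weight vector to the (normalized) covariance
#' `X'y`, extracts the score `t = Xw`, computes X- and y-loadings, and
#' deflates both blocks. Predictors and response are centred
#' internally; any scaling (autoscaling) is the caller's
#' responsibility, so scaling can be learned on a training set only.
#'
#' @param x Numeric matrix, samples x predictors.
#' @param y Numeric response vector.
#' @param ncomp Number of latent factors to extract. If the data
#'   support fewer (rank exhausted or response fully deflated), an
#'   error reports the maximum extractable number.
#' @return A `pls_model` with weights `W`, x-loadings `P`, y-loadings
#'   `Q`, scores `T`, coefficients and intercept on the original
#'   predictor scale, fitted values, `r2`/`adjusted_r2`, the
#'   per-component `r2_path`, and the all-component VIP.
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  ncomp <- .assert_count(ncomp, "ncomp")
  if (nrow(x) != length(y))
    stop("`x` and `y` must have matching sample counts", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("`x` and `y` must be finite", call. = FALSE)
  x_center <- colMeans(x)
  y_center <- mean(y)
  xc <- sweep(x, 2L, x_center, "-")
  yc <- y - y_center
  nip <- .nipals_pls1(xc, yc, ncomp)
  if (nip$extracted < ncomp)
    stop(sprintf(
      "no more than %d latent factor(s) could be extracted (requested %d)",
      nip$extracted, ncomp), call. = FALSE)
  model <- .pls_model_from(nip, x_center, y_center, y,
                           analyte_ids = colnames(x))
  model
}

# Assemble a pls_model object from NIPALS factors.
.pls_model_from <- function(nip, x_center, y_center, y, analyte_ids) {
  A <- nip$extracted
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  contrib <- if (A > 0L) sweep(nip$T, 2L, nip$Q, "*") else
    matrix(0, n, 0)
  # cumulative fitted values and the per-component r2 path
  fitted_path <- y_center +
    (if (A > 0L) t(apply(contrib, 1L, cumsum)) else matrix(0, n, 0))
  if (A == 1L) fitted_path <- matrix(fitted_path, ncol = 1L)
  r2_path <- if (A > 0L)
    1 - colSums((y - fitted_path)^2) / max(tss, .Machine$double.xmin)
  else numeric(0)
  if (tss == 0) r2_path <- rep(0, A)
  coefficients <- .pls_coef(nip$W, nip$P, nip$Q)
  names(coefficients) <- analyte_ids
  intercept <- y_center - sum(x_center * coefficients)
  fitted <- if (A > 0L) fitted_path[, A] else rep(y_center, n)
  r2 <- if (A > 0L) r2_path[A] else 0
  adj <- if (A > 0L && n > A + 1L) adjusted_r2(r2, n, A) else NA_real_
  if (!is.null(analyte_ids)) rownames(nip$W) <- rownames(nip$P) <-
      analyte_ids
  model <- structure(list(
    ncomp = A, weights = nip$W, x_loadings = nip$P, y_loadings = nip$Q,
    scores = nip$T, coefficients = coefficients, intercept = intercept,
    x_center = x_center, y_center = y_center, fitted = fitted,
    r2 = r2, adjusted_r2 = adj, r2_path = r2_path, n = n,
    analyte_ids = analyte_ids
  ), class = "pls_model")
  model$vip <- if (A > 0L) vip(model) else rep(NA_real_, nrow(nip$W))
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent factor(s), %d predictors, n = %d, R2 = %.4f\n",
              x$ncomp, length(x$coefficients), x$n, x$r2))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix of predictors on the same scale (and column
#'   order) the model was fitted on.
#' @param ... Unused.
#' @return Numeric vector of predictions, `intercept + newdata %*% B`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("`newdata` has the wrong number of predictors", call. = FALSE)
  drop(object$intercept + newdata %*% object$coefficients)
}

#' Adjusted R-squared for a PLS model
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)`, with `k` the number of
#' latent factors counted as the model degrees of freedom.
#'
#' @param r2 Training R-squared (vectorized).
#' @param n Number of training samples.
#' @param k Number of latent factors (vectorized with `r2`).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (any(n <= k + 1L))
    stop("adjusted R2 requires n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Choose the number of latent factors by peak adjusted R-squared
#'
#' Fits PLS with 1..`ncomp_max` latent factors (capped at the number
#' the data support and at `n - 2` so the adjusted R-squared is
#' defined) and returns the factor count with the highest adjusted
#' R-squared; exact ties go to the smaller count. A response with no
#' extractable covariance (e.g. constant y) returns 1 with a
#' degenerate intercept-only model.
#'
#' @param x Predictor matrix (already scaled as desired).
#' @param y Response vector.
#' @param ncomp_max Largest factor count to consider.
#' @return List with `ncomp` (the selection), `adjusted_r2_path`,
#'   `r2_path`, `ncomp_max_extractable`, and `model` (refit at the
#'   selected count).
#' @export
select_n_components <- function(x, y, ncomp_max) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  ncomp_max <- .assert_count(ncomp_max, "ncomp_max")
  n <- length(y)
  cap_request <- min(ncomp_max, max(n - 2L, 1L), ncol(x))
  xc <- sweep(x, 2L, colMeans(x), "-")
  nip <- .nipals_pls1(xc, y - mean(y), cap_request)
  cap <- nip$extracted
  if (cap == 0L) {
    model <- .pls_model_from(nip, colMeans(x), mean(y), y, colnames(x))
    return(list(ncomp = 1L, adjusted_r2_path = numeric(0),
                r2_path = numeric(0), ncomp_max_extractable = 0L,
                model = model))
  }
  model_full <- .pls_model_from(nip, colMeans(x), mean(y), y,
                                colnames(x))
  r2_path <- model_full$r2_path
  adj_path <- if (n > cap + 1L) adjusted_r2(r2_path, n, seq_len(cap))
  else {
    ok <- seq_len(max(n - 2L, 0L))
    c(adjusted_r2(r2_path[ok], n, ok), rep(-Inf, cap - length(ok)))
  }
  ncomp <- which.max(adj_path)  # first max: ties go to the smaller count
  list(ncomp = as.integer(ncomp), adjusted_r2_path = adj_path,
       r2_path = r2_path, ncomp_max_extractable = cap,
       model = fit_pls(x, y, ncomp))
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP over the first `components` latent factors:
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with
#' `SSY_a = q_a^2 * t_a't_a` and unit-norm weight vectors, so the mean
#' of `VIP^2` over the `p` predictors is exactly 1. With
#' `components = 1` this reduces to `sqrt(p) * |w_j1|`.
#'
#' @param model A `pls_model`.
#' @param components Number of leading components to use (default: all
#'   fitted components).
#' @return Named numeric vector of VIP values.
#' @export
vip <- function(model, components = model$ncomp) {
  stopifnot(inherits(model, "pls_model"))
  components <- .assert_count(components, "components")
  if (components > model$ncomp)
    stop(sprintf("model has only %d component(s)", model$ncomp),
         call. = FALSE)
  idx <- seq_len(components)
  ssy <- model$y_loadings[idx]^2 * colSums(model$scores[, idx,
                                                        drop = FALSE]^2)
  p <- nrow(model$weights)
  w2 <- model$weights[, idx, drop = FALSE]^2
  denom <- sum(ssy)
  if (denom <= 0) return(stats::setNames(rep(NA_real_, p),
                                         model$analyte_ids))
  v <- sqrt(p * drop(w2 %*% ssy) / denom)
  names(v) <- model$analyte_ids
  v
}

#' PLS discriminant analysis with cross-validated Q-squared
#'
#' Codes a two-class factor as 0/1, fits [fit_pls()], and estimates the
#' predictive ability Q-squared by stratified k-fold cross-validation:
#' `Q2 = 1 - PRESS / TSS` with PRESS accumulated over held-out folds.
#' Also returns the Component-1 VIP used for marker screening. The
#' requested component count is capped at what the data support.
#'
#' @param x Predictor matrix (scaled as desired).
#' @param labels Two-level factor (or coercible), each class with at
#'   least 3 samples.
#' @param ncomp Latent factors (default 4).
#' @param nfold Cross-validation folds (default 10, reduced to the
#'   smaller class size if needed).
#' @param cv_seed Seed for the fold assignment.
#' @return A `plsda_result`: `model`, `q2`, `component1_vip`,
#'   `coding`, `ncomp`.
#' @export
fit_plsda <- function(x, labels, ncomp = 4L, nfold = 10L, cv_seed = 1L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("PLS-DA requires exactly two classes", call. = FALSE)
  if (any(table(labels) < 3L))
    stop("each class needs at least 3 samples", call. = FALSE)
  y <- as.numeric(labels == levels(labels)[2L])
  cap <- .pls_max_components(x, y, ncomp)
  ncomp_used <- max(min(ncomp, cap), 1L)
  model <- fit_pls(x, y, ncomp_used)
  nfold <- min(nfold, min(table(labels)))
  folds <- integer(length(y))
  with_seed(cv_seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- rep_len(seq_len(nfold), length(idx))[sample.int(length(idx))]
    }
  })
  press <- 0
  for (f in seq_len(nfold)) {
    tr <- folds != f
    cap_f <- .pls_max_components(x[tr, , drop = FALSE], y[tr], ncomp_used)
    if (cap_f == 0L) {
      pred <- rep(mean(y[tr]), sum(!tr))
    } else {
      mf <- fit_pls(x[tr, , drop = FALSE], y[tr], min(ncomp_used, cap_f))
      pred <- predict(mf, x[!tr, , drop = FALSE])
    }
    press <- press + sum((y[!tr] - pred)^2)
  }
  tss <- sum((y - mean(y))^2)
  structure(list(model = model, q2 = 1 - press / tss,
                 component1_vip = vip(model, 1L),
                 coding = stats::setNames(c(0, 1), levels(labels)),
                 ncomp = ncomp_used),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("<plsda_result> %d component(s), R2 = %.3f, Q2 = %.3f\n",
              x$ncomp, x$model$r2, x$q2))
  invisible(x)
}

# Largest extractable component count for (x, y), up to `limit`.
.pls_max_components <- function(x, y, limit) {
  xc <- sweep(as.matrix(x), 2L, colMeans(x), "-")
  .nipals_pls1(xc, y - mean(y), limit)$extracted
}

# Training R2 of a PLS fit on centred data; fast path used by the
# permutation test.
.pls_r2 <- function(xc, y, ncomp) {
  yc <- y - mean(y)
  nip <- .nipals_pls1(xc, yc, ncomp)
  if (nip$extracted == 0L) return(0)
  resid <- yc - drop(nip$T %*% nip$Q)
  tss <- sum(yc^2)
  if (tss == 0) 0 else 1 - sum(resid^2) / tss
}

#' Permutation test for a PLS-DA model
#'
#' Tests whether the class separation achieved by the PLS-DA model
#' exceeds chance. The statistic is the training R-squared of the
#' class-coded PLS fit; class labels are permuted `n_perm` times and
#' the p-value uses the add-one estimator
#' `(1 + #(permuted >= observed)) / (1 + n_perm)`, so the smallest
#' attainable p-value is `1 / (1 + n_perm)` (e.g. 5e-4 at 1999
#' permutations).
#'
#' @param x Predictor matrix (scaled as desired).
#' @param labels Two-level class labels.
#' @param ncomp Latent factors for the fit.
#' @param n_perm Number of permutations, at least 19.
#' @param seed Seed for the permutations.
#' @return The permutation p-value, with attributes `observed` and
#'   `permuted` (the null statistics).
#' @export
permutation_test <- function(x, labels, ncomp = 4L, n_perm = 999L,
                             seed = 1L) {
  n_perm <- .assert_count(n_perm, "n_perm")
  if (n_perm < 19L)
    stop("`n_perm` must be at least 19 (else p cannot reach 0.05)",
         call. = FALSE)
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("permutation test requires exactly two classes", call. = FALSE)
  y <- as.numeric(labels == levels(labels)[2L])
  xc <- sweep(x, 2L, colMeans(x), "-")
  limit <- min(ncomp, max(nrow(x) - 2L, 1L))
  observed <- .pls_r2(xc, y, limit)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) .pls_r2(xc, sample(y), limit), numeric(1L))
  })
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  attr(p, "observed") <- observed
  attr(p, "permuted") <- permuted
  p
}
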