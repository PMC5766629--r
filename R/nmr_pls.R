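# Latent-variable discrimination for binned NMR matrices.
#
# The decompositions are implemented here directly (NIPALS PLS1 and
# orthogonal signal correction), because the scores/VIP/permutation
# machinery is the analytical core of the workflow; generic fitters are
# used only as cross-checks in the test suite.

scale_columns <- function(X, scaling = c("uv", "center", "pareto"),
                          center = NULL, scale = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  Xc <- X - rep(center, each = nrow(X))
  if (is.null(scale)) {
    s <- sqrt(colSums(Xc^2) / max(nrow(X) - 1L, 1L))
    s[s == 0] <- 1 # constant column: center only
    scale <- switch(scaling, uv = s, pareto = sqrt(s),
                    center = rep(1, ncol(X)))
  } else {
    Xc <- X - rep(center, each = nrow(X))
  }
  Xs <- Xc / rep(scale, each = nrow(X))
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

encode_y <- function(y) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("exactly two classes required, got ", length(lev))
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  list(y01 = as.numeric(as.character(y) == lev[2]), levels = lev)
}

# NIPALS PLS1 on centered/scaled X and centered univariate y.
# With a single y the weight step is closed-form per component.
pls1_core <- function(Xs, yc, n_comp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  C <- numeric(0)
  ssx0 <- sum(Xs^2); ssy0 <- sum(yc^2)
  E <- Xs; f <- yc
  r2x <- r2y <- numeric(0)
  for (a in seq_len(n_comp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # no covariance left to model
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- as.numeric(crossprod(E, t)) / tt
    cv <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - cv * t
    W <- cbind(W, w); P <- cbind(P, pv); Tm <- cbind(Tm, t); C <- c(C, cv)
    r2x <- c(r2x, 1 - sum(E^2) / ssx0)
    r2y <- c(r2y, 1 - sum(f^2) / ssy0)
  }
  if (ncol(W) == 0L) stop("X carries no covariance with y; no component fitted")
  list(W = W, P = P, scores = Tm, C = C, r2x = r2x, r2y = r2y,
       x_residual = E, y_residual = f)
}

pls1_predict <- function(core, Xs_new) {
  E <- Xs_new
  yhat <- numeric(nrow(Xs_new))
  for (a in seq_along(core$C)) {
    t <- as.numeric(E %*% core$W[, a])
    E <- E - tcrossprod(t, core$P[, a])
    yhat <- yhat + core$C[a] * t
  }
  yhat
}

vip_pls1 <- function(core) {
  ssy_a <- core$C^2 * colSums(core$scores^2)
  p <- nrow(core$W)
  vip <- sqrt(p * as.numeric(core$W^2 %*% ssy_a) / sum(ssy_a))
  setNames(vip, rownames(core$W))
}

venetian_folds <- function(n, k) {
  k <- min(k, n)
  split(seq_len(n), rep_len(seq_len(k), n))
}

# Cumulative Q2 per component by k-fold venetian-blind CV (folds interleave
# samples in their given order). Scaling/centering is re-estimated inside
# each training fold. Returns a vector Q2[1..n_comp].
q2_cv <- function(X, y01, n_comp, scaling, cv_folds = 7) {
  n <- nrow(X)
  folds <- venetian_folds(n, cv_folds)
  press <- matrix(NA_real_, length(folds), n_comp)
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    if (length(unique(y01[-hold])) < 2L) {
      stop("cross-validation fold leaves a single class in training data")
    }
    Xtr <- scale_columns(X[-hold, , drop = FALSE], scaling)
    ybar <- mean(y01[-hold])
    ytr <- y01[-hold] - ybar
    core <- pls1_core(Xtr, ytr, n_comp)
    Xte <- scale_columns(X[hold, , drop = FALSE], scaling,
                         center = attr(Xtr, "center"),
                         scale = attr(Xtr, "scale"))
    E <- Xte
    yhat <- numeric(length(hold))
    for (a in seq_len(n_comp)) {
      if (a <= length(core$C)) {
        t <- as.numeric(E %*% core$W[, a])
        E <- E - tcrossprod(t, core$P[, a])
        yhat <- yhat + core$C[a] * t
      }
      press[i, a] <- sum((y01[hold] - (ybar + yhat))^2)
    }
  }
  ss <- sum((y01 - mean(y01))^2)
  1 - colSums(press) / ss
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis for a two-class binned
#' spectral matrix: NIPALS PLS1 on the 0/1-coded, centered class vector
#' after column scaling of X (unit variance by default). Predictive power
#' is assessed by Q2 from 7-fold venetian-blind cross-validation
#' (Q2 = 1 - PRESS/SS, cumulative over components); with `n_comp = "auto"`
#' components are added while each raises Q2 by more than 0.01.
#'
#' @param X samples x variables numeric matrix (or a `netmet_binned`, whose
#'   `X` and `groups` are used).
#' @param y two-class labels (ignored when `X` is a `netmet_binned`).
#' @param n_comp integer number of components, or `"auto"`.
#' @param scaling `"uv"` (unit variance, default), `"center"`, or
#'   `"pareto"`.
#' @param cv_folds folds for Q2 (default 7).
#' @return object of class `netmet_pls` with fields `kind`, `n_pred`,
#'   `n_orth`, `scores`, `loadings`, `weights`, `y_loadings`, `r2x`, `r2y`,
#'   `q2` (final cumulative values; per-component vectors in `r2x_comp`,
#'   `r2y_comp`, `q2_comp`), `vip`, `splot_cov`, `splot_corr`, `levels`.
#' @export
fit_plsda <- function(X, y = NULL, n_comp = "auto", scaling = "uv",
                      cv_folds = 7) {
  if (inherits(X, "netmet_binned")) { y <- X$groups; X <- X$X }
  X <- as.matrix(X)
  enc <- encode_y(y)
  max_comp <- min(nrow(X) - 2L, ncol(X), 10L)
  if (identical(n_comp, "auto")) {
    q2_all <- q2_cv(X, enc$y01, max_comp, scaling, cv_folds)
    gain <- diff(c(0, q2_all))
    A <- if (gain[1] <= 0.01) 1L else max(which(cumall(gain > 0.01)))
  } else {
    A <- as.integer(n_comp)
    if (A < 1L || A >= min(nrow(X), ncol(X) + 1L)) {
      stop("n_comp must satisfy 1 <= n_comp < min(n samples, n variables + 1)")
    }
  }
  Xs <- scale_columns(X, scaling)
  yc <- enc$y01 - mean(enc$y01)
  core <- pls1_core(Xs, yc, A)
  A <- length(core$C)
  q2_comp <- q2_cv(X, enc$y01, A, scaling, cv_folds)
  t1 <- core$scores[, 1]
  structure(list(
    kind = "PLS-DA", n_pred = A, n_orth = 0L,
    scores = core$scores, loadings = core$P, weights = core$W,
    y_loadings = core$C,
    r2x = core$r2x[A], r2y = core$r2y[A], q2 = q2_comp[A],
    r2x_comp = core$r2x, r2y_comp = core$r2y, q2_comp = q2_comp,
    vip = setNames(as.numeric(vip_pls1(core)), colnames(X)),
    splot_cov = splot_stat(Xs, t1)$cov,
    splot_corr = splot_stat(Xs, t1)$corr,
    levels = enc$levels, scaling = scaling, cv_folds = cv_folds,
    center = attr(Xs, "center"), scale = attr(Xs, "scale")
  ), class = "netmet_pls")
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

splot_stat <- function(Xs, t) {
  n <- nrow(Xs)
  cv <- as.numeric(crossprod(Xs, t)) / (n - 1)
  st <- sd(t)
  sx <- sqrt(colSums((Xs - rep(colMeans(Xs), each = n))^2) / (n - 1))
  corr <- cv / (st * sx)
  corr[!is.finite(corr)] <- 0
  list(cov = setNames(cv, colnames(Xs)), corr = setNames(corr, colnames(Xs)))
}

#' @export
print.netmet_pls <- function(x, ...) {
  cat(sprintf("%s: %d predictive + %d orthogonal component(s)\n",
              x$kind, x$n_pred, x$n_orth))
  cat(sprintf("R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n", x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model under `n_perm` random shuffles of the class labels and
#' records each permuted fit's R2Y and Q2. The model is judged valid when
#' every permuted R2Y *and* Q2 falls strictly below the original values —
#' the standard response-permutation check against overfit discrimination.
#' Label shuffles are drawn uniformly (the accidental identity permutation
#' is not excluded; its probability is negligible at the default 200).
#'
#' @param X samples x variables matrix or `netmet_binned`.
#' @param y two-class labels (ignored for `netmet_binned`).
#' @param n_comp fixed component count for every fit.
#' @param scaling column scaling (as [fit_plsda()]).
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed controlling the shuffles.
#' @param cv_folds folds for Q2.
#' @return object of class `netmet_perm`: `n_perm`, `r2_perm`, `q2_perm`,
#'   `r2_orig`, `q2_orig`, `valid`.
#' @export
permutation_validate <- function(X, y = NULL, n_comp = 2, scaling = "uv",
                                 n_perm = 200, seed = 1, cv_folds = 7) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(X, "netmet_binned")) { y <- X$groups; X <- X$X }
  X <- as.matrix(X)
  orig <- fit_plsda(X, y, n_comp = n_comp, scaling = scaling,
                    cv_folds = cv_folds)
  lev2 <- sort(unique(as.character(y)))[2]
  r2p <- q2p <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yb01 <- as.numeric(sample(y) == lev2)
      fit <- tryCatch({
        core <- pls1_core(scale_columns(X, scaling), yb01 - mean(yb01), n_comp)
        A <- length(core$C)
        c(core$r2y[A], q2_cv(X, yb01, A, scaling, cv_folds)[A])
      }, error = function(e) c(0, -Inf))
      r2p[b] <- fit[1]; q2p[b] <- fit[2]
    }
  })
  structure(list(
    n_perm = as.integer(n_perm), r2_perm = r2p, q2_perm = q2p,
    r2_orig = orig$r2y, q2_orig = orig$q2,
    valid = all(r2p < orig$r2y) && all(q2p < orig$q2)
  ), class = "netmet_perm")
}

#' @export
print.netmet_perm <- function(x, ...) {
  cat(sprintf(
    "permutation validation (%d shuffles): R2Y = %.3f (perm max %.3f), Q2 = %.3f (perm max %.3f) -> %s\n",
    x$n_perm, x$r2_orig, max(x$r2_perm), x$q2_orig, max(x$q2_perm),
    if (x$valid) "VALID" else "NOT valid"))
  invisible(x)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projection to latent structures: variation in X orthogonal to
#' the class vector is removed by `n_orth` orthogonal components, then a
#' single predictive component is fitted on the filtered matrix. This
#' concentrates between-class separation in one predictive score and is the
#' standard follow-up to PLS-DA for biomarker screening. S-plot statistics
#' (covariance and correlation of each scaled variable with the predictive
#' score) and VIP (from the predictive weight vector) are returned for
#' variable selection. Q2 is computed by 7-fold venetian-blind
#' cross-validation of the whole filter+fit sequence.
#'
#' @inheritParams fit_plsda
#' @param n_orth number of orthogonal components (default 1).
#' @return object of class `netmet_pls` (kind `"OPLS-DA"`); additionally
#'   `scores_orth`, `loadings_orth`, `weights_orth`, `r2x_orth`.
#' @export
fit_oplsda <- function(X, y = NULL, n_orth = 1, scaling = "uv",
                       cv_folds = 7) {
  if (inherits(X, "netmet_binned")) { y <- X$groups; X <- X$X }
  X <- as.matrix(X)
  enc <- encode_y(y)
  Xs <- scale_columns(X, scaling)
  yc <- enc$y01 - mean(enc$y01)
  fit <- opls_core(Xs, yc, n_orth)
  q2 <- opls_q2(X, enc$y01, n_orth, scaling, cv_folds)
  ss <- splot_stat(Xs, fit$t_pred)
  p <- ncol(Xs)
  structure(list(
    kind = "OPLS-DA", n_pred = 1L, n_orth = fit$n_orth,
    scores = matrix(fit$t_pred, ncol = 1), loadings = matrix(fit$p_pred, ncol = 1),
    weights = matrix(fit$w, ncol = 1), y_loadings = fit$c,
    scores_orth = fit$T_orth, loadings_orth = fit$P_orth,
    weights_orth = fit$W_orth,
    r2x = fit$r2x_pred, r2x_orth = fit$r2x_orth, r2y = fit$r2y, q2 = q2,
    vip = setNames(sqrt(p) * abs(fit$w), colnames(Xs)),
    splot_cov = ss$cov, splot_corr = ss$corr,
    levels = enc$levels, scaling = scaling, cv_folds = cv_folds,
    center = attr(Xs, "center"), scale = attr(Xs, "scale")
  ), class = "netmet_pls")
}

opls_core <- function(Xs, yc, n_orth) {
  ssx0 <- sum(Xs^2); ssy0 <- sum(yc^2)
  w <- as.numeric(crossprod(Xs, yc))
  w <- w / sqrt(sum(w^2))
  E <- Xs
  W_orth <- P_orth <- matrix(0, ncol(Xs), 0)
  T_orth <- matrix(0, nrow(Xs), 0)
  r2x_orth <- 0
  for (j in seq_len(n_orth)) {
    t <- as.numeric(E %*% w)
    pv <- as.numeric(crossprod(E, t)) / sum(t^2)
    wo <- pv - as.numeric(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break # no y-orthogonal structure left
    wo <- wo / nwo
    to <- as.numeric(E %*% wo)
    po <- as.numeric(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    W_orth <- cbind(W_orth, wo); P_orth <- cbind(P_orth, po)
    T_orth <- cbind(T_orth, to)
    r2x_orth <- r2x_orth + sum(to^2) * sum(po^2) / ssx0
  }
  t_pred <- as.numeric(E %*% w)
  tt <- sum(t_pred^2)
  p_pred <- as.numeric(crossprod(E, t_pred)) / tt
  cc <- sum(yc * t_pred) / tt
  list(w = w, t_pred = t_pred, p_pred = p_pred, c = cc,
       W_orth = W_orth, P_orth = P_orth, T_orth = T_orth,
       n_orth = ncol(W_orth),
       r2x_pred = tt * sum(p_pred^2) / ssx0, r2x_orth = r2x_orth,
       r2y = 1 - sum((yc - cc * t_pred)^2) / ssy0)
}

opls_q2 <- function(X, y01, n_orth, scaling, cv_folds) {
  folds <- venetian_folds(nrow(X), cv_folds)
  press <- 0
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    if (length(unique(y01[-hold])) < 2L) {
      stop("cross-validation fold leaves a single class in training data")
    }
    Xtr <- scale_columns(X[-hold, , drop = FALSE], scaling)
    ybar <- mean(y01[-hold])
    fit <- opls_core(Xtr, y01[-hold] - ybar, n_orth)
    Xte <- scale_columns(X[hold, , drop = FALSE], scaling,
                         center = attr(Xtr, "center"),
                         scale = attr(Xtr, "scale"))
    E <- Xte
    for (j in seq_len(fit$n_orth)) {
      to <- as.numeric(E %*% fit$W_orth[, j])
      E <- E - tcrossprod(to, fit$P_orth[, j])
    }
    yhat <- ybar + fit$c * as.numeric(E %*% fit$w)
    press <- press + sum((y01[hold] - yhat)^2)
  }
  1 - press / sum((y01 - mean(y01))^2)
}
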