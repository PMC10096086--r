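#' Fit a PLS1 regression model by NIPALS
#'
#' Single-response partial least squares: the predictor matrix and response
#' are scaled (training statistics only), then decomposed into `A` latent
#' variables by NIPALS deflation — each component takes the weight vector
#' `w = X'y / |X'y|`, scores `t = Xw`, loadings `p = X't/(t't)` and
#' y-loading `q = y't/(t't)`, after which `t p'` and `t q` are deflated from
#' `X` and `y`. The regression vector in scaled space is
#' `B = W (P'W)^-1 q`; at `A = rank(X)` it coincides with the ordinary
#' least-squares solution.
#'
#' @param X Predictor matrix or data frame (records x variables).
#' @param y Numeric response (retention time, min).
#' @param A Number of latent variables, `>= 1`.
#' @param scale Preprocessing: `"autoscale"` or `"mean-center"` (applied to
#'   both `X` and `y`; y is always at least centered).
#' @return An object of class `qsrr_pls`: weights `W`, loadings `P`, scores
#'   `T`, y-scores `U`, y-loadings `q`, inner coefficients `b_inner`,
#'   scaled-space coefficients `B`, residuals `D` (X) and `F_res` (y),
#'   scaling models, `A`, fitted values on the response scale.
#' @export
fit_pls <- function(X, y, A, scale = c("autoscale", "mean-center")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), A >= 1L)
  rk <- qr(base::scale(X, center = TRUE, scale = FALSE))$rank
  if (A > rk) {
    stop(sprintf("fit_pls(): A = %d exceeds the rank of centered X (max %d)",
                 A, rk), call. = FALSE)
  }
  xs <- fit_apply_scaling(X, mode = scale)
  ys <- fit_apply_scaling(matrix(y, ncol = 1L),
                          mode = if (scale == "autoscale") "autoscale"
                                 else "mean-center")
  Xc <- xs$train
  yc <- as.numeric(ys$train)
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, A)
  Tm <- U <- matrix(0, n, A)
  q <- b_inner <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # response fully explained (e.g. noiseless data): keep what we have
      warning(sprintf("fit_pls(): response exhausted after %d components; A truncated",
                      a - 1L))
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Tm <- Tm[, seq_len(A), drop = FALSE]; U <- U[, seq_len(A), drop = FALSE]
      q <- q[seq_len(A)]; b_inner <- b_inner[seq_len(A)]
      break
    }
    w <- w / nw
    tt <- as.numeric(Xc %*% w)
    t2 <- sum(tt^2)
    pl <- as.numeric(crossprod(Xc, tt)) / t2
    qa <- sum(yc * tt) / t2
    U[, a] <- yc / if (abs(qa) > 1e-14) qa else 1
    W[, a] <- w
    P[, a] <- pl
    Tm[, a] <- tt
    q[a] <- qa
    b_inner[a] <- sum(tt * U[, a]) / t2
    Xc <- Xc - tcrossprod(tt, pl)
    yc <- yc - tt * qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  rownames(W) <- rownames(P) <- rownames(B) <- colnames(X)
  fitted_scaled <- xs$train %*% B
  fitted <- as.numeric(scale_invert(ys, fitted_scaled))
  structure(list(
    W = W, P = P, T = Tm, U = U, q = q, b_inner = b_inner, B = B,
    D = Xc, F_res = yc, A = A,
    x_scaling = ys_strip(xs), y_scaling = ys_strip(ys),
    scale_mode = scale, fitted = fitted, y = y,
    var_names = colnames(X)
  ), class = "qsrr_pls")
}

# keep only the statistics of a scaling (drop the scaled copies of the data)
ys_strip <- function(s) {
  structure(list(center = s$center, scale = s$scale, mode = s$mode),
            class = "qsrr_scaling")
}

#' Predict retention times from a fitted PLS model
#'
#' @param object A `qsrr_pls` model.
#' @param newdata Matrix or data frame containing the model's predictor
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the response scale (min).
#' @export
predict.qsrr_pls <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (all(object$var_names %in% names(newdata))) {
    newdata <- newdata[, object$var_names, drop = FALSE]
  }
  Xn <- scale_apply(object$x_scaling, as.matrix(newdata))
  as.numeric(scale_invert(object$y_scaling, Xn %*% object$B))
}

#' @export
print.qsrr_pls <- function(x, ...) {
  cat(sprintf("<qsrr_pls> %d latent variables over %d predictors (%s)\n",
              x$A, length(x$var_names), x$scale_mode))
  cat(sprintf("training RMSE %.4f over %d records\n",
              rmse(x$y, x$fitted), length(x$y)))
  invisible(x)
}

#' Venetian-blinds cross-validation of a PLS model
#'
#' Interleaved cancellation groups: group `g` holds the records at positions
#' `g, g + k, g + 2k, ...` in the given row order. For each candidate number
#' of latent variables every group is predicted by a model fit on the
#' others; RMSECV and R2cv are computed over the pooled held-out
#' predictions. The chosen complexity is the smallest `A` whose RMSECV is
#' within 2% of the global minimum (parsimony rule).
#'
#' @param X,y Training predictors and response (row order defines the
#'   blinds).
#' @param A_max Largest number of latent variables tried (silently truncated
#'   to what every fold can support).
#' @param n_groups Number of cancellation groups.
#' @param scale Preprocessing mode passed to [fit_pls()].
#' @return A list of class `qsrr_cv`: tibble `metrics` (`A`, `RMSECV`,
#'   `R2cv`), `A_best`, `groups` (assignment vector).
#' @export
venetian_blinds_cv <- function(X, y, A_max = 10L, n_groups = 5L,
                               scale = c("autoscale", "mean-center")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 2L * n_groups)
  groups <- ((seq_len(n) - 1L) %% n_groups) + 1L
  fold_rank <- vapply(seq_len(n_groups), function(g) {
    qr(base::scale(X[groups != g, , drop = FALSE], center = TRUE,
                   scale = FALSE))$rank
  }, integer(1))
  A_feasible <- min(fold_rank)
  if (A_max > A_feasible) {
    warning(sprintf("venetian_blinds_cv(): A_max truncated from %d to %d (fold rank)",
                    A_max, A_feasible))
    A_max <- A_feasible
  }
  pred <- matrix(NA_real_, n, A_max)
  for (g in seq_len(n_groups)) {
    inn <- groups != g
    for (A in seq_len(A_max)) {
      m <- fit_pls(X[inn, , drop = FALSE], y[inn], A, scale = scale)
      pred[!inn, A] <- predict(m, X[!inn, , drop = FALSE])
    }
  }
  tss <- sum((y - mean(y))^2)
  metrics <- tibble::tibble(
    A = seq_len(A_max),
    RMSECV = vapply(seq_len(A_max), function(A) rmse(y, pred[, A]), 0),
    R2cv = vapply(seq_len(A_max),
                  function(A) 1 - sum((y - pred[, A])^2) / tss, 0)
  )
  best_rmse <- min(metrics$RMSECV)
  A_best <- metrics$A[which(metrics$RMSECV <= best_rmse * 1.02)[1L]]
  structure(list(metrics = metrics, A_best = A_best, groups = groups,
                 scale_mode = scale),
            class = "qsrr_cv")
}

#' @export
print.qsrr_cv <- function(x, ...) {
  cat(sprintf("<qsrr_cv> venetian blinds, %d groups; chosen A = %d (RMSECV %.4f)\n",
              max(x$groups), x$A_best,
              x$metrics$RMSECV[x$metrics$A == x$A_best]))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' For variable `i` over a fitted `A`-component PLS model,
#' \deqn{VIP_i = \sqrt{ I \sum_a w_{ia}^2 SSY_a / \sum_a SSY_a }}
#' with `I` the variable count and `SSY_a = q_a^2 t_a't_a` the response
#' variance explained by component `a`. By construction the mean of the
#' squared VIPs is exactly 1 (their squares sum to `I`); the customary
#' retention rule keeps variables with VIP > 1.
#'
#' @param model A `qsrr_pls` model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "qsrr_pls"))
  ssy <- model$q^2 * colSums(model$T^2)
  if (sum(ssy) <= 0) {
    stop("vip_scores(): model explains no response variance", call. = FALSE)
  }
  wn <- sweep(model$W, 2L, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(nrow(model$W) * as.numeric(wn^2 %*% ssy) / sum(ssy))
  stats::setNames(v, model$var_names)
}

#' Covariance selection (CovSel)
#'
#' Greedy forward selection by covariance with the response: at each step
#' the (scaled) predictor with the largest squared covariance with the
#' current response is selected, and both the predictor matrix and the
#' response are orthogonalized (deflated) with respect to the selected
#' column before the next step. Stops early, with a warning, if every
#' remaining column has (numerically) zero variance after deflation.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param k Number of variables to select.
#' @param scale Initial preprocessing, `"autoscale"` or `"mean-center"`.
#' @param deflate_y Also orthogonalize the response against each selected
#'   column (the classical procedure); `FALSE` deflates `X` only.
#' @return A list of class `qsrr_covsel`: `selected` (column names, in
#'   selection order), `indices`, and the deflated `X_res`, `y_res`.
#' @export
covsel <- function(X, y, k, scale = c("autoscale", "mean-center"),
                   deflate_y = TRUE) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(k >= 1L, k <= ncol(X), nrow(X) == length(y))
  Xc <- fit_apply_scaling(X, mode = scale)$train
  yc <- as.numeric(base::scale(y, center = TRUE, scale = (scale == "autoscale")))
  sel <- integer()
  for (step in seq_len(k)) {
    norms2 <- colSums(Xc^2)
    live <- norms2 > 1e-12 * max(1, max(norms2))
    live[sel] <- FALSE
    if (!any(live)) {
      warning(sprintf("covsel(): all remaining columns deflated to zero after %d selections",
                      length(sel)))
      break
    }
    covs2 <- as.numeric(crossprod(Xc, yc))^2
    covs2[!live] <- -Inf
    j <- which.max(covs2)
    sel <- c(sel, j)
    v <- Xc[, j]
    v <- v / sqrt(sum(v^2))
    Xc <- Xc - outer(v, as.numeric(crossprod(Xc, v)))
    if (deflate_y) yc <- yc - v * sum(v * yc)
  }
  structure(list(selected = colnames(X)[sel], indices = sel,
                 X_res = Xc, y_res = yc, scale_mode = scale),
            class = "qsrr_covsel")
}

#' Kennard-Stone duplex train/test splitting
#'
#' Deterministic max-min-distance splitting into two representative sets:
#' the two mutually farthest points (Euclidean, on the scaled predictors) go
#' to the training set, the farthest pair among the remainder to the test
#' set, then the two sets alternately receive the remaining candidate whose
#' minimum distance to the set's current members is largest, until the test
#' set reaches its quota; everything left joins the training set.
#'
#' @param X Predictor matrix (scale beforehand if the columns have
#'   incommensurate units).
#' @param train_fraction Fraction of records assigned to training.
#' @return A list with integer vectors `train` and `test` (row indices).
#' @export
kennard_stone_duplex <- function(X, train_fraction = 0.80) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4L, train_fraction > 0, train_fraction < 1)
  n_test <- n - round(train_fraction * n)
  d <- as.matrix(stats::dist(X))
  if (all(d == 0)) {
    warning("kennard_stone_duplex(): all points coincide; falling back to index order")
    test <- seq.int(n - n_test + 1L, n)
    return(list(train = seq_len(n - n_test), test = test))
  }
  farthest_pair <- function(cand) {
    dd <- d[cand, cand, drop = FALSE]
    ij <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
    cand[sort(ij)]
  }
  remaining <- seq_len(n)
  train <- farthest_pair(remaining)
  remaining <- setdiff(remaining, train)
  test <- farthest_pair(remaining)
  remaining <- setdiff(remaining, test)
  turn <- "train"
  while (length(remaining)) {
    if (length(test) >= n_test) {
      train <- c(train, remaining)
      break
    }
    members <- if (turn == "train") train else test
    mind <- apply(d[remaining, members, drop = FALSE], 1L, min)
    pick <- remaining[which.max(mind)]
    if (turn == "train") train <- c(train, pick) else test <- c(test, pick)
    remaining <- setdiff(remaining, pick)
    turn <- if (turn == "train") "test" else "train"
  }
  list(train = sort(train), test = sort(test))
}
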