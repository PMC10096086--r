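#' ANN training configuration
#'
#' Parameters for full-batch backpropagation with momentum. Restart count
#' defaults to 100: the architecture is retrained from 100 random weight
#' initializations and the per-split metrics averaged, so a good result
#' cannot be an artifact of one lucky starting point.
#'
#' @param learning_rate Gradient-descent step size.
#' @param momentum Momentum coefficient on the previous update.
#' @param max_epochs Hard epoch cap.
#' @param patience Epochs of non-improving validation RMSE tolerated before
#'   stopping.
#' @param n_restarts Number of random initializations in
#'   [ensemble_train_ann()].
#' @param seed Master seed.
#' @return A list of class `qsrr_ann_config`.
#' @export
ann_config <- function(learning_rate = 0.01, momentum = 0.9,
                       max_epochs = 5000L, patience = 50L,
                       n_restarts = 100L, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1L, patience >= 1L, n_restarts >= 1L)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "qsrr_ann_config")
}

# Random weights in [-1, 1] for an I-H-1 network.
init_weights <- function(n_input, n_hidden) {
  list(
    W1 = matrix(stats::runif(n_input * n_hidden, -1, 1), n_input, n_hidden),
    b1 = stats::runif(n_hidden, -1, 1),
    w2 = stats::runif(n_hidden, -1, 1),
    b2 = stats::runif(1L, -1, 1)
  )
}

# Forward pass in scaled space. X: n x I matrix. Returns list(H, yhat).
ann_forward_scaled <- function(w, X) {
  H <- tanh(sweep(X %*% w$W1, 2L, w$b1, "+"))
  list(H = H, yhat = as.numeric(H %*% w$w2 + w$b2))
}

#' Training loss and analytic backpropagation gradients
#'
#' Mean-squared-error loss of a one-hidden-layer tanh network (identity
#' output) and its exact gradients with respect to every weight and bias.
#' Exposed so the analytic gradients can be verified against finite
#' differences.
#'
#' @param w Weight list with `W1` (inputs x hidden), `b1`, `w2`, `b2`.
#' @param X Scaled input matrix (records x inputs).
#' @param y Scaled target vector.
#' @return A list with `loss` and gradient list `grad` (same shapes as `w`).
#' @export
ann_gradients <- function(w, X, y) {
  n <- nrow(X)
  fw <- ann_forward_scaled(w, X)
  r <- fw$yhat - y
  loss <- mean(r^2)
  d_out <- 2 * r / n
  dH <- outer(d_out, w$w2)
  dZ1 <- dH * (1 - fw$H^2)
  list(loss = loss, grad = list(
    W1 = crossprod(X, dZ1),
    b1 = colSums(dZ1),
    w2 = as.numeric(crossprod(fw$H, d_out)),
    b2 = sum(d_out)
  ))
}

#' Train a backpropagation network with early stopping
#'
#' One hidden layer of `n_hidden` tanh units and a single identity output
#' neuron, trained by full-batch gradient descent with momentum on the
#' mean-squared error. Inputs are autoscaled and the response min-max scaled
#' to [-0.8, 0.8] (training statistics only; the margin keeps targets away
#' from tanh saturation). After every epoch the training and validation
#' RMSEs (response units) are recorded; training stops at `max_epochs` or
#' once the validation RMSE has not improved for `patience` epochs, and the
#' returned network carries the weights of the best-validation epoch.
#'
#' @param X_train,y_train Training predictors and response.
#' @param X_val,y_val Validation predictors and response (disjoint from
#'   training; drives early stopping).
#' @param n_hidden Hidden-layer size.
#' @param config An [ann_config()].
#' @param seed Seed for weight initialization (defaults to `config$seed`).
#' @return An object of class `qsrr_ann`: weight list `w`, scalers, `trace`
#'   tibble (`epoch`, `rmse_train`, `rmse_val`), `best_epoch`, layer sizes.
#' @export
train_ann <- function(X_train, y_train, X_val, y_val, n_hidden = 2L,
                      config = ann_config(), seed = config$seed) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  if (is.null(colnames(X_train))) {
    colnames(X_train) <- paste0("x", seq_len(ncol(X_train)))
  }
  stopifnot(nrow(X_train) == length(y_train), nrow(X_val) == length(y_val),
            ncol(X_val) == ncol(X_train))
  xs <- fit_apply_scaling(X_train, mode = "autoscale")
  y_min <- min(y_train); y_max <- max(y_train)
  if (y_max <= y_min) stop("train_ann(): constant training response", call. = FALSE)
  to_scaled <- function(y) -0.8 + 1.6 * (y - y_min) / (y_max - y_min)
  from_scaled <- function(ys) y_min + (ys + 0.8) * (y_max - y_min) / 1.6
  Xtr <- xs$train
  Xva <- scale_apply(xs, X_val)
  ytr <- to_scaled(y_train)

  local_rng(seed)
  w <- init_weights(ncol(Xtr), n_hidden)
  vel <- lapply(w, function(z) z * 0)
  best <- list(w = w, rmse_val = Inf, epoch = 0L)
  tr_tr <- tr_va <- numeric(config$max_epochs)
  stall <- 0L
  n_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    g <- ann_gradients(w, Xtr, ytr)
    if (!is.finite(g$loss)) {
      stop("train_ann(): training diverged (non-finite loss); reduce the learning rate",
           call. = FALSE)
    }
    for (nm in names(w)) {
      vel[[nm]] <- config$momentum * vel[[nm]] - config$learning_rate * g$grad[[nm]]
      w[[nm]] <- w[[nm]] + vel[[nm]]
    }
    pred_tr <- from_scaled(ann_forward_scaled(w, Xtr)$yhat)
    pred_va <- from_scaled(ann_forward_scaled(w, Xva)$yhat)
    tr_tr[epoch] <- rmse(y_train, pred_tr)
    tr_va[epoch] <- rmse(y_val, pred_va)
    n_epochs <- epoch
    if (tr_va[epoch] < best$rmse_val - 1e-12) {
      best <- list(w = w, rmse_val = tr_va[epoch], epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(
    w = best$w, n_input = ncol(Xtr), n_hidden = n_hidden,
    x_scaling = ys_strip(xs), y_min = y_min, y_max = y_max,
    var_names = colnames(X_train),
    trace = tibble::tibble(epoch = seq_len(n_epochs),
                           rmse_train = tr_tr[seq_len(n_epochs)],
                           rmse_val = tr_va[seq_len(n_epochs)]),
    best_epoch = best$epoch, config = config, seed = seed
  ), class = "qsrr_ann")
}

#' Predict retention times from a trained network
#'
#' @param object A `qsrr_ann` network.
#' @param newdata Matrix or data frame with the model's input columns.
#' @param ... Unused.
#' @return Numeric predictions in response units (min).
#' @export
predict.qsrr_ann <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (all(object$var_names %in% names(newdata))) {
    newdata <- newdata[, object$var_names, drop = FALSE]
  }
  Xn <- scale_apply(object$x_scaling, as.matrix(newdata))
  ys <- ann_forward_scaled(object$w, Xn)$yhat
  object$y_min + (ys + 0.8) * (object$y_max - object$y_min) / 1.6
}

#' @export
print.qsrr_ann <- function(x, ...) {
  cat(sprintf("<qsrr_ann> %d-%d-1 network (tanh/identity), best epoch %d, validation RMSE %.4f\n",
              x$n_input, x$n_hidden, x$best_epoch,
              min(x$trace$rmse_val)))
  invisible(x)
}

#' Multi-restart network training with averaged metrics
#'
#' Trains the same architecture from `n_restarts` independent random weight
#' initializations (seeds derived deterministically from the master seed),
#' averages the per-split RMSE and R2 across restarts, and keeps the single
#' network with the lowest validation RMSE for prediction. Restarts that
#' fail (e.g. divergence) are dropped and counted.
#'
#' @param X_train,y_train,X_val,y_val Training and validation data.
#' @param X_test,y_test Optional external test data included in the summary.
#' @param n_hidden Hidden-layer size.
#' @param config An [ann_config()] (`n_restarts`, `seed` are honoured).
#' @return A list of class `qsrr_ann_ensemble`: `summary` tibble (per-split
#'   mean/sd of RMSE and R2 across restarts), `per_restart` tibble, `best`
#'   (the retained `qsrr_ann`), `n_failed`.
#' @export
ensemble_train_ann <- function(X_train, y_train, X_val, y_val,
                               X_test = NULL, y_test = NULL,
                               n_hidden = 2L, config = ann_config()) {
  rows <- list()
  members <- list()
  best <- NULL
  n_failed <- 0L
  for (r in seq_len(config$n_restarts)) {
    seed_r <- derive_seed(config$seed, paste0("restart", r))
    fit <- tryCatch(
      train_ann(X_train, y_train, X_val, y_val, n_hidden = n_hidden,
                config = config, seed = seed_r),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      warning(sprintf("restart %d failed: %s", r, conditionMessage(fit)))
      next
    }
    row <- tibble::tibble(
      restart = r,
      rmse_train = rmse(y_train, predict(fit, X_train)),
      rmse_val = rmse(y_val, predict(fit, X_val)),
      r2_train = r_squared(y_train, predict(fit, X_train)),
      r2_val = r_squared(y_val, predict(fit, X_val)),
      rmse_test = if (!is.null(X_test)) rmse(y_test, predict(fit, X_test)) else NA_real_,
      r2_test = if (!is.null(X_test)) r_squared(y_test, predict(fit, X_test)) else NA_real_
    )
    rows[[length(rows) + 1L]] <- row
    members[[length(members) + 1L]] <- fit
    if (is.null(best) || min(fit$trace$rmse_val) < min(best$trace$rmse_val)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("ensemble_train_ann(): every restart failed", call. = FALSE)
  per_restart <- dplyr::bind_rows(rows)
  summarise_split <- function(col) {
    v <- per_restart[[col]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v))
  }
  long <- tidyr::pivot_longer(per_restart, -"restart",
                              names_to = "metric", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(summary = summary, per_restart = per_restart,
                 best = best, members = members, n_failed = n_failed,
                 config = config),
            class = "qsrr_ann_ensemble")
}

#' Predict from a restart ensemble
#'
#' `type = "best"` uses the single best-validation network; `type =
#' "average"` averages the predictions of every restart, which damps the
#' occasional initialization whose good validation score does not
#' extrapolate to unseen analytes.
#'
#' @param object A `qsrr_ann_ensemble`.
#' @param newdata Matrix or data frame with the input columns.
#' @param type `"best"` or `"average"`.
#' @param ... Unused.
#' @return Numeric predictions (min).
#' @export
predict.qsrr_ann_ensemble <- function(object, newdata,
                                      type = c("best", "average"), ...) {
  type <- match.arg(type)
  if (type == "best") return(predict(object$best, newdata))
  preds <- vapply(object$members, function(m) predict(m, newdata),
                  numeric(nrow(as.data.frame(newdata))))
  rowMeans(as.matrix(preds))
}

#' @export
print.qsrr_ann_ensemble <- function(x, ...) {
  ok <- nrow(x$per_restart)
  cat(sprintf("<qsrr_ann_ensemble> %d restarts (%d failed); mean validation RMSE %.4f\n",
              ok + x$n_failed, x$n_failed, mean(x$per_restart$rmse_val)))
  invisible(x)
}
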