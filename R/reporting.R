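#' Root-mean-square error
#'
#' `sqrt(mean((y - yhat)^2))`: individual errors are squared, summed,
#' divided by their number, and the square root taken.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L) stop("rmse(): empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("rmse(): length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` against the mean of the observed values.
#'
#' @param y Observed values (`n >= 2`, non-constant).
#' @param yhat Predicted values.
#' @return R-squared (can be negative for models worse than the mean).
#' @export
r_squared <- function(y, yhat) {
  if (length(y) < 2L) stop("r_squared(): need at least 2 observations", call. = FALSE)
  if (length(y) != length(yhat)) stop("r_squared(): length mismatch", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("r_squared(): constant observed values", call. = FALSE)
  1 - sum((y - yhat)^2) / tss
}

#' Bundle a fitted model's performance into a report
#'
#' @param model_name Short model label (e.g. `"PLS + CovSel"`, `"ANN"`).
#' @param preprocessing Preprocessing label (e.g. `"Autoscaling"`).
#' @param predictions Tibble with columns `split`, `tr` (observed), `pred`,
#'   and optionally `analyte`; RMSEP is computed on the `"test"` rows.
#' @param rmsecv,r2cv Cross-validation metrics on the training records (from
#'   [venetian_blinds_cv()], or `NA` where CV does not apply).
#' @return A list of class `qsrr_report`.
#' @export
model_report <- function(model_name, preprocessing, predictions,
                         rmsecv = NA_real_, r2cv = NA_real_) {
  stopifnot(all(c("split", "tr", "pred") %in% names(predictions)))
  test <- predictions[predictions$split == "test", ]
  rmsep <- if (nrow(test)) rmse(test$tr, test$pred) else NA_real_
  structure(list(model = model_name, preprocessing = preprocessing,
                 RMSECV = rmsecv, R2cv = r2cv, RMSEP = rmsep,
                 predictions = tibble::as_tibble(predictions)),
            class = "qsrr_report")
}

#' @export
print.qsrr_report <- function(x, ...) {
  cat(sprintf("<qsrr_report> %s (%s): RMSECV %.3f, R2cv %.3f, RMSEP %.3f\n",
              x$model, x$preprocessing, x$RMSECV, x$R2cv, x$RMSEP))
  invisible(x)
}

#' Model comparison table
#'
#' One row per report with its preprocessing and metrics, sorted by
#' ascending RMSEP (missing RMSEP last).
#'
#' @param reports A list of [model_report()] objects.
#' @return A tibble with columns `model`, `preprocessing`, `RMSECV`, `R2cv`,
#'   `RMSEP`.
#' @export
comparison_table <- function(reports) {
  stopifnot(length(reports) > 0)
  tab <- dplyr::bind_rows(lapply(reports, function(r) {
    tibble::tibble(model = r$model, preprocessing = r$preprocessing,
                   RMSECV = r$RMSECV, R2cv = r$R2cv, RMSEP = r$RMSEP)
  }))
  dplyr::arrange(tab, .data$RMSEP)
}

#' Write / read a comparison table as CSV at reporting precision
#'
#' Metrics are written with 3 decimals (the precision such tables are
#' customarily reported at), so a written table re-reads bit-exactly.
#'
#' @param tab Comparison table from [comparison_table()].
#' @param path CSV path.
#' @return `path` (write) or the re-read tibble (read).
#' @export
write_comparison_csv <- function(tab, path) {
  out <- tab
  for (cc in c("RMSECV", "R2cv", "RMSEP")) out[[cc]] <- round(out[[cc]], 3L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Residual diagnostics on held-out predictions
#'
#' Summarizes the residuals of a report: overall mean residual, correlation
#' between residuals and fitted values, and per-analyte mean residual
#' (bias). When a `covariate` is supplied (e.g. the interaction term a
#' linear model omits), its correlation with the residuals is scored by a
#' seeded permutation test — a small p-value means the residuals still carry
#' structure the model failed to describe.
#'
#' @param report A [model_report()].
#' @param split Which split's residuals to summarize.
#' @param covariate Optional numeric vector aligned with the report's rows
#'   of that split.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @return A list of class `qsrr_residuals`: `mean_residual`,
#'   `cor_fitted`, `per_analyte` (tibble or NULL), and when `covariate`
#'   given, `cor_covariate` and `p_covariate`.
#' @export
residual_diagnostics <- function(report, split = "test", covariate = NULL,
                                 n_perm = 999L, seed = 1L) {
  stopifnot(inherits(report, "qsrr_report"))
  pr <- report$predictions[report$predictions$split %in% split, ]
  if (!nrow(pr)) stop("residual_diagnostics(): no predictions for split ",
                      paste(split, collapse = ","), call. = FALSE)
  res <- pr$tr - pr$pred
  out <- list(
    mean_residual = mean(res),
    cor_fitted = if (stats::sd(pr$pred) > 0 && stats::sd(res) > 0) {
      stats::cor(res, pr$pred)
    } else 0,
    per_analyte = if ("analyte" %in% names(pr)) {
      pr |>
        dplyr::mutate(residual = res) |>
        dplyr::group_by(.data$analyte) |>
        dplyr::summarise(bias = mean(.data$residual), .groups = "drop")
    } else NULL
  )
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == nrow(pr))
    if (stats::sd(res) == 0 || stats::sd(covariate) == 0) {
      out$cor_covariate <- 0
      out$p_covariate <- 1
    } else {
      obs <- abs(stats::cor(res, covariate))
      local_rng(seed)
      perm <- replicate(n_perm, abs(stats::cor(sample(res), covariate)))
      out$cor_covariate <- stats::cor(res, covariate)
      out$p_covariate <- (1 + sum(perm >= obs)) / (n_perm + 1)
    }
  }
  structure(out, class = "qsrr_residuals")
}

#' @export
print.qsrr_residuals <- function(x, ...) {
  cat(sprintf("<qsrr_residuals> mean %.4g, cor(residual, fitted) %.3f",
              x$mean_residual, x$cor_fitted))
  if (!is.null(x$p_covariate)) {
    cat(sprintf(", cor(residual, covariate) %.3f (perm p = %.3g)",
                x$cor_covariate, x$p_covariate))
  }
  cat("\n")
  invisible(x)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a fitted PLS model
#'
#' One row per predictor: regression coefficient in scaled space and VIP
#' score.
#'
#' @param x A `qsrr_pls` model.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `vip`.
#' @export
tidy.qsrr_pls <- function(x, ...) {
  tibble::tibble(term = x$var_names,
                 estimate = as.numeric(x$B),
                 vip = unname(vip_scores(x)))
}

#' @rdname tidy.qsrr_pls
#' @export
glance.qsrr_pls <- function(x, ...) {
  tibble::tibble(A = x$A, n = length(x$y), p = length(x$var_names),
                 rmse_train = rmse(x$y, x$fitted),
                 r2_train = r_squared(x$y, x$fitted))
}

#' Tidy a GA selection result
#'
#' One row per (subset, descriptor) pair of the ranked search output.
#'
#' @param x A `qsrr_ga` result.
#' @param ... Unused.
#' @return A tibble with `rank`, `fitness`, `descriptor`.
#' @export
tidy.qsrr_ga <- function(x, ...) {
  tibble::tibble(
    rank = rep(x$rank, x$n_desc),
    fitness = rep(x$fitness, x$n_desc),
    descriptor = unlist(x$descriptors)
  )
}

#' @rdname tidy.qsrr_ga
#' @export
glance.qsrr_ga <- function(x, ...) {
  tibble::tibble(best_fitness = x$fitness[1L],
                 best_n_desc = x$n_desc[1L],
                 n_evaluated = attr(x, "n_evaluated"))
}

#' Tidy a trained network
#'
#' One row per weight or bias, identified by layer and indices.
#'
#' @param x A `qsrr_ann` network.
#' @param ... Unused.
#' @return A tibble with `layer`, `from`, `to`, `value`.
#' @export
tidy.qsrr_ann <- function(x, ...) {
  w <- x$w
  dplyr::bind_rows(
    tidyr::expand_grid(from = seq_len(nrow(w$W1)), to = seq_len(ncol(w$W1))) |>
      dplyr::mutate(layer = "hidden", value = as.numeric(w$W1)[
        (to - 1L) * nrow(w$W1) + from]),
    tibble::tibble(layer = "hidden_bias", from = NA_integer_,
                   to = seq_along(w$b1), value = w$b1),
    tibble::tibble(layer = "output", from = seq_along(w$w2), to = 1L,
                   value = w$w2),
    tibble::tibble(layer = "output_bias", from = NA_integer_, to = 1L,
                   value = w$b2)
  ) |>
    dplyr::relocate("layer")
}

#' @rdname tidy.qsrr_ann
#' @export
glance.qsrr_ann <- function(x, ...) {
  tibble::tibble(n_input = x$n_input, n_hidden = x$n_hidden,
                 epochs = nrow(x$trace), best_epoch = x$best_epoch,
                 rmse_val_best = min(x$trace$rmse_val))
}

#' @export
tidy.qsrr_cv <- function(x, ...) x$metrics

# ---- plots ------------------------------------------------------------------

#' Plot cross-validation error against model complexity
#'
#' @param object A `qsrr_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qsrr_cv <- function(object, ...) {
  ggplot2::ggplot(object$metrics, ggplot2::aes(x = .data$A, y = .data$RMSECV)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$A_best, linetype = "dashed") +
    ggplot2::labs(x = "latent variables", y = "RMSECV (min)",
                  title = "Venetian-blinds cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot the training trace of a network
#'
#' @param object A `qsrr_ann` network.
#' @param ... Unused.
#' @return A ggplot object showing training and validation RMSE per epoch
#'   with the early-stopping epoch marked.
#' @export
autoplot.qsrr_ann <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"epoch",
                              names_to = "set", values_to = "rmse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(y = "RMSE (min)", title = "Backpropagation training trace") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed plot for a model report
#'
#' @param object A `qsrr_report`.
#' @param ... Unused.
#' @return A ggplot object, one panel per split, with the unit line.
#' @export
autoplot.qsrr_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$tr, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(x = "observed tr (min)", y = "predicted tr (min)",
                  title = paste(object$model, "-", object$preprocessing)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
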