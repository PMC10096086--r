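test_that("RMSE follows its closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2)          # constant offset
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt(25 / 2))
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("the forward pass reproduces pencil-and-paper arithmetic", {
  w <- list(W1 = matrix(c(1, -1, 0.5, 0.25), 2, 2), b1 = c(0.1, -0.2),
            w2 = c(2, -3), b2 = 0.5)
  x <- matrix(c(1, 0), 1, 2)
  h1 <- tanh(1 * 1 + 0 * (-1) + 0.1)
  h2 <- tanh(1 * 0.5 + 0 * 0.25 - 0.2)
  expect_equal(qsrr:::ann_forward_scaled(w, x)$yhat, 2 * h1 - 3 * h2 + 0.5,
               tolerance = 1e-12)
  # hidden activations stay inside (-1, 1) for any finite input
  big <- matrix(c(1e6, -1e6), 1, 2)
  H <- qsrr:::ann_forward_scaled(w, big)$H
  expect_true(all(abs(H) <= 1))

  # all-zero weights: prediction is the (back-transformed) output bias
  set.seed(20)
  X <- matrix(rnorm(20 * 2), 20, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20, 5)
  fit <- train_ann(X, y, X, y, n_hidden = 2,
                   config = ann_config(max_epochs = 1, patience = 1), seed = 1)
  fit$w <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0), w2 = c(0, 0), b2 = 0.3)
  expected <- fit$y_min + (0.3 + 0.8) * (fit$y_max - fit$y_min) / 1.6
  expect_equal(unique(round(predict(fit, X), 12)), round(expected, 12))
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    n_in <- sample(2:5, 1); n_h <- sample(1:3, 1)
    X <- matrix(rnorm(12 * n_in), 12)
    y <- rnorm(12)
    w <- qsrr:::init_weights(n_in, n_h)
    g <- ann_gradients(w, X, y)
    eps <- 1e-6
    for (nm in names(w)) {
      for (k in seq_along(w[[nm]])) {
        wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
        wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
        fd <- (ann_gradients(wp, X, y)$loss - ann_gradients(wm, X, y)$loss) /
          (2 * eps)
        expect_equal(g$grad[[nm]][k], fd, tolerance = 1e-6,
                     info = paste(nm, k, "seed", seed))
      }
    }
  }
})

test_that("training fits linear and curved targets within budget", {
  set.seed(21)
  x <- matrix(seq(-1, 1, length.out = 150), ncol = 1)
  y_lin <- as.numeric(2 * x)
  iv <- seq(3, 150, by = 5)
  fit <- train_ann(x[-iv, , drop = FALSE], y_lin[-iv],
                   x[iv, , drop = FALSE], y_lin[iv], n_hidden = 2,
                   config = ann_config(learning_rate = 0.05), seed = 5)
  expect_lt(min(fit$trace$rmse_train), 0.02)

  y_sq <- as.numeric(x^2)
  fit2 <- train_ann(x[-iv, , drop = FALSE], y_sq[-iv],
                    x[iv, , drop = FALSE], y_sq[iv], n_hidden = 2, seed = 5)
  expect_lt(min(fit2$trace$rmse_val), 0.05)
})

test_that("early stopping returns the best-validation epoch", {
  set.seed(22)
  X <- matrix(rnorm(60 * 3), 60)
  y <- as.numeric(X %*% c(1, -1, 0.5)) + rnorm(60, sd = 0.3)
  Xv <- matrix(rnorm(30 * 3), 30)
  yv <- as.numeric(Xv %*% c(1, -1, 0.5)) + rnorm(30, sd = 0.3)
  fit <- train_ann(X, y, Xv, yv, n_hidden = 2,
                   config = ann_config(max_epochs = 800, patience = 30), seed = 7)
  expect_equal(fit$best_epoch, which.min(fit$trace$rmse_val))
  expect_equal(min(fit$trace$rmse_val), fit$trace$rmse_val[fit$best_epoch])

  # with validation == training, the noiseless curved target never stops early
  xx <- matrix(seq(-1, 1, length.out = 100), ncol = 1)
  yy <- as.numeric(xx^2)
  cfg <- ann_config(max_epochs = 400, patience = 50)
  fit2 <- train_ann(xx, yy, xx, yy, n_hidden = 2, config = cfg, seed = 3)
  expect_equal(nrow(fit2$trace), 400L)
})

test_that("full-batch training is invariant to record order", {
  set.seed(23)
  X <- matrix(rnorm(40 * 3), 40)
  y <- as.numeric(X %*% c(1, 0.5, -1)) + rnorm(40, sd = 0.2)
  Xv <- matrix(rnorm(20 * 3), 20)
  yv <- as.numeric(Xv %*% c(1, 0.5, -1))
  cfg <- ann_config(max_epochs = 60, patience = 60)
  a <- train_ann(X, y, Xv, yv, config = cfg, seed = 11)
  perm <- sample(40)
  b <- train_ann(X[perm, ], y[perm], Xv, yv, config = cfg, seed = 11)
  expect_equal(a$w$W1, b$w$W1, tolerance = 1e-8)
  expect_equal(predict(a, Xv), predict(b, Xv), tolerance = 1e-8)
})

test_that("restart ensembles are reproducible and degenerate to a single run", {
  set.seed(24)
  X <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("a", "b")))
  y <- as.numeric(X %*% c(1, -2)) + rnorm(60, sd = 0.1)
  Xv <- matrix(rnorm(25 * 2), 25, dimnames = list(NULL, c("a", "b")))
  yv <- as.numeric(Xv %*% c(1, -2)) + rnorm(25, sd = 0.1)
  cfg1 <- ann_config(max_epochs = 150, n_restarts = 1L, seed = 9)
  e1 <- ensemble_train_ann(X, y, Xv, yv, config = cfg1)
  single <- train_ann(X, y, Xv, yv, config = cfg1,
                      seed = qsrr:::derive_seed(9, "restart1"))
  expect_equal(e1$per_restart$rmse_val, rmse(yv, predict(single, Xv)))

  cfg5 <- ann_config(max_epochs = 150, n_restarts = 5L, seed = 9)
  e5a <- ensemble_train_ann(X, y, Xv, yv, config = cfg5)
  e5b <- ensemble_train_ann(X, y, Xv, yv, config = cfg5)
  expect_identical(e5a$summary, e5b$summary)
  expect_equal(nrow(e5a$per_restart), 5L)
  expect_equal(min(e5a$per_restart$rmse_val), min(e5a$best$trace$rmse_val))
})

test_that("network weights and scalers survive a JSON round-trip", {
  set.seed(25)
  X <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("u", "v", "w")))
  y <- as.numeric(X %*% c(2, -1, 1)) + rnorm(50, sd = 0.2)
  fit <- train_ann(X, y, X, y, config = ann_config(max_epochs = 100), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
})
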