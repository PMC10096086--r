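test_that("PLS1 reduces to simple regression in 1D and to OLS at full rank", {
  set.seed(11)
  x <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "x"))
  y <- as.numeric(2.5 * x + 1 + rnorm(40, sd = 0.3))
  m1 <- fit_pls(x, y, 1, scale = "mean-center")
  slope <- cov(x[, 1], y) / var(x[, 1])
  expect_equal(as.numeric(m1$B), slope, tolerance = 1e-10)

  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("x", 1:5)))
  yy <- as.numeric(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(60)
  mfull <- fit_pls(X, yy, 5, scale = "mean-center")
  ols <- solve(crossprod(scale(X, scale = FALSE)),
               crossprod(scale(X, scale = FALSE), yy - mean(yy)))
  expect_equal(as.numeric(mfull$B), as.numeric(ols), tolerance = 1e-8)

  clean <- as.numeric(X %*% c(1, 2, 3, 4, 5))
  mnl <- fit_pls(X, clean, 5)
  expect_lt(rmse(clean, mnl$fitted), 1e-10)

  expect_error(fit_pls(X, yy, 6), "rank")
})

test_that("NIPALS scores are orthogonal and X-residual norm shrinks", {
  set.seed(12)
  X <- matrix(rnorm(50 * 8), 50)
  y <- as.numeric(X %*% rnorm(8)) + rnorm(50, sd = 0.5)
  norms <- vapply(1:6, function(A) {
    m <- fit_pls(X, y, A)
    G <- crossprod(m$T)
    offdiag <- G
    diag(offdiag) <- 0
    expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
    norm(m$D, "F")
  }, 0)
  expect_true(all(diff(norms) < 1e-12))
})

test_that("PLS predictions agree with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  X <- matrix(rnorm(45 * 6), 45, dimnames = list(NULL, paste0("v", 1:6)))
  y <- as.numeric(X %*% c(2, 0, 1, -1, 0.5, 0)) + rnorm(45, sd = 0.4)
  Xnew <- matrix(rnorm(10 * 6), 10, dimnames = list(NULL, paste0("v", 1:6)))
  m <- fit_pls(X, y, 3, scale = "autoscale")
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                       scale = TRUE)
  ref_pred <- as.numeric(predict(ref, Xnew)$predict[, 1, 3])
  expect_equal(predict(m, Xnew), ref_pred, tolerance = 1e-6)
})

test_that("venetian blinds assigns interleaved groups and finds exact models", {
  set.seed(14)
  X <- matrix(rnorm(10 * 2), 10)
  y <- as.numeric(X %*% c(1, 2))
  cv <- venetian_blinds_cv(X, y, A_max = 2, scale = "mean-center")
  expect_equal(cv$groups, rep(1:5, 2))
  expect_lt(min(cv$metrics$RMSECV), 1e-8)
  expect_gt(max(cv$metrics$R2cv), 1 - 1e-12)

  Xl <- matrix(rnorm(100 * 6), 100)
  yl <- as.numeric(Xl %*% c(3, -2, 1, 0, 0, 0)) + rnorm(100, sd = 0.2)
  cvl <- venetian_blinds_cv(Xl, yl, A_max = 6)
  best <- min(cvl$metrics$RMSECV)
  expect_equal(cvl$A_best,
               cvl$metrics$A[which(cvl$metrics$RMSECV <= 1.02 * best)[1]])
})

test_that("a permuted response yields no cross-validated explanatory power", {
  r2s <- vapply(1:10, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(200 * 10), 200)
    y <- sample(as.numeric(X %*% rnorm(10)) + rnorm(200, sd = 0.3))
    max(venetian_blinds_cv(X, y, A_max = 5)$metrics$R2cv)
  }, 0)
  expect_true(all(r2s <= 0.1))
})

test_that("VIP scores satisfy their algebraic identity and find the signal", {
  set.seed(15)
  X <- matrix(rnorm(80 * 7), 80)
  y <- as.numeric(X %*% rnorm(7)) + rnorm(80, sd = 0.3)
  m <- fit_pls(X, y, 4)
  v <- vip_scores(m)
  expect_equal(sum(v^2), 7, tolerance = 1e-10)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)

  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    Xs <- matrix(rnorm(500 * 10), 500)
    ys <- Xs[, 1] + rnorm(500, sd = 0.01)
    vs <- vip_scores(fit_pls(Xs, ys, 1))
    which.max(vs) == 1L && vs[1] > 1
  }, TRUE)
  expect_true(all(hits))

  m1 <- fit_pls(matrix(rnorm(30), 30, 1), rnorm(30), 1)
  expect_equal(unname(vip_scores(m1)), 1)
})

test_that("CovSel picks the response-matching column first and skips duplicates", {
  set.seed(16)
  y <- rnorm(40)
  X <- cbind(target = y, matrix(rnorm(40 * 4), 40,
                                dimnames = list(NULL, paste0("n", 1:4))))
  cs <- covsel(X, y, 2)
  expect_equal(cs$selected[1], "target")

  Xd <- cbind(X, target_copy = y)
  cs2 <- covsel(Xd, y, 5)
  expect_false("target_copy" %in% cs2$selected[1:4])
})

test_that("CovSel equals brute-force greedy residualization on small problems", {
  for (seed in 1:50) {
    set.seed(seed)
    p <- sample(3:8, 1)
    n <- 30
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- as.numeric(X %*% rnorm(p)) + rnorm(n, sd = 0.5)
    k <- sample(2:min(4, p), 1)
    expect_equal(covsel(X, y, k)$indices, oracle_covsel(X, y, k),
                 info = paste("seed", seed))
  }
})

test_that("Kennard-Stone duplex starts from the farthest pair and is deterministic", {
  set.seed(17)
  X <- matrix(rnorm(30 * 3), 30)
  ks <- kennard_stone_duplex(X, 0.8)
  d <- as.matrix(dist(X))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_true(all(sort(far) %in% ks$train))
  expect_equal(length(ks$train), 24L)
  expect_equal(length(ks$test), 6L)
  expect_length(intersect(ks$train, ks$test), 0)

  ks2 <- kennard_stone_duplex(X, 0.8)
  expect_identical(ks, ks2)

  expect_warning(kennard_stone_duplex(matrix(1, 6, 2), 0.5), "coincide")
})

test_that("duplex test sets are more spread out than any random split", {
  # representativity: the max-min construction spaces the held-out points
  # over the predictor cloud instead of letting them cluster
  for (rep in 1:5) {
    set.seed(rep * 7)
    X <- matrix(rnorm(100 * 4), 100)
    d <- as.matrix(dist(X))
    diag(d) <- Inf
    spread <- function(s) min(d[s, s])
    ks <- kennard_stone_duplex(X, 0.8)
    rand_spread <- vapply(1:200, function(s) {
      set.seed(s + 999)
      spread(sample(100, 20))
    }, 0)
    expect_gt(spread(ks$test), max(rand_spread))
  }
})

test_that("PLS models round-trip through JSON with their predictions", {
  set.seed(19)
  X <- matrix(rnorm(40 * 4), 40, dimnames = list(NULL, paste0("x", 1:4)))
  y <- as.numeric(X %*% c(1, 2, 0, -1)) + rnorm(40, sd = 0.2)
  m <- fit_pls(X, y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  Xnew <- matrix(rnorm(5 * 4), 5, dimnames = list(NULL, paste0("x", 1:4)))
  expect_equal(predict(back, Xnew), predict(m, Xnew), tolerance = 1e-12)
})
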