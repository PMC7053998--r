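test_that("lagged designs have the documented shift structure", {
  x <- matrix(rnorm(60), 30, 2)
  X0 <- build_lagged_design(x, c(0, 1000 / 64), fs = 64)
  expect_equal(attr(X0, "lags"), 0:1)
  expect_equal(ncol(X0), 4)

  imp <- matrix(0, 30, 1); imp[10, 1] <- 1
  Xi <- build_lagged_design(imp, c(0, 5000 / 64), fs = 64)
  expect_equal(ncol(Xi), 6)
  for (l in 0:5) expect_equal(which(Xi[, l + 1] != 0), 10L + l)

  X1 <- build_lagged_design(x, c(0, 1), fs = 64)  # single lag 0
  expect_equal(X1[, 1], x[, 1])
  expect_error(build_lagged_design(x, c(0, 10000), fs = 64), "longer")
  # negative lags are acausal shifts
  Xn <- build_lagged_design(imp, c(-2000 / 64, 0), fs = 64)
  expect_equal(which(Xn[, 1] != 0), 8L)
})

test_that("ridge solution matches a brute-force normal-equations oracle", {
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(12:20, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    y <- matrix(rnorm(n * 2), n, 2)
    lambda <- 10^runif(1, -2, 2)
    fit <- trf(x, y, fs = 10, lag_window_ms = c(0, 100), lambda = lambda)
    # oracle: explicit centred, z-scored design and dense solve
    X <- build_lagged_design(x, c(0, 100), fs = 10)
    Xs <- scale(X)
    ys <- scale(y, scale = FALSE)
    w_s <- solve(crossprod(Xs) + lambda * diag(ncol(Xs)), crossprod(Xs, ys))
    w_raw <- w_s / attr(Xs, "scaled:scale")
    expect_lt(max(abs(fit$w_flat - w_raw)), 1e-10)
    b <- colMeans(y) - drop(crossprod(w_raw, colMeans(X)))
    expect_lt(max(abs(fit$bias - b)), 1e-10)
  }
})

test_that("ridge identities: exact recovery, zero response, shrinkage", {
  set.seed(1)
  x <- matrix(rnorm(2000), 1000, 2)
  k1 <- c(1, 2, 0.5, 0); k2 <- c(0, -1, 0.3, 0.1)
  X <- build_lagged_design(x, c(0, 3), fs = 1000)
  y <- X[, 1:4] %*% k1 + X[, 5:8] %*% k2
  fit <- trf(x, y, fs = 1000, lag_window_ms = c(0, 3), lambda = 1e-8)
  expect_lt(max(abs(coef(fit)[, 1, 1] - k1)), 1e-6)
  expect_lt(max(abs(coef(fit)[, 2, 1] - k2)), 1e-6)
  expect_gt(cor(predict(fit, x)[, 1], y), 1 - 1e-9)

  z <- trf(x, matrix(0, 1000, 1), fs = 1000, lag_window_ms = c(0, 3),
           lambda = 1)
  expect_true(all(z$w_flat == 0))

  norms <- vapply(10^(0:6), function(l) {
    sum(trf(x, y, fs = 1000, lag_window_ms = c(0, 3), lambda = l)$w_flat^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("prediction correlation is invariant to affine response rescaling", {
  set.seed(3)
  xs <- lapply(1:4, function(i) matrix(rnorm(600), 300, 2))
  kern <- array(rnorm(2 * 4 * 2), dim = c(4, 2, 2))
  ys <- lapply(seq_along(xs), function(i)
    simulate_neural(xs[[i]], kern, snr = 2, seed = i, fs = 50)$data)
  cv1 <- trf_crossval(xs, ys, fs = 50, lag_window_ms = c(0, 80),
                      lambda = c(1, 100))
  ys2 <- lapply(ys, function(y) 3.7 * y + 11)
  cv2 <- trf_crossval(xs, ys2, fs = 50, lag_window_ms = c(0, 80),
                      lambda = c(1, 100))
  expect_equal(cv1$r, cv2$r, tolerance = 1e-9)
})

test_that("leave-one-out scores are independent of trial ordering", {
  set.seed(4)
  xs <- lapply(1:4, function(i) matrix(rnorm(400), 200, 2))
  kern <- array(rnorm(2 * 3 * 1), dim = c(3, 2, 1))
  ys <- lapply(seq_along(xs), function(i)
    simulate_neural(xs[[i]], kern, snr = 1, seed = i, fs = 50)$data)
  cv <- trf_crossval(xs, ys, fs = 50, lag_window_ms = c(0, 60), lambda = 1)
  perm <- c(3, 1, 4, 2)
  cvp <- trf_crossval(xs[perm], ys[perm], fs = 50, lag_window_ms = c(0, 60),
                      lambda = 1)
  expect_equal(cvp$r[order(perm), , drop = FALSE], cv$r, tolerance = 1e-9)
  # duplicated trials score identically
  cvd <- trf_crossval(xs[c(1, 1, 2, 3)], ys[c(1, 1, 2, 3)], fs = 50,
                      lag_window_ms = c(0, 60), lambda = 1)
  expect_equal(cvd$r[1, ], cvd$r[2, ], tolerance = 1e-9)
})

test_that("cross-validated r equals the directly computed Pearson r", {
  set.seed(5)
  xs <- lapply(1:3, function(i) matrix(rnorm(300), 150, 2))
  kern <- array(rnorm(2 * 3), dim = c(3, 2, 1))
  ys <- lapply(seq_along(xs), function(i)
    simulate_neural(xs[[i]], kern, snr = 1, seed = i, fs = 50)$data)
  cv <- trf_crossval(xs, ys, fs = 50, lag_window_ms = c(0, 60), lambda = 2)
  for (o in 1:3) {
    fit <- trf(xs[-o], ys[-o], fs = 50, lag_window_ms = c(0, 60), lambda = 2)
    r_direct <- cor(predict(fit, xs[[o]])[, 1], ys[[o]][, 1])
    expect_equal(cv$r[o, 1], r_direct, tolerance = 1e-9)
  }
})

test_that("degenerate all-zero feature columns get zero weights", {
  set.seed(6)
  x <- cbind(rnorm(200), 0)
  y <- matrix(rnorm(200), 200, 1)
  fit <- trf(x, y, fs = 50, lag_window_ms = c(0, 60), lambda = 1)
  expect_true(all(coef(fit)[, 2, 1] == 0))
})

test_that("banded penalties can exclude a feature family entirely", {
  set.seed(8)
  x <- matrix(rnorm(400), 200, 2)
  colnames(x) <- c("Env", "S_p")
  kern <- array(0, dim = c(3, 2, 1)); kern[, 1, 1] <- c(1, 0.5, 0.2)
  y <- simulate_neural(x, kern, snr = 2, seed = 1, fs = 50)$data
  cv <- trf_crossval(list(x, x, x),
                     lapply(1:3, function(i)
                       simulate_neural(x, kern, snr = 2, seed = i, fs = 50)$data),
                     fs = 50, lag_window_ms = c(0, 60), lambda = c(1, 100))
  expect_s3_class(cv$model, "trf")
  # with an infinite penalty on band 2 the S_p weights are exactly zero
  fit <- melodytrf:::ridge_solve(
    melodytrf:::prep_normal(melodytrf:::agg_stats(
      list(melodytrf:::trial_stats(build_lagged_design(x, c(0, 60), fs = 50), y)), 1L)),
    c(rep(1, 4), rep(Inf, 4)))
  expect_true(all(fit$w[5:8, ] == 0))
  expect_false(all(fit$w[1:4, ] == 0))
})
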