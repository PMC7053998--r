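test_that("identical score sets give zero enhancement and p near 1", {
  set.seed(1)
  r <- matrix(runif(40, 0, 0.5), 10, 4)
  cmp <- compare_feature_sets(r, r, n_perm = 500, seed = 2)
  expect_equal(cmp$mean_delta, 0)
  expect_equal(cmp$cohens_d, 0)
  expect_gt(cmp$p, 0.9)
  expect_error(compare_feature_sets(r, r[1:5, ]), "subject counts differ")
})

test_that("a built-in expectation effect is detected across a small cohort", {
  spec <- random_markov_spec(seed = 3)
  cfg <- default_config(n_subjects = 6L, n_pieces = 6L,
                        notes_per_piece = 120L, n_channels = 2L,
                        lambda = 10^seq(0, 6, 2))
  co <- make_cohort(spec, n_subjects = 6L, n_pieces = 6L,
                    notes_per_piece = 120L, n_channels = 2L, snr = 0.2,
                    base_seed = 5L)
  res <- cohort_feature_comparison(co, NULL, cfg)  # exact-table LTM
  expect_gt(res$comparison$mean_delta, 0)
  expect_gte(res$comparison$n_positive, 5)
  expect_lt(res$comparison$p, 0.05)
})

test_that("backward elimination localizes a lag-restricted kernel", {
  fs <- 64
  n <- 24 * fs
  lag_s <- seq(0, 0.45, by = 1 / fs)
  kern <- array(0, dim = c(length(lag_s), 1, 1))
  kern[lag_s >= 0.2 & lag_s <= 0.25, 1, 1] <- 1
  xs <- lapply(1:15, function(i) {
    set.seed(i)
    x <- numeric(n)
    idx <- which(runif(n) < 3 / fs)
    x[idx] <- exp(rnorm(length(idx), 0, 0.5))
    matrix(x)
  })
  ys <- lapply(1:15, function(i)
    simulate_neural(xs[[i]], kern, snr = 1, seed = 50 + i, fs = fs)$data)
  res <- backward_eliminate_lags(xs, ys, fs = fs, n_perm = 1000, seed = 3)
  expect_equal(sort(unique(res$window_start_ms)), seq(-150, 700, 50))
  sig <- res[res$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$window_start_ms >= 150 & sig$window_end_ms <= 300))
  expect_warning(
    backward_eliminate_lags(xs[1:4], ys[1:4], fs = fs, n_perm = 50, seed = 1),
    "coarse")
  expect_error(backward_eliminate_lags(xs[1:3], ys[1:3], fs = fs), "4 trials")
})

test_that("an all-zero predictor is redundant for lag relevance", {
  fs <- 64
  set.seed(9)
  xs1 <- lapply(1:4, function(i) matrix(rnorm(10 * fs)))
  xs2 <- lapply(xs1, function(x) cbind(x, 0))
  kern <- array(0, dim = c(5, 1, 1)); kern[, 1, 1] <- c(0, 1, 2, 1, 0)
  ys <- lapply(1:4, function(i)
    simulate_neural(xs1[[i]], kern, snr = 2, seed = i, fs = fs)$data)
  r1 <- backward_eliminate_lags(xs1, ys, fs = fs, outer_window_ms = c(0, 200),
                                lambda = 1, n_perm = 200, seed = 2)
  r2 <- backward_eliminate_lags(xs2, ys, fs = fs, outer_window_ms = c(0, 200),
                                lambda = 1, n_perm = 200, seed = 2)
  expect_equal(r2$r_loss, r1$r_loss, tolerance = 1e-8)
})

test_that("TRF component contrasts have the documented algebra", {
  fs <- 64
  nl <- 10
  fn <- c("Env", "Env'", "S_p", "H_p", "S_o", "H_o")
  mk_model <- function(w) {
    structure(list(weights = w, lag_ms = seq(0, by = 1000 / fs,
                                             length.out = nl),
                   feature_names = dimnames(w)[[2]],
                   n_channels = dim(w)[3]),
              class = "trf")
  }
  # identical surprise and entropy kernels -> zero contrast
  w <- array(0, dim = c(nl, 6, 2), dimnames = list(NULL, fn, NULL))
  bump <- sin(seq(0, pi, length.out = nl))
  for (f in 3:6) w[, f, ] <- bump
  cc <- trf_component_contrasts(mk_model(w))
  expect_equal(max(abs(cc$surprise_vs_entropy)), 0)
  expect_equal(max(abs(cc$pitch_vs_onset)), 0)

  # swapping the groups flips the sign
  w2 <- w
  w2[, "S_p", ] <- 2 * bump; w2[, "S_o", ] <- 2 * bump
  c2 <- trf_component_contrasts(mk_model(w2))
  w3 <- w
  w3[, "H_p", ] <- 2 * bump; w3[, "H_o", ] <- 2 * bump
  c3 <- trf_component_contrasts(mk_model(w3))
  expect_equal(c2$surprise_vs_entropy, -c3$surprise_vs_entropy)

  # latency split: onset kernels early, pitch kernels late
  w4 <- array(0, dim = c(nl, 6, 1), dimnames = list(NULL, fn, NULL))
  w4[1:4, "S_o", 1] <- 1; w4[1:4, "H_o", 1] <- 1
  w4[6:10, "S_p", 1] <- 1; w4[6:10, "H_p", 1] <- 1
  c4 <- trf_component_contrasts(mk_model(w4))
  expect_true(all(c4$pitch_vs_onset[1:4, 1] < 0))
  expect_true(all(c4$pitch_vs_onset[6:10, 1] > 0))

  expect_error(trf_component_contrasts(
    mk_model(w[, 1:2, , drop = FALSE])), "lacks expectation features")
})
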