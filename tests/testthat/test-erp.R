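erp_fixture <- function(n_notes = 300, snr = 2, sp_gain = TRUE, seed = 1,
                        gain_sd = 0.15) {
  fs <- 64
  spec <- random_markov_spec(seed = 11)
  mel <- generate_melody(spec, n_notes, seed = 21)
  te <- true_expectations(spec, mel)
  gains <- melodytrf:::with_seed(31, exp(rnorm(n_notes, 0, gain_sd)))
  env <- synthesize_envelope(mel, fs, gains = gains)
  fm <- assemble_features("AM", env, te, fs)
  # all-positive kernels: surprise must scale the response magnitude up,
  # not interfere with an opposite-sign acoustic component
  kern <- abs(default_trf_kernels(fs, n_channels = 1,
                                  expectation_peak_s = 0.15, seed = 2))
  kern[, 4:6, ] <- 0
  if (!sp_gain) kern[, 3, ] <- 0
  rec <- simulate_neural(fm, kern, snr = snr, seed = seed)
  meta <- as.data.frame(te)
  meta$peak_env <- melodytrf:::peak_envelope(env, fs, te$onset_s)
  list(rec = rec, te = te, meta = meta, fs = fs)
}

test_that("epoching aligns to onsets and drops boundary notes", {
  fs <- 64
  x <- matrix(0, 10 * fs, 1)
  x[round(5 * fs) + 1, 1] <- 7
  ep <- epoch_notes(x, onsets = 5, window_ms = c(-100, 400), fs = fs)
  expect_equal(dim(ep$epochs)[1], 1)
  expect_equal(ep$epochs[1, which(ep$time_ms == 0), 1], 7)

  ep2 <- epoch_notes(x, onsets = c(0.01, 5), window_ms = c(-100, 400),
                     fs = fs)
  expect_equal(ep2$n_dropped, 1)
  expect_error(epoch_notes(x, onsets = 0.01, window_ms = c(-100, 400),
                           fs = fs), "no note window")

  const <- matrix(3, 5 * fs, 2)
  epc <- epoch_notes(const, onsets = 2, window_ms = c(-50, 50), fs = fs)
  expect_true(all(epc$epochs == 3))
})

test_that("envelope matching keeps notes near the median peak envelope", {
  f <- erp_fixture()
  ep <- epoch_notes(f$rec, f$te$onset_s, window_ms = c(-100, 400),
                    meta = f$meta)
  m <- select_envelope_matched(ep)
  med <- median(f$meta$peak_env)
  expect_true(all(abs(m$meta$peak_env - med) <= 0.05 * med))
  expect_lt(diff(range(m$meta$peak_env)), 0.11 * med)
  frac <- attr(m, "retained_fraction")
  expect_gt(frac, 0.1); expect_lt(frac, 0.4)

  # identical peak envelopes: everything retained
  ep1 <- ep
  ep1$meta$peak_env <- 1
  m1 <- select_envelope_matched(ep1)
  expect_equal(attr(m1, "retained_fraction"), 1)
})

test_that("quantile splits are stable, disjoint and sized", {
  f <- erp_fixture(n_notes = 120)
  ep <- epoch_notes(f$rec, f$te$onset_s, window_ms = c(-100, 400),
                    meta = f$meta)
  ep$meta$fake <- seq_len(dim(ep$epochs)[1])
  n <- dim(ep$epochs)[1]
  grp <- split_by_feature(ep, "fake", 0.2)
  m <- floor(n * 0.2)
  expect_equal(dim(grp$high$epochs)[1], m)
  expect_equal(dim(grp$low$epochs)[1], m)
  expect_equal(grp$low$meta$fake, seq_len(m))
  expect_equal(grp$high$meta$fake, seq(n - m + 1, n))
  expect_length(intersect(grp$low$meta$fake, grp$high$meta$fake), 0)

  ep$meta$flat <- 1
  expect_error(split_by_feature(ep, "flat"), "degenerate")
})

test_that("identical groups show no significant latencies", {
  f <- erp_fixture(n_notes = 150)
  ep <- epoch_notes(f$rec, f$te$onset_s, window_ms = c(-100, 400),
                    meta = f$meta)
  idx <- seq_len(min(40, dim(ep$epochs)[1]))
  g <- melodytrf:::subset_epochs(ep, idx)
  ec <- erp_contrast(g, g, n_perm = 300, seed = 2)
  expect_true(all(!ec$latency_significant))
  expect_gt(ec$power_p, 0.9)
})

test_that("union ERP equals the weighted mean of group ERPs", {
  f <- erp_fixture(n_notes = 150)
  ep <- epoch_notes(f$rec, f$te$onset_s, window_ms = c(-100, 400),
                    meta = f$meta)
  n <- dim(ep$epochs)[1]
  a <- melodytrf:::subset_epochs(ep, 1:30)
  b <- melodytrf:::subset_epochs(ep, 31:n)
  erp_u <- colMeans(ep$epochs[, , 1])
  erp_w <- (30 * colMeans(a$epochs[, , 1]) +
              (n - 30) * colMeans(b$epochs[, , 1])) / n
  expect_equal(erp_u, erp_w, tolerance = 1e-12)
})

test_that("surprise-scaled responses yield a power difference among matched notes", {
  f <- erp_fixture(n_notes = 2500, snr = 3)
  ep <- epoch_notes(f$rec, f$te$onset_s, window_ms = c(-100, 400),
                    meta = f$meta)
  m <- select_envelope_matched(ep)
  grp <- split_by_feature(m, "S_p", 0.2)
  # the confound control: matched mean peak envelopes within 5%
  expect_lt(abs(mean(grp$high$meta$peak_env) - mean(grp$low$meta$peak_env)) /
              mean(grp$low$meta$peak_env), 0.05)
  ec <- erp_contrast(grp$high, grp$low, n_perm = 500, seed = 5)
  expect_gt(ec$power_high, ec$power_low)
  expect_lt(ec$power_p, 0.05)
})
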