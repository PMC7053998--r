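test_that("low-rate band-pass is zero-phase with the stated band", {
  fs <- 512
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- sin(2 * pi * 4 * t) + 2 * sin(2 * pi * 0.05 * t) + 5
  bp <- bandpass_lowrate(neural_recording(matrix(x), fs))
  mid <- 1000:4000
  # 4 Hz tone passed with gain > 0.9 and zero lag
  expect_gt(sd(bp$data[mid, 1]) / sd(sin(2 * pi * 4 * t)[mid]), 0.9)
  cc <- ccf(bp$data[mid, 1], sin(2 * pi * 4 * t)[mid], lag.max = 20,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC removed, slow drift attenuated > 20 dB
  expect_lt(abs(mean(bp$data)), 0.05)
  drift <- bandpass_lowrate(neural_recording(matrix(2 * sin(2 * pi * 0.05 * t)),
                                             fs))
  expect_lt(sd(drift$data[mid, 1]) / sd(2 * sin(2 * pi * 0.05 * t)[mid]),
            10^(-20 / 20))
  expect_error(bandpass_lowrate(neural_recording(matrix(x), 12)),
               "Nyquist")
})

test_that("high-gamma power tracks in-band amplitude", {
  fs <- 1000
  t <- seq(1 / fs, 5, by = 1 / fs)
  x <- cbind(2 * sin(2 * pi * 100 * t), sin(2 * pi * 10 * t))
  hg <- highgamma_power(neural_recording(x, fs))
  expect_equal(hg$fs, 100)
  mid <- 100:400
  expect_lt(abs(mean(hg$data[mid, 1]) - 2), 0.05)
  expect_lt(mean(hg$data[mid, 2]), 0.05)
  # AM carrier: output tracks the modulator
  a <- 1 + 0.5 * sin(2 * pi * 2 * t)
  hg2 <- highgamma_power(neural_recording(matrix(a * sin(2 * pi * 110 * t)),
                                          fs))
  target <- approx(t, a, xout = (mid - 1) / 100, rule = 2)$y
  expect_gt(cor(hg2$data[mid, 1], target), 0.98)
  expect_error(highgamma_power(neural_recording(matrix(rnorm(100)), 200)),
               "too low")
})

test_that("outlier channels are detected and repaired by neighbour means", {
  set.seed(1)
  d <- matrix(rnorm(1000 * 9), 1000, 9)
  coords <- cbind(rep(1:3, each = 3), rep(1:3, 3))
  clean <- detect_and_repair_channels(neural_recording(d, 100), coords)
  expect_length(attr(clean, "repair_report"), 0)

  d2 <- d; d2[, 5] <- d2[, 5] * 10
  fixed <- detect_and_repair_channels(neural_recording(d2, 100), coords)
  expect_equal(attr(fixed, "repair_report"), "ch5")
  nb_var <- median(apply(d2[, c(2, 4, 6, 8)], 2, var))
  expect_lte(var(fixed$data[, 5]), nb_var)
  # untouched channels unchanged; input not modified (pure op)
  expect_equal(fixed$data[, 1], d2[, 1])

  d3 <- d; d3[, c(1, 5, 9)] <- d3[, c(1, 5, 9)] * 10
  expect_error(detect_and_repair_channels(neural_recording(d3, 100), coords),
               "25%")
})

test_that("mastoid re-referencing removes common signals and is idempotent", {
  set.seed(2)
  base <- matrix(rnorm(500 * 4), 500, 4,
                 dimnames = list(NULL, c("a", "b", "M1", "M2")))
  rec <- neural_recording(base, 100)
  # zero mastoids: nothing changes
  z <- base; z[, 3:4] <- 0
  rz <- rereference_mastoids(neural_recording(z, 100), c("M1", "M2"))
  expect_equal(rz$data, z, ignore_attr = TRUE)
  # a common-mode signal added everywhere is removed exactly
  cm <- sin(2 * pi * 3 * seq_len(500) / 100)
  rec_cm <- neural_recording(base + cm, 100)
  r1 <- rereference_mastoids(rec, c("M1", "M2"))
  r2 <- rereference_mastoids(rec_cm, c("M1", "M2"))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
  # idempotence
  expect_equal(rereference_mastoids(r1, c("M1", "M2"))$data, r1$data,
               tolerance = 1e-12)
  expect_equal(r1$channel_kinds[3:4], c("reference", "reference"))
  expect_error(rereference_mastoids(rec, c("M1", "Mx")), "Mx")
})

test_that("responsive-electrode selection uses chunked effect sizes", {
  set.seed(3)
  sil <- matrix(rnorm(3000 * 3), 3000, 3)
  mus <- sil + cbind(rnorm(3000, 0, 2), 0, 0)
  sel <- select_responsive_electrodes(neural_recording(mus, 100),
                                      neural_recording(sil, 100))
  expect_identical(sel$selected, "ch1")
  expect_gt(sel$d[["ch1"]], 0.5)
  expect_lt(abs(sel$d[["ch2"]]), 0.5)
  # statistically identical recordings: no selection expected here
  sil2 <- matrix(rnorm(3000 * 3), 3000, 3)
  sel0 <- select_responsive_electrodes(neural_recording(sil2, 100),
                                       neural_recording(sil, 100), seed = 4)
  expect_length(sel0$selected, 0)
  short <- neural_recording(matrix(rnorm(30 * 3), 30, 3), 100)
  expect_error(select_responsive_electrodes(short, short), "too short")
})
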