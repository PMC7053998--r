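test_that("exact-table LTM without STM reproduces the analytic truth", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 150, seed = 11)
  te <- true_expectations(spec, mel)
  es <- expectation_series(mel, spec, spec, stm = FALSE)
  for (col in c("S_p", "H_p", "S_o", "H_o")) {
    expect_lt(max(abs(es[[col]] - te[[col]])), 1e-9)
  }
})

test_that("first-note conventions hold", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 30, seed = 3)
  es <- expectation_series(mel, NULL, NULL, stm = FALSE)
  # uniform LTM, empty context: S_p = log2 |E|
  expect_equal(es$S_p[1], log2(3))
  expect_equal(es$S_o[1], 0)
  expect_equal(es$H_o[1], 0)
})

test_that("prediction is strictly causal", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 40, seed = 5)
  es1 <- expectation_series(mel, spec, spec)
  mel2 <- mel
  mel2$pitch_sym[30] <- (mel2$pitch_sym[30] %% 3L) + 1L
  mel2$pitch[30] <- spec$pitch_alphabet[mel2$pitch_sym[30]]
  es2 <- expectation_series(mel2, spec, spec)
  expect_equal(es1$S_p[1:29], es2$S_p[1:29])
  expect_equal(es1$H_p[1:29], es2$H_p[1:29])
  expect_false(isTRUE(all.equal(es1$S_p[30], es2$S_p[30])))
})

test_that("repeating one pitch drives surprise down via the STM", {
  spec <- markov_spec(60:63, 0.3, order = 0L)
  mel <- generate_melody(spec, 100, seed = 1)
  mel$pitch_sym[] <- 2L
  mel$pitch[] <- 61L
  es <- expectation_series(mel, NULL, NULL, stm = TRUE)
  s <- es$S_p[5:100]
  expect_true(all(diff(s) <= 1e-9))
  expect_lt(s[length(s)], es$S_p[2])
})

test_that("memory restriction: infinity is the identity, chunks reset the STM", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 120, seed = 21)
  full <- expectation_series(mel, spec, spec)
  inf_mem <- memory_restricted_series(mel, spec, spec, memory_bars = Inf)
  expect_identical(full, inf_mem)
  expect_error(memory_restricted_series(mel, spec, spec, memory_bars = 3),
               "must be one of")

  # at each chunk start the STM is empty: the estimate equals the LTM row
  # combined with the uniform escape floor
  m1 <- memory_restricted_series(mel, spec, spec, memory_bars = 1)
  starts <- which(!duplicated(mel$bar_index))[-1]  # skip the first note
  for (i in starts[1:3]) {
    ltm_row <- melodytrf:::predictive_distribution(
      melodytrf:::spec_row(spec$pitch_transitions,
                           mel$pitch_sym[seq_len(i - 1)], spec$order))
    unif <- melodytrf:::predictive_distribution(rep(1 / 3, 3))
    expected <- surprise(combine_distributions(ltm_row, unif),
                         mel$pitch_sym[i])
    expect_equal(m1$S_p[i], expected, tolerance = 1e-9)
  }
})

test_that("longer memory does not increase average code length on structured input", {
  spec <- random_markov_spec(seed = 8, phrase_repeat_prob = 0.5,
                             bars_per_phrase = 2L)
  ltm <- train_ltm(spec, 4L, 200L, seed = 9)
  mels <- lapply(1:4, function(p) generate_melody(spec, 150, seed = 30 + p))
  mean_s <- function(mem) {
    mean(vapply(mels, function(m) {
      es <- memory_restricted_series(m, ltm$pitch, ltm$ioi, memory_bars = mem)
      mean(es$S_p)
    }, numeric(1)))
  }
  expect_lte(mean_s(32), mean_s(1))
})

test_that("shuffling preserves values and onsets and is seeded", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 60, seed = 2)
  es <- true_expectations(spec, mel)
  sh1 <- shuffle_series(es, seed = 4)
  sh2 <- shuffle_series(es, seed = 4)
  expect_identical(sh1, sh2)
  expect_identical(sh1$onset_s, es$onset_s)
  for (col in c("S_p", "H_p", "S_o", "H_o")) {
    expect_identical(sort(sh1[[col]]), sort(es[[col]]))
  }
  expect_false(identical(sh1$S_p, es$S_p))
  # the same permutation is applied to all four columns: the multiset of
  # value 4-tuples is preserved
  tuples <- function(x) {
    m <- as.matrix(x[, c("S_p", "H_p", "S_o", "H_o")])
    m[do.call(order, as.data.frame(m)), ]
  }
  expect_equal(tuples(sh1), tuples(es), ignore_attr = TRUE)

  one <- es[1, , drop = FALSE]
  class(one) <- class(es)
  expect_identical(shuffle_series(one, seed = 1)$S_p, one$S_p)
})
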