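test_that("markov_spec validates transition tables", {
  expect_error(
    markov_spec(60:61, 0.3,
                pitch_transitions = list("." = c(0.6, 0.5),
                                         "1" = c(0.5, 0.5),
                                         "2" = c(0.5, 0.5)),
                order = 1L),
    "does not sum to 1")
  expect_error(
    markov_spec(60:61, 0.3,
                pitch_transitions = list("1" = c(0.5, 0.5)), order = 1L),
    "empty-context")
  expect_error(
    markov_spec(60:61, 0.3,
                pitch_transitions = list("." = c(0.5, 0.5),
                                         "1,2" = c(0.5, 0.5)),
                order = 1L),
    "longer than order")
})

test_that("degenerate single-pitch alphabet always emits that pitch", {
  spec <- markov_spec(60L, c(0.3, 0.6),
                      pitch_transitions = list("." = 1, "1" = 1),
                      order = 1L)
  mel <- generate_melody(spec, 40, seed = 1)
  expect_true(all(mel$pitch == 60L))
})

test_that("melody generation is deterministic and well-formed", {
  spec <- tiny_spec()
  m1 <- generate_melody(spec, 200, seed = 42)
  m2 <- generate_melody(spec, 200, seed = 42)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- generate_melody(spec, 200, seed = 43)
  expect_false(identical(m3$pitch, m1$pitch))
  expect_true(all(diff(m1$onset_s) > 0))
  expect_true(all(m1$duration_s > 0))
  expect_true(all(m1$pitch %in% spec$pitch_alphabet))
  expect_true(all(m1$ioi_class[-1] %in% seq_along(spec$ioi_alphabet)))
  # bar indices follow cumulative time
  expect_identical(m1$bar_index,
                   as.integer(floor(m1$onset_s / spec$bar_duration_s + 1e-9)))
})

test_that("empirical transition frequencies converge to the source tables", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 50000, seed = 7)
  s <- mel$pitch_sym
  for (ctx in 1:3) {
    idx <- which(s[-length(s)] == ctx)
    emp <- tabulate(s[idx + 1L], nbins = 3) / length(idx)
    expect_lt(max(abs(emp - spec$pitch_transitions[[as.character(ctx)]])),
              0.01)
  }
  # total-variation distance of the pitch marginal
  P <- matrix(unlist(spec$pitch_transitions[c("1", "2", "3")]),
              3, 3, byrow = TRUE)
  stat <- Re(eigen(t(P))$vectors[, 1]); stat <- stat / sum(stat)
  marg <- tabulate(s, nbins = 3) / length(s)
  expect_lt(0.5 * sum(abs(marg - stat)), 0.01)
})

test_that("true expectations match analytic identities", {
  # deterministic source: no surprise, no uncertainty
  mel <- generate_melody(onehot_spec(), 30, seed = 1)
  te <- true_expectations(onehot_spec(), mel)
  expect_equal(max(abs(te$S_p)), 0)
  expect_equal(max(abs(te$H_p)), 0)

  # uniform source over 8 pitches: H_p = 3 bits everywhere
  spec8 <- markov_spec(60:67, 0.3, order = 0L)
  mel8 <- generate_melody(spec8, 25, seed = 2)
  te8 <- true_expectations(spec8, mel8)
  expect_equal(unique(round(te8$H_p, 12)), 3)
  expect_equal(unique(round(te8$S_p, 12)), 3)

  # two-way 0.5/0.5 row: S = 1 bit either way
  spec2 <- markov_spec(60:61, 0.3,
                       pitch_transitions = list("." = c(0.5, 0.5),
                                                "1" = c(0.5, 0.5),
                                                "2" = c(0.5, 0.5)),
                       order = 1L)
  te2 <- true_expectations(spec2, generate_melody(spec2, 20, seed = 3))
  expect_equal(unique(round(te2$S_p, 12)), 1)

  # general bounds
  te_g <- true_expectations(tiny_spec(), generate_melody(tiny_spec(), 300, seed = 4))
  expect_true(all(te_g$S_p >= 0 & te_g$S_o >= 0))
  expect_true(all(te_g$H_p <= log2(3) + 1e-12))
  expect_true(all(te_g$H_o <= log2(2) + 1e-12))
})

test_that("pitches outside the alphabet are rejected", {
  spec <- tiny_spec()
  mel <- generate_melody(spec, 10, seed = 1)
  mel$pitch[3] <- 99L
  expect_error(true_expectations(spec, mel), "outside the spec alphabet")
})

test_that("phrase repetition injects long-range structure", {
  spec <- random_markov_spec(seed = 5, phrase_repeat_prob = 0.6,
                             bars_per_phrase = 2L)
  mel <- generate_melody(spec, 400, seed = 6)
  expect_gt(mean(mel$from_repeat), 0.2)
  spec0 <- random_markov_spec(seed = 5, phrase_repeat_prob = 0)
  expect_true(!any(generate_melody(spec0, 400, seed = 6)$from_repeat))
})
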