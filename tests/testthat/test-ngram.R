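test_that("empty and degenerate models back off to the escape floor", {
  m <- ngram_model(alphabet = 1:4)
  expect_equal(as.numeric(predict(m, integer(0))), rep(0.25, 4))
  expect_equal(as.numeric(predict(m, c(1L, 2L, 3L))), rep(0.25, 4))

  m1 <- ngram_model(list(rep(1L, 4)), alphabet = 1L)
  expect_equal(as.numeric(predict(m1, 1L)), 1)
})

test_that("count tables populate per context instance", {
  s <- c(1L, 2L, 1L, 2L, 1L, 2L)
  m <- ngram_model(list(s), alphabet = 1:2, max_order = 2L)
  env <- m$counts
  keys <- setdiff(ls(env), ".n")
  order2 <- keys[startsWith(keys, "2|")]
  expect_equal(sum(vapply(order2, function(k) sum(env[[k]]), numeric(1))), 4)
  order0 <- env[["0|."]]
  expect_equal(sum(order0), 6)
})

test_that("symbols outside the alphabet are rejected with position", {
  m <- ngram_model(alphabet = 1:3)
  expect_error(ngram_insert(m, 5L, c(1L, 2L)), "outside alphabet.*position 3")
})

test_that("predict_distribution matches the independent PPM-C oracle", {
  # exhaustive over binary corpora up to length 6, contexts up to length 3
  for (len in 1:6) {
    for (id in 0:(2^len - 1)) {
      s <- as.integer(intToBits(id))[1:len] + 1L
      m <- ngram_model(list(s), 1:2, max_order = Inf)
      for (clen in 0:3) {
        for (cid in 0:(2^clen - 1)) {
          ctx <- if (clen == 0) integer(0) else
            as.integer(intToBits(cid))[1:clen] + 1L
          expect_lt(max(abs(as.numeric(predict(m, ctx)) -
                              ppm_oracle(list(s), ctx, 2))), 1e-12)
        }
      }
    }
  }
  # spot-check the documented 5-symbol corpus
  m <- ngram_model(list(c(1L, 2L, 1L, 2L, 1L)), 1:2, max_order = Inf)
  expect_lt(max(abs(as.numeric(predict(m, 1L)) -
                      ppm_oracle(list(c(1L, 2L, 1L, 2L, 1L)), 1L, 2))), 1e-12)
})

test_that("every predictive distribution is a strictly positive pmf", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    seqs <- lapply(seq_len(sample(1:3, 1)), function(j)
      sample.int(k, sample(3:15, 1), replace = TRUE))
    m <- ngram_model(seqs, 1:k, max_order = Inf)
    ctx <- sample.int(k, sample(0:6, 1), replace = TRUE)
    p <- as.numeric(predict(m, ctx))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_lte(entropy_bits(p), log2(k) + 1e-12)
  }
})

test_that("surprise and entropy follow their closed forms", {
  d <- melodytrf:::predictive_distribution(c(0.5, 0.25, 0.25))
  expect_equal(surprise(d, 1L), 1)
  expect_equal(surprise(d, 2L), 2)
  expect_equal(entropy_bits(d), 1.5)
  expect_equal(surprise(melodytrf:::predictive_distribution(1), 1L), 0)
  expect_equal(entropy_bits(c(1, 0, 0)), 0)
  expect_equal(entropy_bits(rep(0.25, 4)), 2)
  expect_error(surprise(d, 7L), "outside the alphabet")
  # entropy maximal iff uniform
  expect_equal(entropy_bits(rep(1 / 3, 3)), log2(3))
  expect_lt(entropy_bits(c(0.5, 0.3, 0.2)), log2(3))
})

test_that("LTM/STM combination is entropy-weighted and idempotent", {
  d <- melodytrf:::predictive_distribution(c(0.7, 0.2, 0.1))
  comb <- combine_distributions(d, d)
  expect_equal(as.numeric(comb), as.numeric(d), tolerance = 1e-12)

  # mirrored two-symbol rows have equal entropy -> symmetric output
  d1 <- melodytrf:::predictive_distribution(c(0.9, 0.1))
  d2 <- melodytrf:::predictive_distribution(c(0.1, 0.9))
  expect_equal(as.numeric(combine_distributions(d1, d2)), c(0.5, 0.5),
               tolerance = 1e-12)

  # a uniform (maximum-entropy) partner is down-weighted relative to the
  # plain unweighted geometric mean
  du <- melodytrf:::predictive_distribution(c(0.5, 0.5))
  weighted <- as.numeric(combine_distributions(d1, du))
  plain <- exp(0.5 * log(c(0.9, 0.1)) + 0.5 * log(c(0.5, 0.5)))
  plain <- plain / sum(plain)
  kl <- function(p, q) sum(p * log2(p / q))
  expect_lt(kl(weighted, c(0.9, 0.1)), kl(plain, c(0.9, 0.1)))

  expect_error(combine_distributions(d1, d), "alphabet mismatch")
})
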