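# Independent oracles and small fixtures used across the test files.

# PPM-C predictive distribution computed by direct top-down recursion with
# fresh substring counting at every call - structurally independent of the
# package's incremental count tables.
ppm_oracle <- function(seqs, context, k, max_order = 16L) {
  count_after <- function(ctx) {
    cnt <- integer(k)
    L <- length(ctx)
    for (s in seqs) {
      if (length(s) < L + 1L) next
      for (i in seq_len(length(s) - L)) {
        if (L == 0L || all(s[i:(i + L - 1L)] == ctx)) {
          cnt[s[i + L]] <- cnt[s[i + L]] + 1L
        }
      }
    }
    cnt
  }
  rec <- function(ctx) {
    base <- if (length(ctx) == 0L) rep(1 / k, k) else rec(ctx[-1L])
    cnt <- count_after(ctx)
    n <- sum(cnt)
    if (n == 0L) return(base)
    t <- sum(cnt > 0L)
    cnt / (n + t) + t / (n + t) * base
  }
  if (length(context) > max_order) {
    context <- context[(length(context) - max_order + 1L):length(context)]
  }
  rec(context)
}

# One-way repeated-measures F from explicit sums of squares.
hand_rm_F <- function(d) {
  n <- nrow(d); k <- ncol(d)
  gm <- mean(d)
  ss_cond <- n * sum((colMeans(d) - gm)^2)
  ss_subj <- k * sum((rowMeans(d) - gm)^2)
  ss_err <- sum((d - gm)^2) - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# A tiny fully hand-specified order-1 source over 3 pitches and 2 IOIs.
tiny_spec <- function(...) {
  markov_spec(
    pitch_alphabet = c(60L, 62L, 64L),
    ioi_alphabet = c(0.3, 0.6),
    pitch_transitions = list(
      "." = c(0.5, 0.3, 0.2),
      "1" = c(0.1, 0.6, 0.3),
      "2" = c(0.7, 0.1, 0.2),
      "3" = c(1 / 3, 1 / 3, 1 / 3)),
    ioi_transitions = list(
      "." = c(0.5, 0.5),
      "1" = c(0.8, 0.2),
      "2" = c(0.25, 0.75)),
    order = 1L, ...)
}

# Deterministic source: every row one-hot.
onehot_spec <- function() {
  markov_spec(
    pitch_alphabet = c(60L, 62L),
    ioi_alphabet = c(0.3, 0.6),
    pitch_transitions = list("." = c(1, 0), "1" = c(0, 1), "2" = c(1, 0)),
    ioi_transitions = list("." = c(1, 0), "1" = c(1, 0), "2" = c(1, 0)),
    order = 1L)
}
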