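#' Note-locked epoching of a neural recording
#'
#' Cuts one epoch per note onset from a continuous recording, aligned so that
#' epoch time 0 is the note onset. Notes whose window would cross a trial
#' edge are dropped (and counted). Per-note metadata (envelope peak,
#' expectation values, preceding inter-onset interval) travels with the
#' epochs so later selection steps can condition on it.
#'
#' @param rec a [neural_recording()] / `simulated_recording` / matrix.
#' @param onsets note onsets in seconds.
#' @param window_ms two-element window `c(pre, post)` in ms around each
#'   onset; `pre` is negative (e.g. `c(-100, 400)`).
#' @param fs sampling rate when `rec` is a matrix.
#' @param meta optional data frame of per-note metadata (one row per onset);
#'   typically the `expectation_series` columns plus `peak_env`.
#' @return An `epoch_set`: list with `epochs` (note x time x channel array),
#'   `time_ms`, `meta`, `n_dropped`.
#' @export
epoch_notes <- function(rec, onsets, window_ms = c(-100, 400), fs = NULL,
                        meta = NULL) {
  rec <- as_recording(rec, fs)
  n <- nrow(rec$data); n_ch <- ncol(rec$data)
  i_pre <- round(window_ms[1L] / 1000 * rec$fs)
  i_post <- round(window_ms[2L] / 1000 * rec$fs)
  centers <- round(onsets * rec$fs) + 1L
  ok <- centers + i_pre >= 1L & centers + i_post <= n
  if (!any(ok)) stop("no note window fits inside the recording")
  keep <- which(ok)
  n_t <- i_post - i_pre + 1L
  ep <- array(NA_real_, dim = c(length(keep), n_t, n_ch))
  for (j in seq_along(keep)) {
    idx <- (centers[keep[j]] + i_pre):(centers[keep[j]] + i_post)
    ep[j, , ] <- rec$data[idx, , drop = FALSE]
  }
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  structure(list(epochs = ep, time_ms = seq(i_pre, i_post) / rec$fs * 1000,
                 fs = rec$fs, meta = meta, onsets = onsets[keep],
                 n_dropped = sum(!ok)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epochs x %d samples x %d channels (%g..%g ms), %d dropped\n",
              dim(x$epochs)[1L], dim(x$epochs)[2L], dim(x$epochs)[3L],
              min(x$time_ms), max(x$time_ms), x$n_dropped))
  invisible(x)
}

subset_epochs <- function(epochs, idx) {
  out <- epochs
  out$epochs <- epochs$epochs[idx, , , drop = FALSE]
  if (!is.null(epochs$meta)) out$meta <- epochs$meta[idx, , drop = FALSE]
  out$onsets <- epochs$onsets[idx]
  out
}

#' Envelope-matched note selection
#'
#' Keeps only epochs whose per-note peak envelope lies within `tolerance` of
#' the median peak envelope across all notes. This is the key acoustic
#' confound control: any later contrast between note groups is computed on
#' notes of (near-)identical envelope, so amplitude differences cannot
#' masquerade as expectation effects. The realized retained fraction is
#' reported.
#'
#' @param epochs an `epoch_set` whose `meta` has a `peak_env` column.
#' @param tolerance relative tolerance around the median (default 0.05 =
#'   plus or minus 5 percent).
#' @return The matched `epoch_set`, with attributes `retained_fraction`.
#' @export
select_envelope_matched <- function(epochs, tolerance = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"))
  pe <- epochs$meta$peak_env
  if (is.null(pe)) stop("epoch metadata lacks a 'peak_env' column")
  med <- stats::median(pe)
  keep <- which(abs(pe - med) <= tolerance * med)
  if (length(keep) < 20L) {
    warning(sprintf("only %d envelope-matched notes retained", length(keep)))
  }
  out <- subset_epochs(epochs, keep)
  attr(out, "retained_fraction") <- length(keep) / length(pe)
  out
}

#' Split epochs into high and low quantile groups of a feature
#'
#' Selects the top and bottom `quantile` fraction of epochs by the chosen
#' expectation feature (stable tie-break by note order). The two groups are
#' always disjoint.
#'
#' @param epochs an `epoch_set` with the feature in `meta`.
#' @param feature metadata column, default `"S_p"`.
#' @param quantile fraction per tail (default 0.20).
#' @return List with `high` and `low` `epoch_set`s.
#' @export
split_by_feature <- function(epochs, feature = "S_p", quantile = 0.20) {
  stopifnot(inherits(epochs, "epoch_set"))
  v <- epochs$meta[[feature]]
  if (is.null(v)) stop("metadata lacks column ", feature)
  n <- length(v)
  if (n < 10L) stop("need at least 10 epochs to split")
  if (stats::sd(v) == 0) stop("degenerate feature: all values equal")
  m <- max(1L, floor(n * quantile))
  ord <- order(v, seq_len(n))  # stable
  low <- ord[seq_len(m)]
  high <- ord[seq(n - m + 1L, n)]
  list(high = subset_epochs(epochs, sort(high)),
       low = subset_epochs(epochs, sort(low)))
}

#' ERP contrast between high- and low-expectation notes
#'
#' Computes group-mean event-related traces with 95 percent confidence intervals,
#' per-latency two-tailed permutation tests with FDR correction across
#' latencies, and a permutation test on total ERP power (mean squared
#' amplitude) in `power_window_ms` (default 0-200 ms, the responsive
#' window). Tests permute epoch group labels.
#'
#' @param high,low `epoch_set`s (channel-compatible).
#' @param power_window_ms window for the power comparison.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param channel channel index used for the latency-wise traces.
#' @return An `erp_contrast` list: `time_ms`, `erp_high`, `erp_low`,
#'   `ci_high`, `ci_low`, `latency_p`, `latency_significant`,
#'   `power_high`, `power_low`, `power_p`.
#' @export
erp_contrast <- function(high, low, power_window_ms = c(0, 200),
                         n_perm = 2000L, seed = 1L, channel = 1L) {
  stopifnot(inherits(high, "epoch_set"), inherits(low, "epoch_set"))
  if (!isTRUE(all.equal(high$time_ms, low$time_ms))) {
    stop("mismatched epoch windows")
  }
  t_ms <- high$time_ms
  eh <- high$epochs[, , channel, drop = FALSE][, , 1L]
  el <- low$epochs[, , channel, drop = FALSE][, , 1L]
  if (!is.matrix(eh)) eh <- matrix(eh, nrow = 1L)
  if (!is.matrix(el)) el <- matrix(el, nrow = 1L)
  mh <- colMeans(eh); ml <- colMeans(el)
  ci <- function(m) 1.96 * apply(m, 2L, stats::sd) / sqrt(nrow(m))

  # per-latency label permutation
  nh <- nrow(eh); nl <- nrow(el)
  pool <- rbind(eh, el)
  obs_diff <- mh - ml
  null_diff <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nh + nl, nh)
      colMeans(pool[idx, , drop = FALSE]) - colMeans(pool[-idx, , drop = FALSE])
    }, numeric(length(t_ms))))
  })
  latency_p <- vapply(seq_along(t_ms), function(j) {
    (1 + sum(abs(null_diff[, j]) >= abs(obs_diff[j]))) / (n_perm + 1)
  }, numeric(1))

  # power in the responsive window
  win <- t_ms >= power_window_ms[1L] & t_ms <= power_window_ms[2L]
  pw <- function(m) rowMeans(m[, win, drop = FALSE]^2)
  ph <- pw(eh); pl <- pw(el)
  power_test <- permutation_test(ph, pl, paired = FALSE, n_perm = n_perm,
                                 seed = seed + 1L)
  structure(list(time_ms = t_ms, erp_high = mh, erp_low = ml,
                 ci_high = ci(eh), ci_low = ci(el),
                 latency_p = latency_p,
                 latency_significant = fdr_bh(latency_p),
                 power_high = mean(ph), power_low = mean(pl),
                 power_p = power_test$p_value),
            class = "erp_contrast")
}

#' @export
print.erp_contrast <- function(x, ...) {
  cat(sprintf("ERP contrast: power(high) = %.4g vs power(low) = %.4g (0-200 ms), p = %.4g; %d/%d latencies significant (FDR)\n",
              x$power_high, x$power_low, x$power_p,
              sum(x$latency_significant), length(x$latency_p)))
  invisible(x)
}

#' @export
plot.erp_contrast <- function(x, ...) {
  rng <- range(x$erp_high + x$ci_high, x$erp_high - x$ci_high,
               x$erp_low + x$ci_low, x$erp_low - x$ci_low)
  graphics::plot(x$time_ms, x$erp_high, type = "l", col = "purple",
                 ylim = rng, xlab = "latency (ms)", ylab = "amplitude (a.u.)",
                 main = "ERP by expectation group", ...)
  graphics::lines(x$time_ms, x$erp_low, col = "pink3")
  sig <- which(x$latency_significant)
  if (length(sig)) graphics::points(x$time_ms[sig], rep(rng[1L], length(sig)),
                                    pch = "*", col = "black")
  graphics::legend("topright", c("high surprise", "low surprise"),
                   col = c("purple", "pink3"), lty = 1, bty = "n")
  invisible(x)
}
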