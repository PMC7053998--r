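#' Ground-truth response kernels for the forward model
#'
#' Builds a lag x feature x channel array of smooth gamma-shaped response
#' kernels: acoustic features (Env, Env') peak near 50 ms, expectation
#' features near 200 ms, mirroring the latency split seen between envelope
#' tracking and expectation responses in cortical recordings. Per-channel
#' gains (drawn once from the seed) differentiate channels; expectation
#' kernels can be scaled globally via `expectation_gain` (0 silences them).
#'
#' @param fs sampling rate in Hz.
#' @param feature_names character vector; names starting with `Env` are
#'   treated as acoustic.
#' @param n_channels number of response channels.
#' @param acoustic_peak_s,expectation_peak_s kernel peak latencies (seconds).
#' @param lag_max_s kernel support length in seconds.
#' @param expectation_gain multiplier on all expectation kernels (the
#'   subject-level effect of interest; 0 silences the expectation signal).
#' @param expectation_scale fixed amplitude scale of expectation kernels
#'   relative to acoustic ones. Expectation regressors are sparse impulse
#'   trains, so an unscaled kernel contributes almost no response variance;
#'   the default of 4 makes the expectation response carry roughly half the
#'   acoustic response variance at the default note rate.
#' @param seed integer seed for the per-channel gain pattern.
#' @return Array `[lag, feature, channel]` with dimnames on features.
#' @export
default_trf_kernels <- function(fs, feature_names = c("Env", "Env'", "S_p",
                                                      "H_p", "S_o", "H_o"),
                                n_channels = 4L, acoustic_peak_s = 0.05,
                                expectation_peak_s = 0.2, lag_max_s = 0.45,
                                expectation_gain = 1, expectation_scale = 4,
                                seed = 1L) {
  lags <- seq(0, lag_max_s, by = 1 / fs)
  nf <- length(feature_names)
  acoustic <- startsWith(feature_names, "Env")
  bump <- function(peak) {
    k <- (lags / peak) * exp(1 - lags / peak)
    k^2  # sharpen so support is effectively local around the peak
  }
  kern <- array(0, dim = c(length(lags), nf, n_channels),
                dimnames = list(NULL, feature_names, NULL))
  gains <- with_seed(seed, matrix(stats::runif(nf * n_channels, 0.5, 1.5) *
                                    sample(c(-1, 1), nf * n_channels,
                                           replace = TRUE, prob = c(.3, .7)),
                                  nf, n_channels))
  for (f in seq_len(nf)) {
    base <- bump(if (acoustic[f]) acoustic_peak_s else expectation_peak_s)
    g <- if (acoustic[f]) 1 else expectation_gain * expectation_scale
    for (ch in seq_len(n_channels)) {
      kern[, f, ch] <- g * gains[f, ch] * base
    }
  }
  kern
}

fft_convolve <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- stats::nextn(n + m - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(k, numeric(L - m))), inverse = TRUE)) / L
  y[seq_len(n)]
}

#' Simulate a multichannel neural recording from known kernels
#'
#' Linear time-invariant forward model: each channel is the sum over features
#' of the feature signal convolved with that channel's kernel, plus 1/f^a
#' coloured noise scaled per channel so the realized signal-to-noise variance
#' ratio equals `snr` exactly (channels whose kernels are all zero receive
#' unit-variance noise). `snr = Inf` gives the noiseless forward output.
#'
#' @param features a `feature_matrix` (or plain time x feature matrix with
#'   `fs` supplied).
#' @param kernels lag x feature x channel array (see [default_trf_kernels()]).
#' @param noise_exponent spectral exponent a of the 1/f^a noise (default 1).
#' @param snr signal/noise variance ratio (> 0, may be `Inf`).
#' @param seed integer seed.
#' @param fs sampling rate, required when `features` is a bare matrix.
#' @param noise_sd absolute noise standard deviation; when supplied it
#'   overrides `snr` (useful when several recordings must share one noise
#'   floor, e.g. across pieces of varying signal strength).
#' @return A `simulated_recording`: list with `data` (time x channel), `fs`,
#'   `true_kernels`, `snr`, `seed`.
#' @export
simulate_neural <- function(features, kernels, noise_exponent = 1, snr = Inf,
                            seed = 1L, fs = NULL, noise_sd = NULL) {
  if (inherits(features, "feature_matrix")) {
    fs <- features$fs
    x <- features$data
  } else {
    x <- as.matrix(features)
    if (is.null(fs)) stop("fs required for a bare feature matrix")
  }
  if (length(dim(kernels)) != 3L) stop("kernels must be a lag x feature x channel array")
  if (dim(kernels)[2L] != ncol(x)) {
    stop(sprintf("kernel feature count (%d) does not match features (%d)",
                 dim(kernels)[2L], ncol(x)))
  }
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  n <- nrow(x)
  n_ch <- dim(kernels)[3L]
  sig <- matrix(0, n, n_ch)
  for (ch in seq_len(n_ch)) {
    for (f in seq_len(ncol(x))) {
      k <- kernels[, f, ch]
      if (any(k != 0)) sig[, ch] <- sig[, ch] + fft_convolve(x[, f], k)
    }
  }
  data <- sig
  if (!is.null(noise_sd) || is.finite(snr)) {
    noise <- with_seed(seed, {
      vapply(seq_len(n_ch), function(ch) colored_noise(n, noise_exponent),
             numeric(n))
    })
    for (ch in seq_len(n_ch)) {
      scale <- if (!is.null(noise_sd)) noise_sd else {
        s_sd <- stats::sd(sig[, ch])
        if (s_sd > 0) s_sd / sqrt(snr) else 1
      }
      data[, ch] <- sig[, ch] + scale * noise[, ch]
    }
  }
  structure(list(data = data, fs = fs, true_kernels = kernels, snr = snr,
                 seed = seed,
                 channel_names = paste0("ch", seq_len(n_ch))),
            class = "simulated_recording")
}

#' Simulate a cohort of subjects listening to a shared set of melodies
#'
#' Generates `n_pieces` melodies from one Markov source, their envelopes and
#' analytic expectation features, then simulates per-subject multichannel
#' recordings (one per piece/trial) that share the stimuli but differ in
#' noise seed. Subjects are split into two equal groups; group 2's
#' expectation kernels are scaled by `expectation_gain` (1 = exchangeable
#' groups, 0 = no expectation signal, >1 models stronger expectation
#' encoding, as for trained musicians).
#'
#' @param spec a [markov_spec()].
#' @param n_subjects even number of subjects (>= 2).
#' @param n_pieces number of pieces = trials per subject.
#' @param notes_per_piece notes per melody.
#' @param fs neural sampling rate (Hz).
#' @param n_channels channels per recording.
#' @param snr per-channel signal/noise variance ratio; the default 0.2 sits
#'   at the optimistic end of low-rate EEG envelope tracking (prediction
#'   correlations around 0.3-0.4).
#' @param noise_exponent 1/f^a noise exponent.
#' @param expectation_gain multiplier on expectation kernels: a single value
#'   scales group 2 only (group 1 stays at 1, modelling a musician effect);
#'   a length-2 vector gives each group's gain explicitly (`c(0, 0)` builds
#'   a null cohort with no expectation signal anywhere).
#' @param base_seed integer; all piece and subject seeds derive from it.
#' @param drive `"true"` to drive expectation responses with the analytic
#'   [true_expectations()] (plain Markov sources), `"model"` to drive them
#'   with the unbounded LTM+STM estimates (needed for phrase-structured
#'   sources, where no analytic truth exists).
#' @param ltm optional list(pitch=, ioi=) LTM used when `drive = "model"`.
#' @return A `cohort`: list with `stimuli` (per piece: melody, envelope,
#'   series, features named by variant later), `subjects` (list of per-trial
#'   `simulated_recording`s), `group`, `kernels`.
#' @export
make_cohort <- function(spec, n_subjects = 20L, n_pieces = 10L,
                        notes_per_piece = 200L, fs = 64, n_channels = 4L,
                        snr = 0.2, noise_exponent = 1, expectation_gain = 1,
                        base_seed = 1L, drive = c("true", "model"),
                        ltm = NULL) {
  drive <- match.arg(drive)
  stopifnot(n_subjects >= 2L)
  feature_names <- c("Env", "Env'", "S_p", "H_p", "S_o", "H_o")
  gains <- if (length(expectation_gain) == 2L) expectation_gain else
    c(1, expectation_gain)
  kern1 <- default_trf_kernels(fs, feature_names, n_channels,
                               expectation_gain = gains[1L], seed = base_seed)
  kern2 <- default_trf_kernels(fs, feature_names, n_channels,
                               expectation_gain = gains[2L], seed = base_seed)
  stimuli <- lapply(seq_len(n_pieces), function(p) {
    mel <- generate_melody(spec, notes_per_piece, seed = base_seed + 1000L + p,
                           piece_id = sprintf("piece%02d", p))
    env <- synthesize_envelope(mel, fs)
    ser <- if (drive == "true") true_expectations(spec, mel) else {
      expectation_series(mel, ltm$pitch %||% spec, ltm$ioi %||% spec)
    }
    feats <- assemble_features("AM", env, ser, fs)
    list(melody = mel, envelope = env, series = ser, features = feats)
  })
  group <- rep(1:2, length.out = n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    kern <- if (group[s] == 1L) kern1 else kern2
    lapply(seq_len(n_pieces), function(p) {
      simulate_neural(stimuli[[p]]$features, kern,
                      noise_exponent = noise_exponent, snr = snr,
                      seed = base_seed + 100L * s + p)
    })
  })
  structure(list(stimuli = stimuli, subjects = subjects, group = group,
                 kernels = list(kern1, kern2), fs = fs, snr = snr,
                 spec = spec, base_seed = base_seed),
            class = "cohort")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat(sprintf("Simulated recording: %d samples x %d channels at %g Hz, snr = %g\n",
              nrow(x$data), ncol(x$data), x$fs, x$snr))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects (groups %s), %d pieces, fs = %g Hz, snr = %g\n",
              length(x$subjects), paste(table(x$group), collapse = "/"),
              length(x$stimuli), x$fs, x$snr))
  invisible(x)
}
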