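#' Synthesize an acoustic envelope from a melody
#'
#' Sums one attack-decay kernel per note: a linear attack over `attack_s`
#' followed by an exponential decay with time constant `decay_s` (piano-like).
#' Amplitudes are constant across notes unless per-note `gains` are supplied.
#' Overlapping notes superpose; the envelope is non-negative by construction.
#'
#' @param melody a `melody_sequence` (or data frame with `onset_s`).
#' @param fs output sampling rate in Hz.
#' @param attack_s,decay_s attack duration and decay time constant in seconds.
#' @param gains optional per-note amplitude vector.
#' @param duration_s optional total duration; defaults to last offset plus
#'   five decay constants.
#' @return Numeric envelope vector at `fs`.
#' @export
synthesize_envelope <- function(melody, fs, attack_s = 0.01, decay_s = 0.1,
                                gains = NULL, duration_s = NULL) {
  stopifnot(fs > 0, attack_s > 0, decay_s > 0)
  onsets <- melody$onset_s
  n_notes <- length(onsets)
  if (is.null(duration_s)) {
    last <- if (n_notes) max(onsets + (melody$duration_s %||% 0)) else 0
    duration_s <- last + 5 * decay_s
  }
  n <- ceiling(duration_s * fs)
  env <- numeric(n)
  if (n_notes == 0L) return(env)
  if (is.null(gains)) gains <- rep(1, n_notes)
  stopifnot(length(gains) == n_notes)
  # one shared kernel, shifted per note
  n_att <- max(1L, round(attack_s * fs))
  t_dec <- seq(0, 5 * decay_s, by = 1 / fs)
  kern <- c(seq(0, 1, length.out = n_att + 1L)[-1L], exp(-t_dec[-1L] / decay_s))
  for (j in seq_len(n_notes)) {
    i0 <- round(onsets[j] * fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    if (length(idx) > 0 && idx[1L] <= n) {
      env[idx] <- env[idx] + gains[j] * kern[seq_along(idx)]
    }
  }
  env
}

#' Broadband envelope of an audio waveform
#'
#' Magnitude of the analytic signal (Hilbert transform), low-pass filtered
#' below the output Nyquist and resampled to `fs_out`; clipped at zero.
#'
#' @param waveform numeric audio samples.
#' @param fs_audio input sampling rate (must exceed `2 * fs_out`).
#' @param fs_out output sampling rate.
#' @export
envelope_from_audio <- function(waveform, fs_audio, fs_out) {
  if (length(waveform) == 0L) stop("empty waveform")
  stopifnot(fs_audio > 2 * fs_out)
  env <- hilbert_envelope(waveform)
  pmax(resample_ts(env, fs_audio, fs_out), 0)
}

#' Half-wave rectified first derivative of an envelope
#'
#' `max(0, diff(envelope) * fs)`, same length as the input (first sample 0).
#'
#' @param envelope numeric envelope.
#' @param fs sampling rate in Hz.
#' @export
rectified_derivative <- function(envelope, fs) {
  pmax(c(0, diff(envelope) * fs), 0)
}

#' Note-onset impulse train modulated by an expectation feature
#'
#' Zeros everywhere except the sample nearest each note onset, which carries
#' that note's feature value (surprise or entropy in bits).
#'
#' @param series an `expectation_series`.
#' @param feature one of `"S_p"`, `"H_p"`, `"S_o"`, `"H_o"`.
#' @param fs sampling rate in Hz.
#' @param duration_s signal duration; all onsets must fall inside it.
#' @export
impulse_train <- function(series, feature = c("S_p", "H_p", "S_o", "H_o"),
                          fs, duration_s) {
  feature <- match.arg(feature)
  n <- ceiling(duration_s * fs)
  x <- numeric(n)
  if (nrow(series) == 0L) return(x)
  idx <- round(series$onset_s * fs) + 1L
  if (any(series$onset_s >= duration_s) || any(idx > n)) {
    stop("note onset beyond the requested duration")
  }
  if (anyDuplicated(idx)) stop("two notes collide on one sample")
  x[idx] <- series[[feature]]
  x
}

#' Assemble a time-by-feature regressor matrix
#'
#' Builds the stimulus descriptor variants used in the encoding analysis:
#' \describe{
#'   \item{A}{acoustics only: envelope `Env` and its half-wave rectified
#'     derivative `Env'` (2 columns).}
#'   \item{AM}{A plus the four expectation impulse trains
#'     `S_p, H_p, S_o, H_o` (6 columns, fixed order).}
#'   \item{AM_shu}{as AM but built from a time-shuffled series (pass the
#'     output of [shuffle_series()], or a `seed` to shuffle here).}
#'   \item{AM_p / AM_o}{A plus only the pitch / only the onset-time columns.}
#' }
#' Columns are returned raw; z-scoring with training-fold statistics happens
#' inside the fitting routines so that no test-fold information leaks.
#'
#' @param variant one of `"A"`, `"AM"`, `"AM_shu"`, `"AM_p"`, `"AM_o"`.
#' @param envelope numeric envelope at `fs`.
#' @param series an `expectation_series` (not needed for `"A"`).
#' @param fs sampling rate in Hz.
#' @param seed seed for the internal shuffle when `variant = "AM_shu"` and
#'   `series` is unshuffled.
#' @return A `feature_matrix`: list with `data` (time x feature), `fs`,
#'   `feature_names`, `piece_id`.
#' @export
assemble_features <- function(variant = c("A", "AM", "AM_shu", "AM_p", "AM_o"),
                              envelope, series = NULL, fs, seed = NULL) {
  variant <- match.arg(variant)
  duration_s <- length(envelope) / fs
  cols <- list(Env = envelope, `Env'` = rectified_derivative(envelope, fs))
  if (variant != "A") {
    if (is.null(series)) stop("expectation series required for variant ", variant)
    if (variant == "AM_shu" && !is.null(seed)) {
      series <- shuffle_series(series, seed)
    }
    want <- switch(variant,
                   AM = c("S_p", "H_p", "S_o", "H_o"),
                   AM_shu = c("S_p", "H_p", "S_o", "H_o"),
                   AM_p = c("S_p", "H_p"),
                   AM_o = c("S_o", "H_o"))
    for (f in want) cols[[f]] <- impulse_train(series, f, fs, duration_s)
  }
  data <- do.call(cbind, cols)
  colnames(data) <- names(cols)
  structure(list(data = data, fs = fs, feature_names = names(cols),
                 variant = variant,
                 piece_id = if (!is.null(series)) series$piece_id[1L] else NA),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix [%s]: %d samples x %d features at %g Hz (%s)\n",
              x$variant, nrow(x$data), ncol(x$data), x$fs,
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}
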