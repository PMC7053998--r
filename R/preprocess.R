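#' Neural recording container
#'
#' Light wrapper for a time x channel matrix with sampling rate and channel
#' metadata; all preprocessing operations are pure (they return a new
#' recording and append a provenance log entry).
#'
#' @param data time x channel numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names optional channel names.
#' @param modality `"raw"`, `"low-rate"` or `"high-gamma"`.
#' @export
neural_recording <- function(data, fs, channel_names = NULL,
                             modality = "raw") {
  data <- as.matrix(data)
  if (is.null(channel_names)) {
    channel_names <- colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  }
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 channel_kinds = rep("scalp", ncol(data)),
                 modality = modality, log = character(0)),
            class = "neural_recording")
}

as_recording <- function(x, fs = NULL) {
  if (inherits(x, "neural_recording")) return(x)
  if (inherits(x, "simulated_recording")) {
    return(neural_recording(x$data, x$fs, x$channel_names))
  }
  neural_recording(x, fs)
}

log_step <- function(rec, msg) {
  rec$log <- c(rec$log, msg)
  rec
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("Neural recording (%s): %d samples x %d channels at %g Hz\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs))
  if (length(x$log)) cat("  processing:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' Low-rate band-pass filtering (1-8 Hz, zero-phase)
#'
#' Order-2 Butterworth high-pass at `lo` followed by order-2 low-pass at
#' `hi`, both applied forward-backward (zero phase), then optional
#' downsampling. This isolates the low-rate band in which envelope tracking
#' and expectation responses are analysed.
#'
#' @param rec a [neural_recording()] (or `simulated_recording`/matrix).
#' @param lo,hi band edges in Hz.
#' @param downsample_to optional output rate in Hz.
#' @param fs sampling rate when `rec` is a bare matrix.
#' @export
bandpass_lowrate <- function(rec, lo = 1, hi = 8, downsample_to = NULL,
                             fs = NULL) {
  rec <- as_recording(rec, fs)
  if (hi >= rec$fs / 2) stop("upper band edge must be below Nyquist")
  d <- butter_filtfilt(rec$data, rec$fs, lo, "high", order = 2L)
  d <- butter_filtfilt(d, rec$fs, hi, "low", order = 2L)
  out_fs <- rec$fs
  if (!is.null(downsample_to) && downsample_to < rec$fs) {
    d <- resample_ts(d, rec$fs, downsample_to)
    out_fs <- downsample_to
  }
  out <- neural_recording(d, out_fs, rec$channel_names, modality = "low-rate")
  out$channel_kinds <- rec$channel_kinds
  log_step(out, sprintf("bandpass %g-%g Hz%s", lo, hi,
                        if (out_fs != rec$fs) sprintf(", ds to %g Hz", out_fs) else ""))
}

#' High-gamma power extraction
#'
#' Band-pass (default 70-150 Hz, zero-phase Butterworth order 3), analytic
#' signal magnitude (Hilbert transform), then anti-alias low-pass and
#' resampling to `fs_out` (default 100 Hz). The result tracks the local
#' high-frequency power envelope, a proxy for local neuronal activity in
#' intracranial recordings.
#'
#' @inheritParams bandpass_lowrate
#' @param band two-element band in Hz.
#' @param fs_out output sampling rate.
#' @export
highgamma_power <- function(rec, band = c(70, 150), fs_out = 100, fs = NULL) {
  rec <- as_recording(rec, fs)
  if (rec$fs <= 2 * band[2L]) stop("sampling rate too low for the requested band")
  d <- butter_filtfilt(rec$data, rec$fs, band, "pass", order = 3L)
  d <- apply(d, 2L, hilbert_envelope)
  d <- resample_ts(d, rec$fs, fs_out)
  out <- neural_recording(d, fs_out, rec$channel_names, modality = "high-gamma")
  out$channel_kinds <- rec$channel_kinds
  log_step(out, sprintf("high-gamma %g-%g Hz power at %g Hz", band[1L], band[2L], fs_out))
}

#' Detect and repair outlier channels
#'
#' Flags channels whose variance exceeds `factor` times the median variance
#' of their `k` nearest neighbours (by sensor coordinates) and replaces them
#' by the mean of those neighbours (a deliberate simplification of spline
#' interpolation; the downstream statistics do not depend on the
#' interpolation method). Aborts if more than a quarter of channels are bad.
#'
#' @param rec a [neural_recording()].
#' @param coords channel x 2 (or 3) coordinate matrix.
#' @param k number of nearest neighbours.
#' @param factor variance ratio threshold.
#' @return The repaired recording; attribute `"repair_report"` lists repaired
#'   channels.
#' @export
detect_and_repair_channels <- function(rec, coords, k = 4L, factor = 3) {
  rec <- as_recording(rec)
  coords <- as.matrix(coords)
  n_ch <- ncol(rec$data)
  stopifnot(nrow(coords) == n_ch)
  dd <- as.matrix(stats::dist(coords))
  v <- apply(rec$data, 2L, stats::var)
  neighbours <- lapply(seq_len(n_ch), function(ch) {
    order(dd[ch, ])[2:(k + 1L)]
  })
  bad <- vapply(seq_len(n_ch), function(ch) {
    v[ch] > factor * stats::median(v[neighbours[[ch]]])
  }, logical(1))
  if (mean(bad) > 0.25) {
    stop(sprintf("%d/%d channels flagged bad (> 25%%); aborting repair",
                 sum(bad), n_ch))
  }
  out <- rec
  for (ch in which(bad)) {
    good_nb <- setdiff(neighbours[[ch]], which(bad))
    if (length(good_nb) == 0L) good_nb <- neighbours[[ch]]
    out$data[, ch] <- rowMeans(rec$data[, good_nb, drop = FALSE])
  }
  out <- log_step(out, sprintf("repaired %d channel(s)", sum(bad)))
  attr(out, "repair_report") <- rec$channel_names[bad]
  out
}

#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the two named mastoid channels from every channel;
#' mastoids are retained and flagged as reference channels. Idempotent (the
#' mastoid average is zero after one application).
#'
#' @param rec a [neural_recording()].
#' @param mastoid_channels length-2 character vector of channel names.
#' @export
rereference_mastoids <- function(rec, mastoid_channels) {
  rec <- as_recording(rec)
  idx <- match(mastoid_channels, rec$channel_names)
  if (anyNA(idx)) {
    stop("mastoid channel(s) not found: ",
         paste(mastoid_channels[is.na(idx)], collapse = ", "))
  }
  ref <- rowMeans(rec$data[, idx, drop = FALSE])
  out <- rec
  out$data <- rec$data - ref
  out$channel_kinds[idx] <- "reference"
  log_step(out, "re-referenced to mastoid average")
}

#' Select music-responsive electrodes
#'
#' Compares chunk-wise response magnitudes (RMS over `chunk_ms` windows,
#' `n_chunks` per condition) between a music recording and a silence
#' recording, channel by channel, using Cohen's d; channels with
#' `d > d_threshold` (medium effect) are marked responsive.
#'
#' @param rec_music,rec_silence recordings sharing `fs` and channels.
#' @param chunk_ms chunk duration in ms.
#' @param n_chunks chunks per condition.
#' @param d_threshold effect-size threshold.
#' @param seed seed for the random chunk placement.
#' @return List with `selected` (channel names), `d` (per-channel effect
#'   sizes).
#' @export
select_responsive_electrodes <- function(rec_music, rec_silence,
                                         chunk_ms = 200, n_chunks = 25L,
                                         d_threshold = 0.5, seed = 1L) {
  m <- as_recording(rec_music); s <- as_recording(rec_silence)
  stopifnot(m$fs == s$fs, ncol(m$data) == ncol(s$data))
  len <- round(chunk_ms / 1000 * m$fs)
  pick_chunks <- function(x, sub_seed) {
    n_pos <- nrow(x) - len + 1L
    if (n_pos < n_chunks) stop("recording too short for the requested chunks")
    starts <- with_seed(sub_seed, sample.int(n_pos, n_chunks))
    out <- vapply(starts, function(s0) {
      sqrt(colMeans(x[s0:(s0 + len - 1L), , drop = FALSE]^2))
    }, numeric(ncol(x)))  # channels x chunks
    if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
    out
  }
  rms_m <- pick_chunks(m$data, seed)
  rms_s <- pick_chunks(s$data, seed + 1L)
  d <- vapply(seq_len(ncol(m$data)), function(ch) {
    cohens_d(rms_m[ch, ], rms_s[ch, ])
  }, numeric(1))
  list(selected = m$channel_names[d > d_threshold], d = stats::setNames(d, m$channel_names))
}
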