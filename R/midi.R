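# Minimal standard-MIDI (format 0) I/O for monophonic melodies. Only the
# events this package produces are supported: set-tempo, time-signature,
# note-on/note-off on one channel. No installed package provides MIDI I/O,
# so the byte-level format is handled here directly.

TPQ <- 480L  # ticks per quarter note

int_be <- function(x, n_bytes) {
  as.raw(sapply(rev(seq_len(n_bytes)) - 1L, function(i) (x %/% 256^i) %% 256))
}

varlen_encode <- function(x) {
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

#' Write a melody as a standard MIDI file (format 0)
#'
#' Single track, one channel: a time-signature and set-tempo event followed
#' by note-on/note-off pairs. Onsets and durations are quantized to the MIDI
#' tick (480 ticks per quarter note), which is exact for IOI alphabets built
#' on regular note values.
#'
#' @param melody a `melody_sequence`.
#' @param path output file path.
#' @param tempo_bpm tempo in beats per minute (defaults to the melody's bar
#'   duration assuming 4 beats per bar).
#' @param beats_per_bar meter numerator.
#' @param velocity note-on velocity.
#' @return `path`, invisibly.
#' @export
midi_write <- function(melody, path, tempo_bpm = NULL, beats_per_bar = 4L,
                       velocity = 80L) {
  bar_s <- attr(melody, "bar_duration_s") %||% 2.4
  if (is.null(tempo_bpm)) tempo_bpm <- beats_per_bar * 60 / bar_s
  us_per_quarter <- round(60e6 / tempo_bpm)
  ticks_per_sec <- TPQ * tempo_bpm / 60

  on_ticks <- round(melody$onset_s * ticks_per_sec)
  off_ticks <- round((melody$onset_s + melody$duration_s) * ticks_per_sec)
  off_ticks <- pmax(off_ticks, on_ticks + 1L)
  ev <- rbind(
    data.frame(tick = on_ticks, prio = 1L, status = 0x90, p1 = melody$pitch,
               p2 = velocity),
    data.frame(tick = off_ticks, prio = 0L, status = 0x80, p1 = melody$pitch,
               p2 = 0L)
  )
  ev <- ev[order(ev$tick, ev$prio), ]

  trk <- c(
    varlen_encode(0L), as.raw(c(0xFF, 0x58, 0x04, beats_per_bar, 2L, 24L, 8L)),
    varlen_encode(0L), as.raw(c(0xFF, 0x51, 0x03)), int_be(us_per_quarter, 3L)
  )
  last <- 0L
  for (i in seq_len(nrow(ev))) {
    trk <- c(trk, varlen_encode(ev$tick[i] - last),
             as.raw(c(ev$status[i], ev$p1[i], ev$p2[i])))
    last <- ev$tick[i]
  }
  trk <- c(trk, varlen_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), int_be(6L, 4L), int_be(0L, 2L), int_be(1L, 2L),
             int_be(TPQ, 2L),
             charToRaw("MTrk"), int_be(length(trk), 4L), trk), con)
  invisible(path)
}

varlen_decode <- function(bytes, pos) {
  val <- 0L
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128L + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

#' Parse a monophonic standard MIDI file
#'
#' Reads a format-0 (or single-melody format-1) MIDI file into a
#' `melody_sequence`: note on/off events are paired, onsets converted to
#' seconds through the tempo map, and bar indices assigned from the time
#' signature. Overlapping notes (polyphony) are an error; a missing tempo
#' falls back to 120 bpm with a warning.
#'
#' @param path MIDI file path.
#' @param ioi_alphabet optional IOI durations (seconds); when supplied, each
#'   note's inter-onset interval is mapped to the nearest alphabet class so
#'   the melody round-trips exactly.
#' @param pitch_alphabet optional pitch alphabet (MIDI numbers) used to
#'   assign `pitch_sym` indices; defaults to the sorted pitches present.
#' @param piece_id label for the resulting melody.
#' @return A `melody_sequence`.
#' @export
midi_read <- function(path, ioi_alphabet = NULL, pitch_alphabet = NULL,
                      piece_id = NULL) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(bytes[1:4]) != "MThd") stop("not a standard MIDI file")
  be <- function(idx) sum(as.integer(bytes[idx]) * 256^(rev(seq_along(idx)) - 1L))
  division <- be(13:14)
  if (division >= 32768L) stop("SMPTE time division not supported")
  n_tracks <- be(11:12)

  notes <- data.frame(tick_on = integer(0), tick_off = integer(0),
                      pitch = integer(0))
  tempo_events <- data.frame(tick = 0L, us_per_quarter = NA_real_)
  timesig <- c(num = 4L, denom_pow = 2L)
  pos <- 15L
  for (trk in seq_len(n_tracks)) {
    if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") stop("malformed track header")
    trk_len <- be((pos + 4L):(pos + 7L))
    pos <- pos + 8L
    end <- pos + trk_len
    tick <- 0L
    running <- NA_integer_
    active <- NULL  # currently sounding note: list(pitch, tick)
    while (pos < end) {
      d <- varlen_decode(bytes, pos); pos <- d$pos
      tick <- tick + d$value
      b <- as.integer(bytes[pos])
      if (b >= 0x80) { running <- b; pos <- pos + 1L } else b <- running
      hi <- b %/% 16L
      if (b == 0xFF) {
        type <- as.integer(bytes[pos]); pos <- pos + 1L
        l <- varlen_decode(bytes, pos); pos <- l$pos
        dat <- bytes[seq(pos, length.out = l$value)]
        pos <- pos + l$value
        if (type == 0x51) {
          tempo_events <- rbind(tempo_events,
                                data.frame(tick = tick,
                                           us_per_quarter = sum(as.integer(dat) *
                                                                  256^(2:0))))
        } else if (type == 0x58) {
          timesig <- c(num = as.integer(dat[1L]),
                       denom_pow = as.integer(dat[2L]))
        }
      } else if (b %in% c(0xF0, 0xF7)) {
        l <- varlen_decode(bytes, pos); pos <- l$pos
        pos <- pos + l$value
      } else if (hi == 0x9 || hi == 0x8) {
        pitch <- as.integer(bytes[pos]); vel <- as.integer(bytes[pos + 1L])
        pos <- pos + 2L
        is_on <- hi == 0x9 && vel > 0L
        if (is_on) {
          if (!is.null(active)) {
            stop(sprintf("polyphony: note %d starts at tick %d while note %d (tick %d) still sounds",
                         pitch, tick, active$pitch, active$tick))
          }
          active <- list(pitch = pitch, tick = tick)
        } else {
          if (is.null(active) || active$pitch != pitch) {
            stop(sprintf("unmatched note-off for pitch %d at tick %d", pitch, tick))
          }
          notes <- rbind(notes, data.frame(tick_on = active$tick,
                                           tick_off = tick, pitch = pitch))
          active <- NULL
        }
      } else if (hi %in% c(0xA, 0xB, 0xE)) {
        pos <- pos + 2L
      } else if (hi %in% c(0xC, 0xD)) {
        pos <- pos + 1L
      } else stop(sprintf("unsupported MIDI status byte 0x%X", b))
    }
  }
  if (nrow(notes) == 0L) stop("no notes found")
  tempo_events <- tempo_events[!is.na(tempo_events$us_per_quarter), , drop = FALSE]
  if (nrow(tempo_events) == 0L) {
    warning("no tempo event; assuming 120 bpm")
    tempo_events <- data.frame(tick = 0L, us_per_quarter = 500000)
  }
  tempo_events <- tempo_events[order(tempo_events$tick), , drop = FALSE]

  if (tempo_events$tick[1L] > 0L) {
    tempo_events <- rbind(data.frame(tick = 0L, us_per_quarter = 500000),
                          tempo_events)
  }
  # cumulative seconds at the start of each tempo segment
  seg_sec <- cumsum(c(0, diff(tempo_events$tick) *
                        utils::head(tempo_events$us_per_quarter, -1L) /
                        (division * 1e6)))
  tick_to_sec <- function(ticks) {
    vapply(ticks, function(tk) {
      i <- max(which(tempo_events$tick <= tk))
      seg_sec[i] + (tk - tempo_events$tick[i]) *
        tempo_events$us_per_quarter[i] / (division * 1e6)
    }, numeric(1))
  }

  notes <- notes[order(notes$tick_on), , drop = FALSE]
  onset_s <- tick_to_sec(notes$tick_on)
  offset_s <- tick_to_sec(notes$tick_off)
  quarter_s <- tempo_events$us_per_quarter[1L] / 1e6
  bar_quarters <- timesig["num"] * 4 / 2^timesig["denom_pow"]
  bar_s <- unname(bar_quarters * quarter_s)

  ioi <- c(NA_real_, diff(onset_s))
  ioi_class <- if (!is.null(ioi_alphabet)) {
    cl <- vapply(ioi, function(v) {
      if (is.na(v)) NA_integer_ else which.min(abs(ioi_alphabet - v))
    }, integer(1))
    cl
  } else {
    u <- sort(unique(ioi[!is.na(ioi)]))
    match(ioi, u)
  }
  structure(data.frame(
    onset_s = onset_s,
    duration_s = offset_s - onset_s,
    pitch = notes$pitch,
    pitch_sym = match(notes$pitch,
                      pitch_alphabet %||% sort(unique(notes$pitch))),
    ioi_class = ioi_class,
    bar_index = as.integer(floor(onset_s / bar_s + 1e-9)),
    from_repeat = FALSE
  ), class = c("melody_sequence", "data.frame"),
  bar_duration_s = bar_s,
  piece_id = piece_id %||% sub("\\.midi?$", "", basename(path)),
  spec_order = NA_integer_)
}
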