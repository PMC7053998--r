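#' Markov melody generator specification
#'
#' Defines a known stochastic source of monophonic melodies: a finite pitch
#' alphabet, a quantized inter-onset-interval (IOI) alphabet with durations in
#' seconds, and conditional transition tables for both viewpoints. Because the
#' source is known, every downstream stage (expectation estimation, TRF
#' fitting, ERP analysis) has an analytic oracle via [true_expectations()].
#'
#' Transition tables are named lists mapping a context key (symbols joined by
#' ",", `"."` for the empty context) to a probability vector over the alphabet.
#' Every context of length `0..order` that can occur must be present.
#'
#' Optional phrase-level structure: with `phrase_repeat_prob > 0`, melodies are
#' built phrase by phrase (each phrase spans `bars_per_phrase` bars) and a new
#' phrase repeats an earlier one verbatim with that probability. This injects
#' long-range (cross-bar) dependencies that a short-memory predictor cannot
#' exploit, which is what the memory-restriction control measures.
#'
#' @param pitch_alphabet integer vector of MIDI pitches.
#' @param ioi_alphabet numeric vector of IOI durations in seconds (class k has
#'   duration `ioi_alphabet[k]`).
#' @param pitch_transitions,ioi_transitions named lists of probability vectors
#'   (see Details). If `NULL`, near-uniform tables are built.
#' @param order non-negative integer Markov order of the generator.
#' @param tempo_bpm,beats_per_bar tempo and meter fixing the bar duration
#'   (default 100 bpm, 4/4, so one bar lasts 2.4 s).
#' @param bars_per_phrase bars per phrase for the long-range structure.
#' @param phrase_repeat_prob probability that a new phrase repeats an earlier
#'   phrase verbatim (0 = plain Markov source).
#' @return An object of class `markov_spec`.
#' @seealso [generate_melody()], [true_expectations()], [random_markov_spec()]
#' @export
markov_spec <- function(pitch_alphabet, ioi_alphabet,
                        pitch_transitions = NULL, ioi_transitions = NULL,
                        order = 1L, tempo_bpm = 100, beats_per_bar = 4,
                        bars_per_phrase = 2L, phrase_repeat_prob = 0) {
  pitch_alphabet <- as.integer(pitch_alphabet)
  ioi_alphabet <- as.numeric(ioi_alphabet)
  stopifnot(length(pitch_alphabet) >= 1L, length(ioi_alphabet) >= 1L,
            all(ioi_alphabet > 0), order >= 0L, tempo_bpm > 0,
            phrase_repeat_prob >= 0, phrase_repeat_prob <= 1)
  if (is.null(pitch_transitions)) {
    pitch_transitions <- uniform_transitions(length(pitch_alphabet), order)
  }
  if (is.null(ioi_transitions)) {
    ioi_transitions <- uniform_transitions(length(ioi_alphabet), order)
  }
  spec <- structure(list(
    pitch_alphabet = pitch_alphabet,
    ioi_alphabet = ioi_alphabet,
    pitch_transitions = pitch_transitions,
    ioi_transitions = ioi_transitions,
    order = as.integer(order),
    tempo_bpm = tempo_bpm,
    beats_per_bar = beats_per_bar,
    bar_duration_s = beats_per_bar * 60 / tempo_bpm,
    bars_per_phrase = as.integer(bars_per_phrase),
    phrase_repeat_prob = phrase_repeat_prob
  ), class = "markov_spec")
  validate_markov_spec(spec)
  spec
}

uniform_transitions <- function(k, order) {
  out <- list()
  contexts <- list(character(0))
  for (len in 0:order) {
    keys <- if (len == 0L) "." else {
      grid <- do.call(expand.grid, rep(list(seq_len(k)), len))
      apply(grid, 1L, paste, collapse = ",")
    }
    for (key in keys) out[[key]] <- rep(1 / k, k)
  }
  out
}

validate_markov_spec <- function(spec) {
  check_table <- function(tab, k, what) {
    if (!("." %in% names(tab))) {
      stop(sprintf("%s transitions lack an empty-context row", what))
    }
    for (key in names(tab)) {
      row <- tab[[key]]
      if (length(row) != k) {
        stop(sprintf("%s row '%s' has length %d, expected %d",
                     what, key, length(row), k))
      }
      if (any(row < 0)) {
        stop(sprintf("%s row '%s' has negative entries", what, key))
      }
      if (abs(sum(row) - 1) > 1e-12) {
        stop(sprintf("%s row '%s' does not sum to 1 (sum = %.15g)",
                     what, key, sum(row)))
      }
      n_ctx <- if (identical(key, ".")) 0L else
        length(strsplit(key, ",", fixed = TRUE)[[1L]])
      if (n_ctx > spec$order) {
        stop(sprintf("%s context '%s' longer than order %d",
                     what, key, spec$order))
      }
    }
  }
  check_table(spec$pitch_transitions, length(spec$pitch_alphabet), "pitch")
  check_table(spec$ioi_transitions, length(spec$ioi_alphabet), "ioi")
  invisible(spec)
}

#' Draw a random (but reproducible) Markov melody source
#'
#' Convenience constructor drawing Dirichlet transition rows, used throughout
#' the simulation studies. `concentration < 1` gives peaked, structured rows
#' (low-entropy transitions); large values approach uniform.
#'
#' @inheritParams markov_spec
#' @param n_pitch number of pitches (chromatic run starting at MIDI 60).
#' @param ioi_alphabet IOI durations in seconds; the defaults are eighth,
#'   quarter and half notes at 100 bpm, all exact multiples of the MIDI tick.
#' @param concentration Dirichlet concentration for transition rows. A
#'   length-2 vector gives a (log-uniform) range sampled per row, so some
#'   contexts are nearly deterministic and others nearly uniform - melodies
#'   then span a wide range of entropies, as real music does.
#' @param seed integer seed.
#' @return A `markov_spec`.
#' @export
random_markov_spec <- function(n_pitch = 8L, ioi_alphabet = c(0.3, 0.6, 1.2),
                               order = 1L, concentration = c(0.05, 5),
                               seed = 1L,
                               tempo_bpm = 100, beats_per_bar = 4,
                               bars_per_phrase = 2L, phrase_repeat_prob = 0) {
  rdirichlet_row <- function(k) {
    conc <- if (length(concentration) == 2L) {
      exp(stats::runif(1, log(concentration[1L]), log(concentration[2L])))
    } else concentration
    g <- stats::rgamma(k, shape = conc)
    if (sum(g) == 0) g <- rep(1, k)
    g / sum(g)
  }
  with_seed(seed, {
    pt <- uniform_transitions(n_pitch, order)
    for (key in names(pt)) pt[[key]] <- rdirichlet_row(n_pitch)
    it <- uniform_transitions(length(ioi_alphabet), order)
    for (key in names(it)) it[[key]] <- rdirichlet_row(length(ioi_alphabet))
    markov_spec(seq(60L, length.out = n_pitch), ioi_alphabet,
                pitch_transitions = pt, ioi_transitions = it, order = order,
                tempo_bpm = tempo_bpm, beats_per_bar = beats_per_bar,
                bars_per_phrase = bars_per_phrase,
                phrase_repeat_prob = phrase_repeat_prob)
  })
}

ctx_key <- function(ctx) if (length(ctx) == 0L) "." else paste(ctx, collapse = ",")

# Conditional distribution of the generator for a context of symbol indices.
spec_row <- function(tab, ctx, order) {
  if (length(ctx) > order) {
    ctx <- if (order == 0L) integer(0) else
      ctx[(length(ctx) - order + 1L):length(ctx)]
  }
  key <- ctx_key(ctx)
  row <- tab[[key]]
  if (is.null(row)) stop(sprintf("no transition row for context '%s'", key))
  row
}

#' Generate a melody from a Markov source
#'
#' Samples `n_notes` note events (pitch and IOI symbol per note) from the
#' generator's conditional tables, assigning onsets from cumulative IOIs and
#' bar indices from the spec's bar duration. The first note starts at 0 s and
#' carries the designated initial IOI class (`NA`), since no preceding
#' interval exists. Deterministic given `seed`.
#'
#' @param spec a [markov_spec()].
#' @param n_notes number of notes (>= 1).
#' @param seed integer seed.
#' @param piece_id label attached to the melody.
#' @return A `melody_sequence`: data frame with columns `onset_s`,
#'   `duration_s`, `pitch`, `pitch_sym` (alphabet index), `ioi_class`,
#'   `bar_index`, plus attributes `bar_duration_s`, `piece_id`, `spec_order`.
#' @export
generate_melody <- function(spec, n_notes, seed, piece_id = "piece1") {
  stopifnot(inherits(spec, "markov_spec"), n_notes >= 1L)
  validate_markov_spec(spec)
  n_pitch <- length(spec$pitch_alphabet)
  n_ioi <- length(spec$ioi_alphabet)
  bar_s <- spec$bar_duration_s
  # phrase length in notes: spans bars_per_phrase bars at the mean note rate
  phrase_len <- max(4L, round(spec$bars_per_phrase * bar_s /
                                mean(spec$ioi_alphabet)))

  with_seed(seed, {
    pitch_sym <- integer(n_notes)
    ioi_sym <- integer(n_notes)      # ioi_sym[i] = class of onset[i]-onset[i-1]
    from_repeat <- logical(n_notes)
    phrases <- list()                # completed phrases as symbol blocks
    repeating <- NULL

    for (i in seq_len(n_notes)) {
      pos_in_phrase <- (i - 1L) %% phrase_len + 1L
      if (pos_in_phrase == 1L) {
        if (i > 1L) {
          blk <- (i - phrase_len):(i - 1L)
          phrases[[length(phrases) + 1L]] <-
            list(pitch = pitch_sym[blk], ioi = ioi_sym[blk])
        }
        repeating <- NULL
        if (spec$phrase_repeat_prob > 0 && length(phrases) > 0L &&
            stats::runif(1) < spec$phrase_repeat_prob) {
          repeating <- phrases[[sample.int(length(phrases), 1L)]]
        }
      }
      if (!is.null(repeating)) {
        pitch_sym[i] <- repeating$pitch[pos_in_phrase]
        ioi_sym[i] <- if (i == 1L) NA_integer_ else {
          v <- repeating$ioi[pos_in_phrase]
          if (is.na(v)) 1L else v
        }
        from_repeat[i] <- TRUE
      } else {
        p_ctx <- pitch_sym[seq_len(i - 1L)]
        p_row <- spec_row(spec$pitch_transitions, p_ctx, spec$order)
        pitch_sym[i] <- sample.int(n_pitch, 1L, prob = p_row)
        if (i == 1L) {
          ioi_sym[i] <- NA_integer_
        } else {
          i_ctx <- ioi_sym[seq_len(i - 1L)]
          i_ctx <- i_ctx[!is.na(i_ctx)]
          i_row <- spec_row(spec$ioi_transitions, i_ctx, spec$order)
          ioi_sym[i] <- sample.int(n_ioi, 1L, prob = i_row)
        }
      }
    }

    ioi_s <- c(0, spec$ioi_alphabet[ioi_sym[-1L]])
    onsets <- cumsum(ioi_s)
    # duration: hold until next onset (legato), last note one mean IOI
    durations <- c(diff(onsets), mean(spec$ioi_alphabet))
    durations[durations <= 0] <- min(spec$ioi_alphabet)
    mel <- data.frame(
      onset_s = onsets,
      duration_s = durations,
      pitch = spec$pitch_alphabet[pitch_sym],
      pitch_sym = pitch_sym,
      ioi_class = ioi_sym,
      bar_index = as.integer(floor(onsets / bar_s + 1e-9)),
      from_repeat = from_repeat
    )
    structure(mel, class = c("melody_sequence", "data.frame"),
              bar_duration_s = bar_s, piece_id = piece_id,
              spec_order = spec$order)
  })
}

#' Analytic per-note surprise and entropy under the generating source
#'
#' Computes, for every note of a melody generated by [generate_melody()], the
#' true surprise `S = -log2 p(e_i | context)` and Shannon entropy of the
#' generator's conditional distribution, in bits, for both the pitch and the
#' IOI (onset-time) viewpoints. These are ground truth, not estimates. The
#' first note's onset-time values are set to 0 (no preceding interval; the
#' initial IOI class is excluded from evaluation by convention).
#'
#' For phrase-repeating sources the values still reflect the local Markov
#' tables (the repetition mechanism is deliberately not conditioned on), so
#' they are exact only when `phrase_repeat_prob == 0`.
#'
#' @param spec the generating [markov_spec()].
#' @param melody a `melody_sequence` drawn from `spec`.
#' @return An `expectation_series` data frame: `piece_id`, `note_index`,
#'   `onset_s`, `S_p`, `H_p`, `S_o`, `H_o`.
#' @export
true_expectations <- function(spec, melody) {
  stopifnot(inherits(spec, "markov_spec"), inherits(melody, "melody_sequence"))
  n <- nrow(melody)
  if (any(!melody$pitch %in% spec$pitch_alphabet)) {
    stop("melody contains pitches outside the spec alphabet")
  }
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (n > 1L && any(is.na(melody$ioi_class[-1L]))) {
    stop("melody contains IOI classes outside the spec alphabet")
  }
  S_p <- H_p <- S_o <- H_o <- numeric(n)
  for (i in seq_len(n)) {
    p_ctx <- melody$pitch_sym[seq_len(i - 1L)]
    p_row <- spec_row(spec$pitch_transitions, p_ctx, spec$order)
    S_p[i] <- -log2(max(p_row[melody$pitch_sym[i]], 1e-300))
    H_p[i] <- ent(p_row)
    if (i == 1L) {
      S_o[i] <- 0; H_o[i] <- 0
    } else {
      i_ctx <- melody$ioi_class[seq_len(i - 1L)]
      i_ctx <- i_ctx[!is.na(i_ctx)]
      i_row <- spec_row(spec$ioi_transitions, i_ctx, spec$order)
      S_o[i] <- -log2(max(i_row[melody$ioi_class[i]], 1e-300))
      H_o[i] <- ent(i_row)
    }
  }
  expectation_series_df(attr(melody, "piece_id"), melody$onset_s,
                        S_p, H_p, S_o, H_o)
}

expectation_series_df <- function(piece_id, onset_s, S_p, H_p, S_o, H_o) {
  structure(data.frame(
    piece_id = piece_id %||% "piece1",
    note_index = seq_along(onset_s),
    onset_s = onset_s,
    S_p = S_p, H_p = H_p, S_o = S_o, H_o = H_o
  ), class = c("expectation_series", "data.frame"))
}

#' @export
print.melody_sequence <- function(x, ...) {
  cat(sprintf("Melody '%s': %d notes, %.1f s, %d pitches, bar = %.2f s\n",
              attr(x, "piece_id"), nrow(x),
              max(x$onset_s + x$duration_s), length(unique(x$pitch)),
              attr(x, "bar_duration_s")))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more notes\n", nrow(x) - 5L))
  invisible(x)
}
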