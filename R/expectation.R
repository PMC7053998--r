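#' Per-note surprise and entropy of pitch and onset-time
#'
#' Estimates the four melodic-expectation features (S_p, H_p, S_o, H_o, in
#' bits) for every note of a melody, combining a pre-trained long-term model
#' (LTM; schematic knowledge from a held-out corpus) with a short-term model
#' (STM) trained online on the current piece only. Prediction is strictly
#' causal: the STM is updated with a note only after that note has been
#' predicted.
#'
#' The LTM for each viewpoint may be either an [ngram_model()] or a
#' [markov_spec()]; the latter predicts from the exact generator tables, which
#' is how simulated ground truth is recovered (with `stm = FALSE`, the output
#' equals [true_expectations()]).
#'
#' `memory_bars` implements the memory-restriction control: the piece is cut
#' into chunks of that many musical bars and the STM is rebuilt from scratch
#' at every chunk boundary, leaving the LTM untouched. `Inf` reproduces the
#' unrestricted analysis exactly.
#'
#' @param melody a `melody_sequence`.
#' @param ltm_pitch,ltm_ioi long-term models (see Details); `NULL` for a
#'   uniform (empty) LTM.
#' @param stm logical: include the online short-term model?
#' @param stm_max_order maximum STM context length in notes.
#' @param memory_bars STM memory in bars: one of 1, 2, 4, 8, 16, 32, `Inf`.
#' @return An `expectation_series` data frame with columns `piece_id`,
#'   `note_index`, `onset_s`, `S_p`, `H_p`, `S_o`, `H_o`. The first note's
#'   onset-time values are 0 by convention (no preceding interval).
#' @export
expectation_series <- function(melody, ltm_pitch = NULL, ltm_ioi = NULL,
                               stm = TRUE, stm_max_order = Inf,
                               memory_bars = Inf) {
  stopifnot(inherits(melody, "melody_sequence"))
  if (!memory_bars %in% c(1, 2, 4, 16, 8, 32, Inf)) {
    stop("memory_bars must be one of 1, 2, 4, 8, 16, 32, Inf")
  }
  n <- nrow(melody)
  chunk <- if (is.finite(memory_bars)) {
    melody$bar_index %/% memory_bars
  } else rep(0L, n)

  n_pitch_alpha <- ltm_alphabet_size(ltm_pitch, "pitch", melody$pitch_sym)
  ioi_obs <- melody$ioi_class
  n_ioi_alpha <- ltm_alphabet_size(ltm_ioi, "ioi", ioi_obs[!is.na(ioi_obs)])

  S_p <- H_p <- S_o <- H_o <- numeric(n)
  stm_p <- stm_o <- NULL
  cur_chunk <- -1L

  for (i in seq_len(n)) {
    if (chunk[i] != cur_chunk) {
      cur_chunk <- chunk[i]
      if (isTRUE(stm)) {
        stm_p <- ngram_model(alphabet = seq_len(n_pitch_alpha),
                             max_order = stm_max_order, role = "stm")
        stm_o <- ngram_model(alphabet = seq_len(n_ioi_alpha),
                             max_order = stm_max_order, role = "stm")
      }
      chunk_start <- i
    }
    # --- pitch viewpoint ---
    ctx_full <- melody$pitch_sym[seq_len(i - 1L)]
    ctx_chunk <- melody$pitch_sym[seq(chunk_start, length.out = i - chunk_start)]
    d_ltm <- ltm_predict(ltm_pitch, "pitch", ctx_full, n_pitch_alpha)
    d <- if (isTRUE(stm)) {
      combine_distributions(d_ltm, predict(stm_p, ctx_chunk))
    } else d_ltm
    S_p[i] <- surprise(d, melody$pitch_sym[i])
    H_p[i] <- entropy_bits(d)
    if (isTRUE(stm)) ngram_insert(stm_p, melody$pitch_sym[i], ctx_chunk)

    # --- onset-time (IOI) viewpoint; first note excluded by convention ---
    if (i > 1L) {
      io_full <- ioi_obs[seq_len(i - 1L)]; io_full <- io_full[!is.na(io_full)]
      io_chunk <- ioi_obs[seq(chunk_start, length.out = i - chunk_start)]
      io_chunk <- io_chunk[!is.na(io_chunk)]
      d_ltm_o <- ltm_predict(ltm_ioi, "ioi", io_full, n_ioi_alpha)
      d_o <- if (isTRUE(stm)) {
        combine_distributions(d_ltm_o, predict(stm_o, io_chunk))
      } else d_ltm_o
      S_o[i] <- surprise(d_o, ioi_obs[i])
      H_o[i] <- entropy_bits(d_o)
      if (isTRUE(stm)) ngram_insert(stm_o, ioi_obs[i], io_chunk)
    }
  }
  expectation_series_df(attr(melody, "piece_id"), melody$onset_s,
                        S_p, H_p, S_o, H_o)
}

ltm_alphabet_size <- function(ltm, viewpoint, observed) {
  if (is.null(ltm)) return(max(observed, na.rm = TRUE))
  if (inherits(ltm, "markov_spec")) {
    return(if (viewpoint == "pitch") length(ltm$pitch_alphabet)
           else length(ltm$ioi_alphabet))
  }
  ltm$n_symbols
}

ltm_predict <- function(ltm, viewpoint, context, k) {
  if (is.null(ltm)) return(predictive_distribution(rep(1 / k, k)))
  if (inherits(ltm, "markov_spec")) {
    tab <- if (viewpoint == "pitch") ltm$pitch_transitions else ltm$ioi_transitions
    return(predictive_distribution(spec_row(tab, context, ltm$order)))
  }
  predict(ltm, context)
}

#' Memory-restricted expectation series (control analysis)
#'
#' Convenience wrapper over [expectation_series()] that rebuilds the STM from
#' scratch in consecutive chunks of `memory_bars` musical bars, producing
#' expectation features of identical dimensionality but progressively less
#' local context. `memory_bars = Inf` is the identity case.
#'
#' @inheritParams expectation_series
#' @export
memory_restricted_series <- function(melody, ltm_pitch = NULL, ltm_ioi = NULL,
                                     memory_bars, stm_max_order = Inf) {
  expectation_series(melody, ltm_pitch, ltm_ioi, stm = TRUE,
                     stm_max_order = stm_max_order, memory_bars = memory_bars)
}

#' Shuffle expectation values in time (null control)
#'
#' Permutes the four feature columns of an expectation series by one shared
#' random permutation while keeping note onsets fixed, preserving each
#' column's value multiset exactly. This builds the AM_shu null feature set:
#' same dimensionality and value distribution, no melodic information.
#'
#' @param series an `expectation_series`.
#' @param seed integer seed.
#' @export
shuffle_series <- function(series, seed) {
  stopifnot(inherits(series, "expectation_series"))
  n <- nrow(series)
  perm <- with_seed(seed, sample.int(n))
  out <- series
  for (col in c("S_p", "H_p", "S_o", "H_o")) {
    out[[col]] <- series[[col]][perm]
  }
  out
}
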