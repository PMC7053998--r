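#' Variable-order n-gram model with PPM-C smoothing
#'
#' Trains count tables for all context lengths up to `max_order` over a finite
#' symbol alphabet, in the style of variable-order Markov models of melodic
#' expectation. Prediction by partial matching (escape method C) turns the
#' counts into a full-support predictive distribution: each matched context of
#' length k contributes its maximum-likelihood estimate, reserving escape mass
#' `t/(n+t)` (t = distinct continuations seen) for back-off to the next
#' shorter context, terminating in the uniform order-(-1) distribution.
#'
#' Symbols are integer indices `1..|alphabet|`. Use `role = "stm"` models for
#' per-piece online training via [ngram_insert()].
#'
#' @param sequences list of integer symbol-index vectors (may be empty).
#' @param alphabet vector giving the alphabet (only its length matters for
#'   prediction; kept for labelling).
#' @param max_order maximum context length (use `Inf` for unbounded; contexts
#'   are then capped at an internal bound of 16, see the methods vignette).
#' @param role `"ltm"` or `"stm"` label.
#' @return An object of class `ngram_model`.
#' @seealso [predict.ngram_model()], [surprise()], [entropy_bits()]
#' @export
ngram_model <- function(sequences = list(), alphabet, max_order = Inf,
                        role = c("ltm", "stm")) {
  role <- match.arg(role)
  k <- length(alphabet)
  stopifnot(k >= 1L)
  cap <- if (is.finite(max_order)) as.integer(max_order) else 16L
  model <- structure(list(
    alphabet = alphabet,
    n_symbols = k,
    max_order = cap,
    unbounded = !is.finite(max_order),
    role = role,
    counts = new.env(parent = emptyenv()),
    n_trained = 0L
  ), class = "ngram_model")
  for (s in sequences) {
    for (i in seq_along(s)) {
      ngram_insert(model, s[i], s[seq_len(i - 1L)])
    }
  }
  model
}

#' Online (incremental) n-gram update
#'
#' Registers one observed symbol after its context, updating every count table
#' of order `0..min(max_order, |context|)`. The model environment is updated
#' in place (this is what makes the short-term model cheap to train note by
#' note); the model is also returned invisibly.
#'
#' @param model an [ngram_model()].
#' @param symbol integer symbol index in `1..n_symbols`.
#' @param context integer vector of preceding symbol indices (oldest first).
#' @export
ngram_insert <- function(model, symbol, context) {
  k <- model$n_symbols
  if (is.na(symbol) || symbol < 1L || symbol > k) {
    stop(sprintf("symbol '%s' outside alphabet of size %d at position %d",
                 symbol, k, length(context) + 1L))
  }
  env <- model$counts
  kmax <- min(model$max_order, length(context))
  for (ord in 0:kmax) {
    ctx <- if (ord == 0L) integer(0) else
      context[(length(context) - ord + 1L):length(context)]
    key <- paste0(ord, "|", ctx_key(ctx))
    cnt <- env[[key]]
    if (is.null(cnt)) cnt <- integer(k)
    cnt[symbol] <- cnt[symbol] + 1L
    env[[key]] <- cnt
  }
  model$n_trained <- model$n_trained + 1L  # local copy; count kept in env too
  env[[".n"]] <- (env[[".n"]] %||% 0L) + 1L
  invisible(model)
}

#' Predictive distribution over the alphabet for a context (PPM-C)
#'
#' Blends the maximum-likelihood distributions of every matched context
#' suffix, from the empty context up to the longest match, with escape mass
#' `t/(n+t)` passed down to shorter contexts and a uniform floor at order -1.
#' Always returns a strictly positive distribution summing to 1.
#'
#' @param object an [ngram_model()].
#' @param context integer vector of preceding symbol indices (oldest first).
#' @param ... unused.
#' @return A `predictive_distribution`: numeric probability vector with
#'   attributes `alphabet`.
#' @export
predict.ngram_model <- function(object, context = integer(0), ...) {
  k <- object$n_symbols
  env <- object$counts
  p <- rep(1 / k, k)  # order -1: uniform escape floor
  kmax <- min(object$max_order, length(context))
  for (ord in 0:kmax) {
    ctx <- if (ord == 0L) integer(0) else
      context[(length(context) - ord + 1L):length(context)]
    cnt <- env[[paste0(ord, "|", ctx_key(ctx))]]
    if (is.null(cnt)) break  # no longer suffix can match either
    n <- sum(cnt)
    if (n == 0L) break
    t <- sum(cnt > 0L)
    p <- cnt / (n + t) + (t / (n + t)) * p
  }
  predictive_distribution(p, object$alphabet)
}

predictive_distribution <- function(p, alphabet = seq_along(p)) {
  structure(as.numeric(p), alphabet = alphabet,
            class = "predictive_distribution")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("PPM-C n-gram model (%s): |alphabet| = %d, max order = %d%s, %d symbols trained\n",
              x$role, x$n_symbols, x$max_order,
              if (x$unbounded) " (unbounded, capped)" else "",
              x$counts[[".n"]] %||% 0L))
  invisible(x)
}

#' Entropy-weighted geometric combination of predictive distributions
#'
#' Combines long- and short-term predictive distributions over the same
#' alphabet. Each distribution gets weight `w = 1 / (1 + H/log2 |E|)` (its
#' relative entropy of prediction), so confident models dominate; the
#' combination is the weight-normalized geometric mean, floored at 1e-12 and
#' renormalized.
#'
#' @param ... two or more `predictive_distribution`s (or a single list).
#' @return A `predictive_distribution`.
#' @export
combine_distributions <- function(...) {
  dists <- list(...)
  if (length(dists) == 1L && is.list(dists[[1L]]) &&
      !inherits(dists[[1L]], "predictive_distribution")) {
    dists <- dists[[1L]]
  }
  stopifnot(length(dists) >= 2L)
  k <- length(dists[[1L]])
  for (d in dists) {
    if (length(d) != k) stop("alphabet mismatch between distributions")
  }
  if (k == 1L) return(predictive_distribution(1, attr(dists[[1L]], "alphabet")))
  hmax <- log2(k)
  w <- vapply(dists, function(d) 1 / (1 + entropy_bits(d) / hmax), numeric(1))
  w <- w / sum(w)
  logp <- rep(0, k)
  for (m in seq_along(dists)) {
    logp <- logp + w[m] * log(pmax(as.numeric(dists[[m]]), 1e-12))
  }
  p <- exp(logp - max(logp))
  predictive_distribution(p / sum(p), attr(dists[[1L]], "alphabet"))
}

#' Surprise (information content) of an observed symbol, in bits
#'
#' `-log2 p(observed)` under a predictive distribution; finite because PPM
#' smoothing guarantees full support (probabilities floored at 1e-12).
#'
#' @param dist a `predictive_distribution` (or bare probability vector).
#' @param observed integer symbol index.
#' @export
surprise <- function(dist, observed) {
  p <- as.numeric(dist)
  if (is.na(observed) || observed < 1L || observed > length(p)) {
    stop("observed symbol outside the alphabet")
  }
  -log2(max(p[observed], 1e-12))
}

#' Shannon entropy of a predictive distribution, in bits
#'
#' Expected surprise over all possible continuations, with `0 log 0 = 0`.
#'
#' @param dist a `predictive_distribution` (or bare probability vector).
#' @export
entropy_bits <- function(dist) {
  p <- as.numeric(dist)
  p <- p[p > 0]
  -sum(p * log2(p))
}
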