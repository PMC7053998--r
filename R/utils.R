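# Internal numerical utilities shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All user-facing randomness goes through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Analytic signal via the FFT half-spectrum method; x real vector.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

hilbert_envelope <- function(x) Mod(analytic_signal(x))

# 1/f^exponent (power spectrum) coloured noise, unit variance, length n.
colored_noise <- function(n, exponent = 1) {
  if (n < 2L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  # frequency index magnitude; DC removed, amplitude ~ f^(-exponent/2)
  k <- c(0, seq_len(n - 1L))
  k <- pmin(k, n - k)
  amp <- c(0, k[-1L]^(-exponent / 2))
  y <- Re(stats::fft(X * amp, inverse = TRUE) / n)
  y <- y - mean(y)
  s <- stats::sd(y)
  if (s > 0) y <- y / s
  y
}

# Zero-phase order-`order` Butterworth filtering of a vector or of each
# column of a matrix (forward-backward via signal::filtfilt).
butter_filtfilt <- function(x, fs, cutoff, type, order = 2L) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("cutoff frequency must lie inside (0, fs/2)")
  }
  flt <- signal::butter(order, w, type = type)
  f1 <- function(v) signal::filtfilt(flt, v)
  if (is.matrix(x)) apply(x, 2L, f1) else f1(x)
}

# Low-pass + linear-interpolation resampling of a vector or matrix columns.
resample_ts <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop("upsampling not supported")
  if (fs_out == fs_in) return(x)
  one <- function(v) {
    v <- butter_filtfilt(v, fs_in, 0.45 * fs_out, "low", order = 4L)
    n_out <- floor(length(v) * fs_out / fs_in)
    t_out <- (seq_len(n_out) - 1) / fs_out
    t_in <- (seq_along(v) - 1) / fs_in
    stats::approx(t_in, v, xout = t_out, rule = 2)$y
  }
  if (is.matrix(x)) apply(x, 2L, one) else one(x)
}

# Pearson correlation per column pair of two matrices (or vectors).
colwise_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  vapply(seq_len(ncol(a)), function(j) {
    if (stats::sd(a[, j]) == 0 || stats::sd(b[, j]) == 0) return(0)
    stats::cor(a[, j], b[, j])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
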