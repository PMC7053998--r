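#' Lagged design matrix for temporal response function estimation
#'
#' Expands a time x feature stimulus matrix into a time x (feature x lag)
#' design: a stimulus sample at time t populates the predictors of response
#' samples t + lag for every lag in the window. Out-of-range samples are
#' zero-padded so trials stay aligned across feature sets. Columns are
#' feature-major, lag-minor.
#'
#' @param features `feature_matrix` or time x feature matrix.
#' @param lag_window_ms two-element lag window in ms (negative = acausal).
#' @param fs sampling rate in Hz (taken from the feature matrix if present).
#' @return Design matrix with attributes `lags` (samples), `lag_ms`,
#'   `feature_names`.
#' @export
build_lagged_design <- function(features, lag_window_ms, fs = NULL) {
  if (inherits(features, "feature_matrix")) {
    fs <- features$fs
    x <- features$data
  } else {
    x <- as.matrix(features)
    if (is.null(fs)) stop("fs required")
  }
  stopifnot(length(lag_window_ms) == 2L, lag_window_ms[1L] < lag_window_ms[2L])
  lags <- seq(round(lag_window_ms[1L] / 1000 * fs),
              round(lag_window_ms[2L] / 1000 * fs))
  n <- nrow(x); nf <- ncol(x); nl <- length(lags)
  if (nl >= n) stop("lag window longer than the trial")
  X <- matrix(0, n, nf * nl)
  for (f in seq_len(nf)) {
    for (li in seq_len(nl)) {
      L <- lags[li]
      col <- (f - 1L) * nl + li
      if (L >= 0L) {
        if (L < n) X[(1L + L):n, col] <- x[1:(n - L), f]
      } else {
        X[1:(n + L), col] <- x[(1L - L):n, f]
      }
    }
  }
  structure(X, lags = lags, lag_ms = lags / fs * 1000,
            feature_names = colnames(x) %||% paste0("f", seq_len(nf)))
}

# --- internal sufficient-statistics machinery ------------------------------
# All fitting works from per-trial cross-products so any union of trials can
# be fit without touching the raw designs again.

trial_stats <- function(X, y) {
  y <- as.matrix(y)
  list(Sxx = crossprod(X), Sxy = crossprod(X, y),
       sx = colSums(X), sy = colSums(y), syy = colSums(y^2), n = nrow(X))
}

agg_stats <- function(stats, idx) {
  out <- stats[[idx[1L]]]
  for (i in idx[-1L]) {
    out$Sxx <- out$Sxx + stats[[i]]$Sxx
    out$Sxy <- out$Sxy + stats[[i]]$Sxy
    out$sx <- out$sx + stats[[i]]$sx
    out$sy <- out$sy + stats[[i]]$sy
    out$syy <- out$syy + stats[[i]]$syy
    out$n <- out$n + stats[[i]]$n
  }
  out
}

# Per-channel Pearson correlation between X w + b and y for one trial,
# computed from the trial's sufficient statistics only (the correlation is
# invariant to the intercept, so it never has to be materialized).
r_from_stats <- function(stat, fit, cols = NULL) {
  w <- fit$w
  Sxx <- stat$Sxx; Sxy <- stat$Sxy; sx <- stat$sx
  if (!is.null(cols)) {
    Sxx <- Sxx[cols, cols, drop = FALSE]
    Sxy <- Sxy[cols, , drop = FALSE]
    sx <- sx[cols]
  }
  n <- stat$n
  my <- stat$sy / n
  wm <- drop(crossprod(w, sx / n))                 # per-channel mean of Xw
  num <- colSums(w * Sxy) - n * wm * my            # w'Cxy per channel
  den_x <- colSums(w * (Sxx %*% w)) - n * wm^2     # w'Cxx w per channel
  den_y <- stat$syy - n * my^2
  r <- numeric(ncol(w))
  ok <- den_x > 0 & den_y > 0
  r[ok] <- num[ok] / sqrt(den_x[ok] * den_y[ok])
  pmin(pmax(r, -1), 1)
}

# Centre + z-score the aggregated normal equations; drop degenerate columns.
prep_normal <- function(agg) {
  n <- agg$n
  mx <- agg$sx / n
  my <- agg$sy / n
  Sc <- agg$Sxx - n * tcrossprod(mx)
  sdx <- sqrt(pmax(diag(Sc), 0) / (n - 1))
  good <- sdx > 1e-12
  Sy <- agg$Sxy - outer(mx, my) * n
  Ss <- Sc[good, good, drop = FALSE] / tcrossprod(sdx[good])
  Sys <- Sy[good, , drop = FALSE] / sdx[good]
  list(n = n, mx = mx, my = my, sdx = sdx, good = good, Ss = Ss, Sys = Sys)
}

# Ridge solution; `lambda` is a scalar or a per-column penalty vector
# (banded ridge), applied on the z-scored scale. Returns raw-scale weights
# and the unpenalized intercept.
ridge_solve <- function(prep, lambda) {
  p_all <- length(prep$good)
  n_ch <- ncol(prep$Sys)
  w <- matrix(0, p_all, n_ch)
  lam_all <- if (length(lambda) == 1L) rep(lambda, p_all) else lambda
  # infinite penalty = exclude the column (its weight is exactly 0)
  use <- prep$good & is.finite(lam_all)
  if (any(use)) {
    keep <- use[prep$good]
    prep <- list(n = prep$n, mx = prep$mx, my = prep$my, sdx = prep$sdx,
                 good = use,
                 Ss = prep$Ss[keep, keep, drop = FALSE],
                 Sys = prep$Sys[keep, , drop = FALSE])
    lam <- lam_all[use]
    ws <- if (all(lam > 0)) {
      A <- prep$Ss
      diag(A) <- diag(A) + lam
      solve(A, prep$Sys)
    } else {
      sv <- svd(prep$Ss)
      pos <- sv$d > max(sv$d) * 1e-10
      if (!all(pos)) warning("singular system with lambda = 0; using pseudo-inverse")
      sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], prep$Sys) / sv$d[pos])
    }
    w[prep$good, ] <- ws / prep$sdx[prep$good]
  }
  bias <- prep$my - drop(crossprod(w, prep$mx))
  list(w = w, bias = bias)
}

predict_raw <- function(X, fit) {
  sweep(X %*% fit$w, 2L, fit$bias, "+")
}

#' Fit a temporal response function by ridge regression
#'
#' Estimates a lag x feature x channel linear filter mapping stimulus
#' features to multichannel neural responses: `w = (X'X + lambda I)^-1 X'y`
#' on the lagged, z-scored design (intercept unpenalized, fitted through
#' centring). Deterministic. For cross-validated prediction and data-driven
#' regularization use [trf_crossval()].
#'
#' @param x stimulus: a `feature_matrix`, time x feature matrix, or list of
#'   such (multiple trials).
#' @param y response: time x channel matrix / recording, or list matching
#'   `x`.
#' @param fs sampling rate in Hz (taken from `x` if available).
#' @param lag_window_ms lag window, default `c(0, 350)` ms.
#' @param lambda ridge parameter (0 falls back to a pseudo-inverse with a
#'   warning if the system is singular).
#' @return An object of class `trf` with elements `weights` (lag x feature x
#'   channel array), `bias`, `lambda`, `lag_ms`, `fs`, `feature_names`.
#' @seealso [trf_crossval()], [predict.trf()], [plot.trf()]
#' @examples
#' x <- matrix(rnorm(500), 500, 1)
#' k <- c(0, 1, 0.5, 0.2)
#' y <- stats::filter(x, k, method = "convolution", sides = 1)
#' y[is.na(y)] <- 0
#' fit <- trf(x, y, fs = 64, lag_window_ms = c(0, 100), lambda = 1e-6)
#' round(coef(fit)[1:4, 1, 1], 2)
#' @export
trf <- function(x, y, fs = NULL, lag_window_ms = c(0, 350), lambda = 1) {
  xl <- if (is.list(x) && !inherits(x, "feature_matrix")) x else list(x)
  yl <- if (is.list(y) && !inherits(y, c("neural_recording", "simulated_recording"))) y else list(y)
  stopifnot(length(xl) == length(yl))
  if (is.null(fs) && inherits(xl[[1L]], "feature_matrix")) fs <- xl[[1L]]$fs
  get_y <- function(yy) if (inherits(yy, c("neural_recording", "simulated_recording"))) yy$data else as.matrix(yy)
  stats_l <- vector("list", length(xl))
  X1 <- NULL
  for (i in seq_along(xl)) {
    X <- build_lagged_design(xl[[i]], lag_window_ms, fs)
    if (i == 1L) X1 <- X
    yy <- get_y(yl[[i]])
    if (nrow(yy) != nrow(X)) stop("design and response lengths differ")
    stats_l[[i]] <- trial_stats(X, yy)
  }
  prep <- prep_normal(agg_stats(stats_l, seq_along(stats_l)))
  fit <- ridge_solve(prep, lambda)
  new_trf(fit, attr(X1, "lags"), attr(X1, "lag_ms"),
          attr(X1, "feature_names"), fs, lambda, lag_window_ms)
}

new_trf <- function(fit, lags, lag_ms, feature_names, fs, lambda,
                    lag_window_ms) {
  nl <- length(lags); nf <- length(feature_names); nc <- ncol(fit$w)
  weights <- array(0, dim = c(nl, nf, nc),
                   dimnames = list(NULL, feature_names, NULL))
  for (f in seq_len(nf)) {
    weights[, f, ] <- fit$w[((f - 1L) * nl + 1L):(f * nl), ]
  }
  structure(list(weights = weights, w_flat = fit$w, bias = fit$bias,
                 lambda = lambda, lags = lags, lag_ms = lag_ms,
                 lag_window_ms = lag_window_ms, fs = fs,
                 feature_names = feature_names, n_channels = nc),
            class = "trf")
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("Temporal response function: %d features x %d lags (%g..%g ms) x %d channels, lambda = %s\n",
              length(x$feature_names), length(x$lags),
              x$lag_ms[1L], x$lag_ms[length(x$lag_ms)], x$n_channels,
              paste(format(x$lambda), collapse = "/")))
  invisible(x)
}

#' @export
summary.trf <- function(object, ...) {
  w <- object$weights
  peak <- vapply(seq_along(object$feature_names), function(f) {
    prof <- rowMeans(abs(array(w[, f, ], dim = dim(w)[c(1L, 3L)])))
    object$lag_ms[which.max(prof)]
  }, numeric(1))
  cat(sprintf("TRF fit (lambda = %s), lag window %g..%g ms at %g Hz\n",
              paste(format(object$lambda), collapse = "/"),
              object$lag_window_ms[1L], object$lag_window_ms[2L], object$fs))
  df <- data.frame(feature = object$feature_names,
                   peak_lag_ms = peak,
                   rms_weight = apply(w, 2L, function(m) sqrt(mean(m^2))))
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
coef.trf <- function(object, ...) object$weights

#' Predict neural responses from a fitted TRF
#'
#' @param object a `trf`.
#' @param newdata a `feature_matrix` or time x feature matrix.
#' @param ... unused.
#' @return Time x channel matrix of predicted responses.
#' @export
predict.trf <- function(object, newdata, ...) {
  X <- build_lagged_design(newdata, object$lag_window_ms, object$fs)
  predict_raw(X, list(w = object$w_flat, bias = object$bias))
}

#' Plot TRF weights against time lag
#'
#' @param x a `trf`.
#' @param channel channel index to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trf <- function(x, channel = 1L, ...) {
  graphics::matplot(x$lag_ms, x$weights[, , channel], type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "weight",
                    main = sprintf("TRF weights, channel %d", channel), ...)
  graphics::legend("topright", legend = x$feature_names, lty = 1,
                   col = seq_along(x$feature_names), bty = "n", cex = 0.8)
  invisible(x)
}

#' Leave-one-trial-out cross-validated TRF prediction
#'
#' For each held-out trial, fits a ridge TRF on the remaining trials (with
#' the ridge parameter chosen by an inner cross-validation over the training
#' trials only, so no test information leaks) and scores the prediction by
#' Pearson's correlation per channel. Also returns a final model fit on all
#' trials at the modal fold lambda.
#'
#' @param x list of per-trial stimuli (`feature_matrix` or matrices).
#' @param y list of per-trial responses (matrices or recordings).
#' @param fs sampling rate in Hz.
#' @param lag_window_ms lag window, default `c(0, 350)` ms for prediction
#'   (use `c(-150, 750)` when the weights themselves are inspected).
#' @param lambda candidate ridge parameters (log grid).
#' @param inner_folds folds of the inner lambda-selection CV.
#' @param penalty_groups integer vector, one entry per feature, assigning
#'   features to penalty bands (banded ridge: each band gets its own lambda
#'   from the grid, so e.g. sparse expectation impulses and the dense
#'   envelope are regularized on their own scales, and a band that carries
#'   no signal can be shrunk away without affecting the rest). `NULL` (the
#'   default) puts features named `Env*` in band 1 and all others in band 2;
#'   a single band reduces to ordinary ridge.
#' @param lambda_per_fold optional precomputed per-fold lambdas (a list of
#'   per-band vectors; reused, e.g., across feature variants of identical
#'   dimensionality).
#' @return A `trf_cv`: list with `r` (trial x channel Pearson correlations),
#'   `model` (final `trf`), `lambda_per_fold`, `lag_window_ms`.
#' @export
trf_crossval <- function(x, y, fs = NULL, lag_window_ms = c(0, 350),
                         lambda = 10^seq(-3, 6), inner_folds = 3L,
                         penalty_groups = NULL, lambda_per_fold = NULL) {
  stopifnot(is.list(x), is.list(y), length(x) == length(y))
  n_trials <- length(x)
  if (n_trials < 3L) stop("need at least 3 trials for leave-one-out CV")
  if (is.null(fs) && inherits(x[[1L]], "feature_matrix")) fs <- x[[1L]]$fs
  get_y <- function(yy) if (inherits(yy, c("neural_recording", "simulated_recording"))) yy$data else as.matrix(yy)

  stats_l <- vector("list", n_trials)
  n_ch <- NULL; lags1 <- NULL; lag_ms1 <- NULL; feature_names <- NULL
  for (i in seq_len(n_trials)) {
    X <- build_lagged_design(x[[i]], lag_window_ms, fs)
    yy <- get_y(y[[i]])
    if (nrow(yy) != nrow(X)) stop("trial ", i, ": lengths differ")
    stats_l[[i]] <- trial_stats(X, yy)
    if (i == 1L) {
      n_ch <- ncol(yy)
      lags1 <- attr(X, "lags"); lag_ms1 <- attr(X, "lag_ms")
      feature_names <- attr(X, "feature_names")
    }
  }
  nf <- length(feature_names)
  nl <- length(lags1)
  if (is.null(penalty_groups)) {
    penalty_groups <- ifelse(startsWith(feature_names, "Env"), 1L, 2L)
  }
  stopifnot(length(penalty_groups) == nf)
  bands <- sort(unique(penalty_groups))
  col_band <- rep(match(penalty_groups, bands), each = nl)
  # candidate per-band lambda combinations; bands after the first may also
  # be switched off entirely (infinite penalty), so a feature family that
  # carries no signal costs nothing
  combos <- if (length(bands) == 1L) {
    lapply(lambda, function(l) l)
  } else {
    cand <- c(list(lambda), rep(list(c(lambda, Inf)), length(bands) - 1L))
    grid <- do.call(expand.grid, cand)
    lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  }
  col_lambda <- function(band_lams) {
    if (length(band_lams) == 1L) rep(band_lams, nf * nl) else
      band_lams[col_band]
  }

  choose_lambda <- function(train_idx) {
    if (length(combos) == 1L) return(combos[[1L]])
    groups <- split(train_idx,
                    rep_len(seq_len(max(2L, min(inner_folds,
                                                length(train_idx)))),
                            length(train_idx)))
    groups <- groups[lengths(groups) > 0L &
                       lengths(groups) < length(train_idx)]
    score <- numeric(length(combos))
    for (g in groups) {
      fit_idx <- setdiff(train_idx, g)
      prep <- prep_normal(agg_stats(stats_l, fit_idx))
      for (ci in seq_along(combos)) {
        fit <- ridge_solve(prep, col_lambda(combos[[ci]]))
        for (j in g) {
          score[ci] <- score[ci] + mean(r_from_stats(stats_l[[j]], fit))
        }
      }
    }
    combos[[which.max(score)]]
  }

  r <- matrix(NA_real_, n_trials, n_ch)
  lam_fold <- vector("list", n_trials)
  for (o in seq_len(n_trials)) {
    train_idx <- setdiff(seq_len(n_trials), o)
    lam <- if (!is.null(lambda_per_fold)) lambda_per_fold[[o]] else
      choose_lambda(train_idx)
    lam_fold[[o]] <- lam
    fit <- ridge_solve(prep_normal(agg_stats(stats_l, train_idx)),
                       col_lambda(lam))
    r[o, ] <- r_from_stats(stats_l[[o]], fit)
  }
  keys <- vapply(lam_fold, paste, "", collapse = "/")
  lam_final <- lam_fold[[match(names(sort(table(keys), decreasing = TRUE))[1L],
                               keys)]]
  fit_all <- ridge_solve(prep_normal(agg_stats(stats_l, seq_len(n_trials))),
                         col_lambda(lam_final))
  model <- new_trf(fit_all, lags1, lag_ms1, feature_names, fs, lam_final,
                   lag_window_ms)
  structure(list(r = r, model = model, lambda_per_fold = lam_fold,
                 penalty_groups = penalty_groups,
                 lag_window_ms = lag_window_ms, fs = fs),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf("Cross-validated TRF: %d trials x %d channels; mean r = %.4f (lambda = %s)\n",
              nrow(x$r), ncol(x$r), mean(x$r),
              paste(format(x$model$lambda), collapse = "/")))
  invisible(x)
}

#' @export
summary.trf_cv <- function(object, ...) {
  cat(sprintf("Leave-one-out TRF prediction, lag window %g..%g ms\n",
              object$lag_window_ms[1L], object$lag_window_ms[2L]))
  cat(sprintf("  mean r = %.4f; per-channel range %.4f..%.4f; fold lambdas: %s\n",
              mean(object$r), min(colMeans(object$r)), max(colMeans(object$r)),
              paste(unique(vapply(object$lambda_per_fold, paste, "",
                                  collapse = "/")), collapse = ", ")))
  invisible(colMeans(object$r))
}
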