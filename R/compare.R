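#' Compare prediction scores of two feature sets
#'
#' Tests whether one stimulus descriptor (e.g. acoustics + melodic
#' expectations, AM) predicts held-out neural data better than another (e.g.
#' acoustics alone, A). The per-subject statistic is the channel-averaged
#' prediction correlation; the group test is a two-tailed paired permutation
#' (sign-flip) test on the per-subject differences, with a paired Cohen's d
#' effect size. Optionally also runs the per-subject trial-level test.
#'
#' @param scores_a,scores_b subject x channel matrices (or per-subject
#'   vectors) of prediction correlations for the two feature sets.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @param tails `"one"` (default) tests the directional hypothesis that set
#'   b predicts better than set a. The direction is part of the hypothesis
#'   (adding informative features can only help a correctly regularized
#'   model), and the small negative bias that cross-validated scores of the
#'   larger model carry under the null makes the one-tailed test
#'   conservative. `"two"` gives the non-directional test.
#' @param trial_r_a,trial_r_b optional lists (one element per subject) of
#'   per-trial channel-mean correlations, for subject-level significance.
#' @return A `feature_set_comparison`: per-subject `delta_r`, group `p`,
#'   paired `cohens_d`, `n_positive`, and (if trial scores given)
#'   `subject_p`.
#' @export
compare_feature_sets <- function(scores_a, scores_b, n_perm = 10000L,
                                 seed = 1L, tails = c("one", "two"),
                                 trial_r_a = NULL, trial_r_b = NULL) {
  tails <- match.arg(tails)
  to_vec <- function(s) if (is.matrix(s)) rowMeans(s) else as.numeric(s)
  ra <- to_vec(scores_a); rb <- to_vec(scores_b)
  if (length(ra) != length(rb)) stop("subject counts differ between score sets")
  delta <- rb - ra
  test <- permutation_test(rb, ra, paired = TRUE, n_perm = n_perm,
                           tails = tails, seed = seed)
  subject_p <- NULL
  if (!is.null(trial_r_a) && !is.null(trial_r_b)) {
    subject_p <- mapply(function(a, b) {
      permutation_test(b, a, paired = TRUE, n_perm = n_perm, tails = tails,
                       seed = seed)$p_value
    }, trial_r_a, trial_r_b)
  }
  structure(list(delta_r = delta, mean_delta = mean(delta),
                 p = test$p_value, cohens_d = cohens_d(rb, ra, paired = TRUE),
                 n_positive = sum(delta > 0), n_subjects = length(delta),
                 subject_p = subject_p),
            class = "feature_set_comparison")
}

#' @export
print.feature_set_comparison <- function(x, ...) {
  cat(sprintf("Feature-set comparison: mean delta-r = %+.4f (d = %.2f), %d/%d subjects positive, p = %.4g\n",
              x$mean_delta, x$cohens_d, x$n_positive, x$n_subjects, x$p))
  invisible(x)
}

#' Backward elimination of time-lag windows (r_LOSS)
#'
#' Quantifies the relevance of each 50 ms block of stimulus-response lags to
#' the encoding model: TRFs are fit on the full outer lag window and refit
#' after excluding one block of lags at a time (first elimination pass only);
#' the loss is the drop in held-out prediction correlation,
#' `r_LOSS = r_full - r_without_block`, per channel. Blocks whose exclusion
#' hurts carry non-redundant response energy. Significance is a one-sided
#' sign-flip permutation test over evaluation trials on the per-trial losses
#' (relevance means positive loss), Bonferroni-corrected across blocks and
#' channels; the enumeration is exhaustive (exact) when it fits in about
#' twice the permutation budget.
#'
#' The models are fit once on a dedicated training subset of trials and the
#' losses evaluated on the remaining trials. With a single shared training
#' fit the evaluation-trial losses are independent and symmetric under the
#' null, so the sign-flip test is exact; leave-one-out evaluation would
#' couple the folds through their overlapping training sets and inflate the
#' false-positive rate several-fold (the classic anticonservativeness of
#' cross-validation tests). Note the p-value floor `2^-n_eval`: Bonferroni
#' significance across the default 18 blocks needs at least 10 evaluation
#' trials.
#'
#' @param x,y lists of per-trial stimuli and responses.
#' @param fs sampling rate in Hz.
#' @param outer_window_ms full lag window, default `c(-150, 750)` ms.
#' @param window_ms excluded-block width, default 50 ms.
#' @param lambda fixed ridge parameter for all fits; `NULL` chooses it once
#'   by inner CV on the training trials of the full model.
#' @param n_train number of training trials (default one third, at least 3);
#'   the rest are evaluation trials.
#' @param n_perm permutations (values below 100 trigger a warning).
#' @param alpha family-wise significance level before Bonferroni division.
#' @param seed integer seed.
#' @return A `lag_selection` data frame: `window_start_ms`, `window_end_ms`,
#'   `channel`, `r_loss`, `p`, `significant`.
#' @export
backward_eliminate_lags <- function(x, y, fs = NULL,
                                    outer_window_ms = c(-150, 750),
                                    window_ms = 50, lambda = NULL,
                                    n_train = NULL,
                                    n_perm = 10000L, alpha = 0.05,
                                    seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation p-value")
  stopifnot(is.list(x), is.list(y), length(x) == length(y))
  n_trials <- length(x)
  if (n_trials < 4L) stop("need at least 4 trials")
  if (is.null(n_train)) n_train <- max(3L, floor(n_trials / 3))
  if (n_train >= n_trials) stop("no evaluation trials left")
  train_idx <- seq_len(n_train)
  eval_idx <- setdiff(seq_len(n_trials), train_idx)
  if (is.null(fs) && inherits(x[[1L]], "feature_matrix")) fs <- x[[1L]]$fs
  get_y <- function(yy) if (inherits(yy, c("neural_recording", "simulated_recording"))) yy$data else as.matrix(yy)

  stats_l <- vector("list", n_trials)
  lag_ms <- NULL; nf <- NULL; n_ch <- NULL
  for (i in seq_len(n_trials)) {
    X <- build_lagged_design(x[[i]], outer_window_ms, fs)
    yy <- get_y(y[[i]])
    stats_l[[i]] <- trial_stats(X, yy)
    if (i == 1L) {
      lag_ms <- attr(X, "lag_ms")
      nf <- length(attr(X, "feature_names"))
      n_ch <- ncol(yy)
    }
  }
  nl <- length(lag_ms)

  if (is.null(lambda)) {
    cv <- trf_crossval(x[train_idx], y[train_idx], fs = fs,
                       lag_window_ms = outer_window_ms)
    lambda <- cv$model$lambda
    if (length(lambda) > 1L) {
      pg <- cv$penalty_groups
      lambda_cols <- lambda[match(pg, sort(unique(pg)))][rep(seq_len(nf),
                                                             each = nl)]
    } else lambda_cols <- rep(lambda, nf * nl)
  } else lambda_cols <- rep(lambda, length.out = nf * nl)

  agg_train <- agg_stats(stats_l, train_idx)
  eval_r <- function(keep) {
    sub <- list(Sxx = agg_train$Sxx[keep, keep, drop = FALSE],
                Sxy = agg_train$Sxy[keep, , drop = FALSE],
                sx = agg_train$sx[keep], sy = agg_train$sy,
                syy = agg_train$syy, n = agg_train$n)
    fit <- ridge_solve(prep_normal(sub), lambda_cols[keep])
    r <- matrix(NA_real_, length(eval_idx), n_ch)
    for (j in seq_along(eval_idx)) {
      r[j, ] <- r_from_stats(stats_l[[eval_idx[j]]], fit, cols = keep)
    }
    r
  }

  all_cols <- seq_len(nf * nl)
  r_full <- eval_r(all_cols)
  n_eval <- length(eval_idx)

  starts <- seq(outer_window_ms[1L], outer_window_ms[2L] - window_ms,
                by = window_ms)
  res <- vector("list", length(starts))
  # exhaustive sign-flip enumeration whenever it costs no more than about
  # twice the requested budget (exact p, floor 1/2^n); random flips otherwise
  exhaustive <- 2^n_eval <= 2 * n_perm
  flips <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n_eval)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n_eval,
                                  replace = TRUE), n_perm, n_eval))
  }
  for (wi in seq_along(starts)) {
    lo <- starts[wi]; hi <- starts[wi] + window_ms
    drop_lag <- if (wi == length(starts)) lag_ms >= lo & lag_ms <= hi else
      lag_ms >= lo & lag_ms < hi
    keep <- all_cols[!rep(drop_lag, times = nf)]
    r_ex <- eval_r(keep)
    loss <- r_full - r_ex                     # eval trials x channels
    obs <- colMeans(loss)
    null_means <- flips %*% loss / n_eval     # permutations x channels
    p <- vapply(seq_len(n_ch), function(ch) {
      if (exhaustive) mean(null_means[, ch] >= obs[ch]) else
        (1 + sum(null_means[, ch] >= obs[ch])) / (n_perm + 1)
    }, numeric(1))
    res[[wi]] <- data.frame(window_start_ms = lo, window_end_ms = hi,
                            channel = seq_len(n_ch), r_loss = obs, p = p)
  }
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha / (length(starts) * n_ch)
  class(out) <- c("lag_selection", "data.frame")
  out
}

#' Contrasts of TRF weight components
#'
#' Computes, per channel and lag, the surprise-vs-entropy contrast
#' `(S_p + S_o)/2 - (H_p + H_o)/2` and the pitch-vs-onset contrast
#' `(S_p + H_p)/2 - (S_o + H_o)/2` of a TRF fit on the full AM feature set.
#' Given a list of per-subject models, also runs a two-tailed sign-flip
#' permutation test across subjects per (lag, channel) with BH/FDR
#' correction.
#'
#' @param model a `trf` fit on AM, or a list of per-subject `trf`s.
#' @param n_perm permutations for the group test.
#' @param seed integer seed.
#' @return List with `surprise_vs_entropy` and `pitch_vs_onset` (lag x
#'   channel matrices; group means when a list is given), plus `p` and
#'   `significant` masks for each contrast in the group case, and `lag_ms`.
#' @export
trf_component_contrasts <- function(model, n_perm = 2000L, seed = 1L) {
  one <- function(m) {
    fn <- m$feature_names
    need <- c("S_p", "H_p", "S_o", "H_o")
    if (!all(need %in% fn)) stop("model lacks expectation features: ",
                                 paste(setdiff(need, fn), collapse = ", "))
    w <- m$weights
    list(sve = (w[, "S_p", ] + w[, "S_o", ]) / 2 -
           (w[, "H_p", ] + w[, "H_o", ]) / 2,
         pvo = (w[, "S_p", ] + w[, "H_p", ]) / 2 -
           (w[, "S_o", ] + w[, "H_o", ]) / 2)
  }
  if (inherits(model, "trf")) {
    c1 <- one(model)
    return(list(surprise_vs_entropy = as.matrix(c1$sve),
                pitch_vs_onset = as.matrix(c1$pvo),
                lag_ms = model$lag_ms))
  }
  stopifnot(is.list(model), length(model) >= 2L)
  per <- lapply(model, one)
  n_sub <- length(per)
  group_test <- function(key) {
    mats <- lapply(per, function(z) as.matrix(z[[key]]))
    flat <- t(vapply(mats, as.numeric, numeric(length(mats[[1L]]))))
    obs <- colMeans(flat)
    flips <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n_sub,
                                           replace = TRUE), n_perm, n_sub))
    null_means <- flips %*% flat / n_sub
    p <- (1 + colSums(abs(null_means) >= abs(matrix(obs, n_perm,
                                                    length(obs), byrow = TRUE)))) /
      (n_perm + 1)
    dims <- dim(mats[[1L]])
    list(mean = matrix(obs, dims[1L], dims[2L]),
         p = matrix(p, dims[1L], dims[2L]),
         significant = matrix(fdr_bh(p), dims[1L], dims[2L]))
  }
  sve <- group_test("sve"); pvo <- group_test("pvo")
  list(surprise_vs_entropy = sve$mean, pitch_vs_onset = pvo$mean,
       p = list(surprise_vs_entropy = sve$p, pitch_vs_onset = pvo$p),
       significant = list(surprise_vs_entropy = sve$significant,
                          pitch_vs_onset = pvo$significant),
       lag_ms = model[[1L]]$lag_ms)
}
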