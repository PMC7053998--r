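#' Two-sample permutation test
#'
#' Paired version: sign-flip test on the within-pair differences; unpaired:
#' random relabelling of group membership. The statistic is the mean
#' difference; p-values use the add-one convention
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)` (two-tailed) so p is
#' never 0 and never below `1/(n_perm + 1)`. Deterministic given `seed`.
#' When all `2^n` sign flips of a paired test fit inside `n_perm`, the
#' enumeration is exhaustive and the p-value exact (`#{|T| >= |T_obs|}/2^n`,
#' which includes the identity flip and so is still never 0).
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param n_perm number of permutations.
#' @param tails `"two"` or `"one"` (one-tailed: x greater than y).
#' @param seed integer seed.
#' @return A `perm_test` list: `statistic`, `p_value`, `n_perm`, `tails`.
#' @export
permutation_test <- function(x, y, paired = FALSE, n_perm = 10000L,
                             tails = c("two", "one"), seed = 1L) {
  tails <- match.arg(tails)
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    n <- length(d)
    if (n < 3L) stop("need at least 3 pairs")
    obs <- mean(d)
    exhaustive <- 2^n <= n_perm
    flips <- if (exhaustive) {
      as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
    } else {
      with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                             n_perm, n))
    }
    null <- drop(flips %*% d) / n
    if (exhaustive) {
      p <- if (tails == "two") mean(abs(null) >= abs(obs)) else
        mean(null >= obs)
      return(structure(list(statistic = obs, p_value = p, n_perm = 2^n,
                            tails = tails, paired = TRUE, exact = TRUE),
                       class = "perm_test"))
    }
  } else {
    nx <- length(x); ny <- length(y)
    if (nx < 3L || ny < 3L) stop("need at least 3 observations per group")
    obs <- mean(x) - mean(y)
    pool <- c(x, y)
    null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nx + ny, nx)
      mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1)))
  }
  p <- if (tails == "two") {
    (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  } else {
    (1 + sum(null >= obs)) / (n_perm + 1)
  }
  structure(list(statistic = obs, p_value = p, n_perm = n_perm,
                 tails = tails, paired = paired), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s %s-tailed permutation test: statistic = %.4g, p = %.4g (%d permutations)\n",
              if (x$paired) "Paired" else "Unpaired", x$tails, x$statistic,
              x$p_value, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Controls the false discovery rate at level `q` across a family of
#' p-values; returns the logical rejection mask.
#'
#' @param p_values numeric p-values in (0, 1].
#' @param q target FDR level.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Cohen's d effect size
#'
#' Unpaired: mean difference over the pooled standard deviation; paired: mean
#' of the differences over their standard deviation.
#'
#' @param x,y numeric samples.
#' @param paired logical.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    s <- stats::sd(d)
    if (s == 0) {
      if (mean(d) == 0) return(0)
      warning("zero variance of differences; returning signed infinity")
      return(sign(mean(d)) * Inf)
    }
    return(mean(d) / s)
  }
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    warning("zero pooled variance; returning signed infinity")
    return(sign(mean(x) - mean(y)) * Inf)
  }
  (mean(x) - mean(y)) / sp
}

#' Topographic dissimilarity between two channel-space maps
#'
#' `DISS = 2 * (1 - r)` where r is the Pearson correlation between the two
#' maps across channels (so identical maps give 0, uncorrelated maps 2,
#' anti-correlated maps 4). `sqrt_form = TRUE` gives the conventional
#' `sqrt(2 (1 - r))` variant instead. Significance (one-sided, larger DISS)
#' comes from a randomization test that exchanges the two maps' values
#' channel by channel, the null of no topographic difference.
#'
#' @param map1,map2 numeric channel vectors (>= 3 channels).
#' @param n_perm randomizations (default 100).
#' @param seed integer seed.
#' @param sqrt_form use the square-root form of the index.
#' @return A list: `diss`, `r`, `p_value`, `n_perm`.
#' @export
diss <- function(map1, map2, n_perm = 100L, seed = 1L, sqrt_form = FALSE) {
  stopifnot(length(map1) == length(map2), length(map1) >= 3L)
  if (stats::sd(map1) == 0 || stats::sd(map2) == 0) {
    stop("zero-variance map; DISS undefined")
  }
  stat <- function(a, b) {
    d <- 2 * (1 - stats::cor(a, b))
    if (sqrt_form) sqrt(max(d, 0)) else d
  }
  obs <- stat(map1, map2)
  n <- length(map1)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, map2, map1)
    b <- ifelse(swap, map1, map2)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stat(a, b)
  }, numeric(1)))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= obs)) / (length(null) + 1)
  list(diss = obs, r = stats::cor(map1, map2), p_value = p,
       n_perm = length(null))
}

#' Spearman rank correlation with permutation significance
#'
#' Tie-corrected rank correlation; the two-tailed p-value comes from
#' permuting one variable.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return A list: `rho`, `p_value`, `n_perm`.
#' @export
spearman_test <- function(x, y, n_perm = 2000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y), method = "spearman")
  }, numeric(1)))
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n_perm = n_perm)
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Classical within-subject one-way ANOVA, `F(k-1, (k-1)(n-1))`, via the
#' multivariate linear model machinery (car::Anova). Mauchly's test checks
#' sphericity; when it rejects at 0.05 the Greenhouse-Geisser epsilon
#' correction is applied to the degrees of freedom and p-value.
#'
#' @param data subject x condition numeric matrix (>= 4 subjects, >= 3
#'   conditions, no missing cells).
#' @return A list: `F`, `df1`, `df2` (corrected when applicable), `p_value`,
#'   `epsilon` (GG), `mauchly_p`, `sphericity_ok`.
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (k < 3L) stop("need at least 3 conditions")
  if (n < 4L) stop("need at least 4 subjects")
  if (anyNA(data)) stop("missing cells are not supported")
  colnames(data) <- paste0("c", seq_len(k))
  fit <- stats::lm(data ~ 1)
  idata <- data.frame(cond = factor(seq_len(k)))
  av <- car::Anova(fit, idata = idata, idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  Fv <- ut["cond", "F value"]
  df1 <- ut["cond", "num Df"]; df2 <- ut["cond", "den Df"]
  p <- ut["cond", "Pr(>F)"]
  grab <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  # Mauchly's test needs more subjects than conditions; when it cannot be
  # computed the uncorrected F is reported.
  mauchly_p <- grab(s$sphericity.tests["cond", "p-value"])
  eps <- grab(s$pval.adjustments["cond", "GG eps"])
  p_gg <- grab(s$pval.adjustments["cond", "Pr(>F[GG])"])
  correct <- is.finite(mauchly_p) && mauchly_p < 0.05 && is.finite(eps)
  list(F = unname(Fv),
       df1 = unname(if (correct) eps * df1 else df1),
       df2 = unname(if (correct) eps * df2 else df2),
       p_value = unname(if (correct) p_gg else p),
       epsilon = unname(eps),
       mauchly_p = unname(mauchly_p),
       sphericity_ok = !correct)
}
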