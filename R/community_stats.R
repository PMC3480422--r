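# Seasonal-survey statistics: trends, dispersion, site comparisons,
# matrix correlation.

#' Two-period style moving average of a seasonal series
#'
#' Smooths a seasonal density series the way the survey figures plot
#' their trend lines: the average of raw points 2 and 3 is portrayed at
#' position 1, and so forth -- output element `i` averages raw points
#' `i+1 ... i+window` (the final window is truncated at the end of the
#' series, so even `window = n` yields one element, the mean of points
#' `2 ... n`).  The conventional trailing alignment (element `i`
#' averages points `i-window+1 ... i`) is available via
#' `align = "trailing"`.
#'
#' @param x numeric series ordered by sampling week.
#' @param window number of points per average (default 2).
#' @param align `"legend"` (the figure-legend convention above) or
#'   `"trailing"`.
#' @return smoothed numeric vector (length `max(1, n - window)` for
#'   `"legend"`, `n - window + 1` for `"trailing"`).
#' @examples
#' moving_average(c(1, 3, 5))           # 4
#' moving_average(1:6, 2, "trailing")   # 1.5 2.5 3.5 4.5 5.5
#' @export
moving_average <- function(x, window = 2L, align = c("legend", "trailing")) {
  align <- match.arg(align)
  n <- length(x)
  if (window < 1L || window > n) {
    stop("window must lie in [1, length(x)]", call. = FALSE)
  }
  if (align == "trailing") {
    return(vapply(seq_len(n - window + 1L),
                  function(i) mean(x[i:(i + window - 1L)]), 0))
  }
  idx <- seq_len(max(1L, n - window))
  vapply(idx, function(i) mean(x[(i + 1L):min(i + window, n)]), 0)
}

#' Coefficient of variation as a percentage
#'
#' @param mean sample mean (> 0).
#' @param sd sample standard deviation (>= 0).
#' @return 100 * sd / mean, rounded to one decimal.
#' @examples
#' coefficient_of_variation(2392, 1151)  # 48.1
#' @export
coefficient_of_variation <- function(mean, sd) {
  stopifnot_scalar_number(mean, "mean")
  stopifnot_scalar_number(sd, "sd")
  if (mean <= 0) stop("mean must be positive", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  round(100 * sd / mean, 1)
}

#' Mann-Whitney U comparison of two sites
#'
#' Independent two-sided Mann-Whitney U test for per-taxon or per-guild
#' density series of two habitats.  The exact null distribution is used
#' for small samples (n + m <= 12) without ties; otherwise the normal
#' approximation with tie correction (and continuity correction) is
#' applied and the switch is reported.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (statistic for `x`), `p` (two-sided), `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @examples
#' compare_sites_mwu(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
compare_sites_mwu <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Welch t-test on log-transformed totals
#'
#' Overall comparison of total nematode numbers between two habitats:
#' totals are log10-transformed and compared with a t-test not assuming
#' equal variances (Welch-Satterthwaite degrees of freedom).
#'
#' @param x,y positive totals, each with >= 2 values.
#' @return list with `t`, `df`, `p` (two-sided) and the log10 means.
#' @export
compare_log_totals <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs >= 2 values", call. = FALSE)
  }
  if (any(c(x, y) <= 0)) stop("totals must be positive", call. = FALSE)
  tt <- t.test(log10(x), log10(y), var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_log_x = mean(log10(x)),
       mean_log_y = mean(log10(y)))
}

#' Simple and partial Mantel tests between distance matrices
#'
#' Tests the association between two (dis)similarity matrices over the
#' same entities -- e.g. squared-Euclidean distances between the weekly
#' fungivore community profiles of two habitats.  The observed statistic
#' is the Mantel Z (sum of element-wise products of the upper-triangle
#' entries), also reported as the normalized correlation r.  With a
#' third control matrix `Z` the partial form correlates the residuals of
#' `X|Z` and `Y|Z`.  Significance comes from simultaneously permuting
#' rows and columns of `X`: the p-value uses the add-one convention
#' p = (#\{Z_perm >= Z_obs\} + 1) / (n_permutations + 1) and can never be
#' zero.  For small matrices all `n! - 1` non-identity permutations can
#' be enumerated (`permutations = "exhaustive"`, automatic when
#' cheaper than the requested number of random draws).
#'
#' @param X,Y square symmetric distance matrices with zero diagonals.
#' @param Z optional control matrix (partial Mantel).
#' @param n_permutations random permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return an `nq_mantel`: list with `z_observed`, `r_observed`,
#'   `z_random_mean`, `p`, `n_permutations`, `partial`, `exhaustive`,
#'   `seed`.
#' @export
mantel_test <- function(X, Y, Z = NULL, n_permutations = 9999L, seed = NULL,
                        permutations = c("auto", "random", "exhaustive")) {
  permutations <- match.arg(permutations)
  check_dist_matrix <- function(M, nm) {
    if (!is.matrix(M) || nrow(M) != ncol(M)) {
      stop(nm, " must be a square matrix", call. = FALSE)
    }
    if (!isTRUE(all.equal(M, t(M)))) stop(nm, " must be symmetric", call. = FALSE)
    if (any(abs(diag(M)) > 1e-12)) stop(nm, " must have a zero diagonal", call. = FALSE)
  }
  check_dist_matrix(X, "X"); check_dist_matrix(Y, "Y")
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have matching dimensions", call. = FALSE)
  if (!is.null(Z)) {
    check_dist_matrix(Z, "Z")
    if (nrow(Z) != n) stop("Z must match X and Y", call. = FALSE)
  }
  ut <- upper.tri(X)
  partial <- !is.null(Z)
  stat <- function(Xm) {
    xv <- Xm[ut]; yv <- Y[ut]
    if (partial) {
      zv <- Z[ut]
      xv <- residuals(lm(xv ~ zv))
      yv <- residuals(lm(yv ~ zv))
    }
    c(z = sum(xv * yv),
      r = if (sd(xv) == 0 || sd(yv) == 0) NA_real_ else cor(xv, yv))
  }
  obs <- stat(X)

  n_all <- factorial(n) - 1
  exhaustive <- permutations == "exhaustive" ||
    (permutations == "auto" && n_all <= n_permutations)
  perm_stats <- if (exhaustive) {
    perms <- all_permutations(n)
    vapply(perms[-1], function(p) stat(X[p, p])[["z"]], 0)  # drop identity
  } else {
    runner <- function() {
      vapply(seq_len(n_permutations), function(i) {
        p <- sample.int(n)
        stat(X[p, p])[["z"]]
      }, 0)
    }
    if (is.null(seed)) runner() else with_seed(seed, runner())
  }
  p <- (sum(perm_stats >= obs[["z"]]) + 1) / (length(perm_stats) + 1)
  structure(list(
    z_observed = obs[["z"]], r_observed = obs[["r"]],
    z_random_mean = mean(perm_stats), p = p,
    n_permutations = length(perm_stats), partial = partial,
    exhaustive = exhaustive, seed = seed
  ), class = "nq_mantel")
}

#' @export
print.nq_mantel <- function(x, ...) {
  cat(sprintf("<%s Mantel> Z = %.4g (random mean %.4g), r = %.3f, p = %.4g (%d %s permutations)\n",
              if (x$partial) "partial" else "simple",
              x$z_observed, x$z_random_mean, x$r_observed, x$p,
              x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

# all permutations of 1..n as a list (identity first)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Cumulative covariate over the days preceding a sampling
#'
#' Sums a daily environmental series (e.g. rainfall in mm) over the
#' `window_days` days strictly before the sampling day -- the cumulative
#' rainfall of the latest 21 days before sampling being the canonical
#' use.
#'
#' @param daily_values numeric vector indexed by day (day 1 = first
#'   element).
#' @param sampling_day index of the sampling day.
#' @param window_days length of the look-back window (default 21).
#' @return sum over days `sampling_day - window_days` to
#'   `sampling_day - 1`.
#' @export
covariate_window_sum <- function(daily_values, sampling_day, window_days = 21L) {
  first <- sampling_day - window_days
  last <- sampling_day - 1L
  if (first < 1L || last > length(daily_values)) {
    stop("daily series does not cover the ", window_days,
         "-day window before day ", sampling_day, call. = FALSE)
  }
  sum(daily_values[first:last])
}
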