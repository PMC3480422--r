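# Calibration: the linear relation Ct = a log10(N) + b per assay.

#' Construct a calibration curve from known parameters
#'
#' Builds the per-assay linear relation Ct = a log10(N) + b between the
#' threshold cycle and the number of target nematodes, e.g. from a
#' published parameter table.  Slope `a` is in cycles per log10
#' individual and must be negative for a valid assay (more template
#' amplifies earlier); the intercept `b` is the expected Ct of a single
#' nematode.  The amplification efficiency 10^(-1/a) - 1 is derived
#' (slope -1/log10(2) = -3.32 corresponds to perfect doubling).
#'
#' @param assay assay name.
#' @param a slope (cycles per log10 individual).
#' @param b intercept (cycles).
#' @param r2 coefficient of determination, if known.
#' @param n_points number of calibration points behind the fit.
#' @param genera_pooled genera whose series entered the fit.
#' @param points optional data frame of the underlying `(n, ct)` points.
#' @return an `nq_calibration_curve`.
#' @export
calibration_curve <- function(assay, a, b, r2 = NA_real_,
                              n_points = NA_integer_,
                              genera_pooled = character(0), points = NULL) {
  stopifnot_scalar_number(a, "slope a")
  stopifnot_scalar_number(b, "intercept b")
  valid <- a < 0
  if (!valid) {
    warning("calibration slope is non-negative; curve flagged invalid",
            call. = FALSE)
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]", call. = FALSE)
  structure(list(
    assay = assay, a = a, b = b, r2 = r2, n_points = n_points,
    efficiency = 10^(-1 / a) - 1, genera_pooled = genera_pooled,
    points = points, valid = valid
  ), class = "nq_calibration_curve")
}

#' @export
print.nq_calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s: Ct = %.3f log10(N) + %.3f (R2 %s, eff %.0f%%)%s\n",
              x$assay, x$a, x$b,
              ifelse(is.na(x$r2), "?", sprintf("%.3f", x$r2)),
              100 * x$efficiency,
              if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Fit a calibration curve from a dilution series
#'
#' Ordinary least squares of Ct on log10(number of nematodes) over a
#' hand-picked dilution series (the standard protocol uses 1, 5, 10, 50
#' and 100 individuals; fractional counts from dilution series are
#' allowed).  R-squared is the squared Pearson correlation between
#' observed and fitted Ct, which stays meaningful with replicated
#' counts.
#'
#' @param series data frame with columns `n` (nematode count, > 0) and
#'   `ct` (cycles in (0, 60]); optional attributes/columns `assay`,
#'   `genus`.
#' @param assay,genus names, taken from `series` columns when absent.
#' @return an `nq_calibration_curve` carrying the raw points.
#' @examples
#' s <- data.frame(n = c(1, 5, 10, 50, 100))
#' s$ct <- -4.41 * log10(s$n) + 25.13
#' fit_calibration(s)
#' @export
fit_calibration <- function(series, assay = NULL, genus = NULL) {
  if (!all(c("n", "ct") %in% names(series))) {
    stop("series needs columns n and ct", call. = FALSE)
  }
  if (any(series$n <= 0)) stop("nematode counts must be positive", call. = FALSE)
  if (any(series$ct <= 0 | series$ct > 60)) {
    stop("Ct values must lie in (0, 60]", call. = FALSE)
  }
  if (length(unique(series$n)) < 2L) {
    stop("need >= 2 distinct nematode counts", call. = FALSE)
  }
  assay <- assay %||% series$assay[1] %||% NA_character_
  genus <- genus %||% series$genus[1] %||% NA_character_
  x <- log10(series$n)
  fit <- lm(series$ct ~ x)
  r2 <- if (sd(series$ct) == 0) 1 else cor(series$ct, fitted(fit))^2
  calibration_curve(
    assay = assay, a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
    r2 = r2, n_points = nrow(series),
    genera_pooled = if (is.na(genus)) character(0) else genus,
    points = data.frame(n = series$n, ct = series$ct,
                        genus = genus, stringsAsFactors = FALSE)
  )
}

#' Predict the Ct of a known number of target nematodes
#'
#' @param curve an `nq_calibration_curve`.
#' @param n number of nematodes (> 0, vectorised).
#' @return predicted Ct in cycles: `a * log10(n) + b`.
#' @examples
#' cv <- calibration_curve("Alaimidae", a = -3.31, b = 25.47)
#' predict_ct(cv, 1)   # the intercept
#' @export
predict_ct <- function(curve, n) {
  if (!inherits(curve, "nq_calibration_curve")) {
    stop("curve must be an nq_calibration_curve", call. = FALSE)
  }
  if (any(!is.finite(n) | n <= 0)) stop("n must be positive", call. = FALSE)
  curve$a * log10(n) + curve$b
}

#' Estimate nematode density from an observed Ct
#'
#' Inverts the calibration relation: N = 10^((Ct - b) / a).  Template
#' quantity is inversely proportional to Ct, so estimates follow by
#' direct comparison with the known standards behind the curve.  Ct
#' values at or beyond the no-signal cutoff (the protocol runs 60
#' cycles) are censored to zero rather than extrapolated; the
#' `censored` attribute flags them so downstream sums can propagate the
#' information.  `NA` Ct (no signal called by the instrument) is
#' treated the same way.
#'
#' @param curve a valid `nq_calibration_curve` (negative slope).
#' @param ct observed Ct, cycles (vectorised; `NA` = no signal).
#' @param cutoff no-signal cutoff in cycles (default 60).
#' @return numeric vector of estimated counts with logical attribute
#'   `censored`.
#' @export
estimate_density <- function(curve, ct, cutoff = 60) {
  if (!inherits(curve, "nq_calibration_curve")) {
    stop("curve must be an nq_calibration_curve", call. = FALSE)
  }
  if (!curve$valid) {
    stop("calibration curve for ", curve$assay,
         " is invalid (non-negative slope)", call. = FALSE)
  }
  censored <- is.na(ct) | ct >= cutoff
  out <- ifelse(censored, 0, 10^((ct - curve$b) / curve$a))
  attr(out, "censored") <- censored
  out
}

#' Pool genus-level calibration series into one family curve
#'
#' Family-level assays are calibrated from one or more genus-level
#' dilution series.  Only genera actually observed in the monitored
#' samples are retained -- body size and hence DNA content can differ
#' substantially between genera of one family, and including absent
#' genera would distort the family relation.  The pooled curve is
#' refitted on the union of the retained raw points (not by averaging
#' slopes), so its R-squared honestly reflects the between-genus spread.
#'
#' @param genus_curves list of `nq_calibration_curve` carrying raw
#'   points (as returned by [fit_calibration()]).
#' @param observed_genera character vector of genera observed in the
#'   samples.
#' @param assay name for the pooled curve (default from first curve).
#' @return an `nq_calibration_curve` with `genera_pooled` recording the
#'   retained genera.
#' @export
pool_family_curve <- function(genus_curves, observed_genera, assay = NULL) {
  genera <- vapply(genus_curves, function(cv) {
    if (length(cv$genera_pooled) > 0) cv$genera_pooled[1] else NA_character_
  }, "")
  keep <- which(genera %in% observed_genera)
  if (length(keep) == 0L) {
    stop("no calibration series for an observed genus", call. = FALSE)
  }
  pts <- do.call(rbind, lapply(genus_curves[keep], function(cv) {
    if (is.null(cv$points)) {
      stop("curve for ", cv$assay, " carries no raw points", call. = FALSE)
    }
    cv$points
  }))
  out <- fit_calibration(pts, assay = assay %||% genus_curves[[1]]$assay)
  out$genera_pooled <- unique(genera[keep])
  out
}
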