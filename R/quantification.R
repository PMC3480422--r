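# Quantification: environmental Ct panels -> community profiles,
# internal-standard correction, guild sums, coverage diagnostics.

#' Extraction-efficiency correction from the internal standard
#'
#' A fixed amount of mammalian DNA spiked into every sample before lysis
#' is quantified with its own primer combination; comparing its Ct with
#' the Ct of the same spike through a reference (complete-recovery)
#' extraction estimates the fraction of DNA lost in lysis/purification.
#' Under an amplification efficiency of `efficiency` (default 1, i.e.
#' doubling per cycle) the correction factor is
#' `(1 + efficiency)^(internal_ct - reference_ct)`: one cycle of delay
#' means half the DNA was recovered, so densities are multiplied by 2.
#'
#' @param internal_ct Ct of the internal standard in the sample (`NA`
#'   when missing: factor 1 with a warning).
#' @param reference_ct Ct of the same spike under complete recovery.
#' @param efficiency assumed per-cycle amplification efficiency.
#' @return multiplicative correction factor for all densities of the
#'   sample.
#' @export
correct_for_extraction <- function(internal_ct, reference_ct, efficiency = 1) {
  if (is.na(internal_ct) || is.null(internal_ct)) {
    warning("internal standard Ct missing; correction factor set to 1",
            call. = FALSE)
    return(1)
  }
  stopifnot_scalar_number(reference_ct, "reference_ct")
  (1 + efficiency)^(internal_ct - reference_ct)
}

#' Quantify a community profile from a sample's Ct panel
#'
#' Converts each assay's Ct into a density (individuals per 100 ml
#' elutriated soil) through its calibration curve, applies the
#' internal-standard extraction correction and the dilution adjustment,
#' and sums to a total.  No-signal assays (`NA` Ct or Ct at/after the
#' cutoff) contribute censored zeros, flagged rather than dropped.
#'
#' The dilution adjustment accounts for calibration lysates and field
#' lysates being assayed at different template dilutions (protocol
#' default: calibration at 1000x, environmental samples at 50x, hence
#' 20); it is deliberately exposed as an argument and recorded in the
#' profile.
#'
#' @param sample list or one-row data frame with `sample_id`, `site`,
#'   `week`, `cts` (named numeric vector, assay -> Ct, `NA` = no
#'   signal), `internal_standard_ct`.
#' @param curves named list of `nq_calibration_curve`, one per assay in
#'   `cts`.
#' @param reference_standard_ct Ct of the internal standard under
#'   complete recovery; `NULL` skips the correction (factor 1).
#' @param dilution_adjustment calibration-to-sample dilution ratio.
#' @param cutoff no-signal Ct cutoff (cycles).
#' @return an `nq_profile`: list with `sample_id`, `site`, `week`,
#'   `densities` (named vector), `censored` (named logical), `total`,
#'   `correction_factor`, `dilution_adjustment`.
#' @export
quantify_sample <- function(sample, curves, reference_standard_ct = NULL,
                            dilution_adjustment = 20, cutoff = 60) {
  cts <- sample$cts
  if (is.null(names(cts)) || length(cts) == 0L) {
    stop("sample$cts must be a named assay -> Ct vector", call. = FALSE)
  }
  missing_curves <- setdiff(names(cts), names(curves))
  if (length(missing_curves) > 0L) {
    stop("no calibration curve for assay(s): ",
         paste(missing_curves, collapse = ", "), call. = FALSE)
  }
  factor <- if (is.null(reference_standard_ct)) 1 else
    correct_for_extraction(sample$internal_standard_ct, reference_standard_ct)
  dens <- numeric(length(cts))
  cens <- logical(length(cts))
  for (i in seq_along(cts)) {
    est <- estimate_density(curves[[names(cts)[i]]], cts[[i]], cutoff = cutoff)
    cens[i] <- attr(est, "censored")
    dens[i] <- factor * dilution_adjustment * as.numeric(est)
  }
  names(dens) <- names(cens) <- names(cts)
  structure(list(
    sample_id = sample$sample_id %||% NA_character_,
    site = sample$site %||% NA_character_,
    week = sample$week %||% NA_integer_,
    densities = dens, censored = cens, total = sum(dens),
    correction_factor = factor, dilution_adjustment = dilution_adjustment
  ), class = "nq_profile")
}

#' @export
print.nq_profile <- function(x, ...) {
  cat(sprintf("<community profile> %s (%s, week %s): %d taxa, total %.1f per 100 ml\n",
              x$sample_id, x$site, x$week, length(x$densities), x$total))
  invisible(x)
}

#' Aggregate a community profile into feeding guilds
#'
#' Sums taxon densities into trophic guilds (bacterivores, fungivores,
#' omnivores, predators); guild sums always conserve the profile total.
#'
#' @param profile an `nq_profile`.
#' @param taxon_guilds named character vector taxon -> guild code.
#' @return named numeric vector of guild densities.
#' @export
aggregate_guilds <- function(profile, taxon_guilds) {
  taxa <- names(profile$densities)
  unmapped <- setdiff(taxa, names(taxon_guilds))
  if (length(unmapped) > 0L) {
    stop("no guild for taxa: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) == 0L) return(setNames(numeric(0), character(0)))
  sums <- tapply(profile$densities, taxon_guilds[taxa], sum)
  setNames(as.numeric(sums), names(sums))
}

#' Coverage of qPCR totals against microscopic counts
#'
#' If every taxon present were covered by an assay, the summed qPCR
#' densities would equal the microscopic total count.  The diagnostic
#' regresses log10(qPCR total) on log10(microscopy total): a slope
#' indistinguishable from one indicates allometrically faithful
#' coverage, and samples are expected to stay within +-0.5 log10 units
#' (half an order of magnitude) of the fitted trend, measured as
#' vertical distance.  Externally Studentized residuals flag outlying
#' samples (threshold |2|).
#'
#' @param pairs data frame with columns `microscopy` and `qpcr` (total
#'   individuals per sample by each method); non-positive totals are
#'   excluded with a warning.
#' @param band half-width of the acceptance band in log10 units.
#' @return an `nq_coverage`: list with `slope`, `intercept`, `slope_se`,
#'   `fraction_within_band`, `studentized_residuals`, `n`, `band`,
#'   `outliers` (|studentized| > 2).
#' @export
coverage_check <- function(pairs, band = 0.5) {
  if (!all(c("microscopy", "qpcr") %in% names(pairs))) {
    stop("pairs needs columns microscopy and qpcr", call. = FALSE)
  }
  ok <- pairs$microscopy > 0 & pairs$qpcr > 0
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with non-positive totals excluded",
            call. = FALSE)
    pairs <- pairs[ok, ]
  }
  if (nrow(pairs) < 3L) stop("need >= 3 positive pairs", call. = FALSE)
  x <- log10(pairs$microscopy)
  y <- log10(pairs$qpcr)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))    # quiet on numerically perfect fits
  resid_v <- y - fitted(fit)
  stud <- if (sd(resid_v) < 1e-10) rep(0, length(y)) else rstudent(fit)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_se = sm$coefficients[2, 2],
    fraction_within_band = mean(abs(resid_v) <= band),
    studentized_residuals = stud,
    outliers = which(abs(stud) > 2),
    n = nrow(pairs), band = band
  ), class = "nq_coverage")
}

#' @export
print.nq_coverage <- function(x, ...) {
  cat(sprintf(
    "<coverage> n=%d: slope %.3f +- %.3f, intercept %.3f, %.0f%% within +-%.1f log10\n",
    x$n, x$slope, x$slope_se, x$intercept,
    100 * x$fraction_within_band, x$band))
  invisible(x)
}
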