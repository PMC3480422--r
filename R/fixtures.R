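# Packaged fixtures: the genus occurrence survey and the assay
# calibration parameter table of the two-site seasonal monitoring study.

#' Packaged genus occurrence table
#'
#' The microscopy-based genus inventory of the monitored former arable
#' field and adjacent beech forest (sandy soils, Veluwe, NL): 45 genera
#' with their family, qPCR coverage and quantitative-range flags,
#' obligate-plant-parasite status, and per-habitat presence.
#'
#' @return an `nq_occurrence` table (see [load_occurrence_table()]).
#' @examples
#' occurrence_summary(occurrence_fixture())
#' @export
occurrence_fixture <- function() {
  load_occurrence_table(
    system.file("extdata", "genus_occurrence.csv", package = "nemaquant")
  )
}

#' Packaged assay calibration table
#'
#' The 15 monitored taxa (13 families, two of them split into genus
#' assays, plus one genus monitored separately from the rest of its
#' family) with their feeding guild, colonizer-persister score,
#' empirical specificity gap (delta Ct, `NA` when non-targets produced
#' no signal at all), calibration slope `a`, intercept `b`, R-squared,
#' and the number of genera pooled into the family curve.
#'
#' @return data frame with columns `assay, family, rank, guild,
#'   facultative_plant_parasite, cp, delta_ct, a, b, r2, n_genera`.
#' @export
calibration_fixture <- function() {
  read.csv(
    system.file("extdata", "assay_calibration.csv", package = "nemaquant"),
    stringsAsFactors = FALSE
  )
}

#' Calibration curves from the packaged assay table
#'
#' @return named list of `nq_calibration_curve`, one per assay.
#' @examples
#' predict_ct(fixture_curves()[["Alaimidae"]], 1)
#' @export
fixture_curves <- function() {
  tab <- calibration_fixture()
  setNames(lapply(seq_len(nrow(tab)), function(i) {
    calibration_curve(tab$assay[i], a = tab$a[i], b = tab$b[i],
                      r2 = tab$r2[i])
  }), tab$assay)
}

#' Guild map of the packaged assays
#'
#' @return named character vector assay -> guild code.
#' @export
fixture_guilds <- function() {
  tab <- calibration_fixture()
  setNames(tab$guild, tab$assay)
}
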