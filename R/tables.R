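#' Reported divergence-age tables for the reaction-center family
#'
#' Reference tables of reported mean ages (+/- sd, Ga) for the most
#' ancestral Type II node (II), the D1/D2 duplication (D0) and the
#' ancestral standard D1, with the reported Delta-T and its range, across
#' root-prior means (`scan = "rootPrior"`) or root-prior standard
#' deviations (`scan = "rootSd"`). They serve as regression fixtures for
#' the Delta-T arithmetic; the `flag` column marks rows whose printed
#' values are internally inconsistent (transposed or mistyped entries in
#' the source table), which the consistency checks treat separately.
#'
#' @param scan `"rootPrior"` or `"rootSd"`.
#' @return data.frame with columns `model`, `x` (root mean or sd, Ga),
#'   `ii_mean`, `ii_sd`, `d0_mean`, `d0_sd`, `sd1_mean`, `sd1_sd`, `dt`,
#'   `dt_high`, `dt_low`, `flag`.
#' @export
reportedAgeTable <- function(scan = c("rootPrior", "rootSd")) {
  scan <- match.arg(scan)
  f <- system.file("extdata",
                   if (scan == "rootPrior") "rc_reported_ages_root_prior.tsv"
                   else "rc_reported_ages_root_sd.tsv",
                   package = "photoclock")
  read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Recompute Delta-T and its range from a reported-age table
#'
#' Applies the Delta-T arithmetic (`d0_mean - sd1_mean`, with the +/- 1 sd
#' envelope range) to each row, for comparison against the reported
#' columns.
#'
#' @param tab a table from [reportedAgeTable()].
#' @return The table with `dt_calc`, `dt_high_calc`, `dt_low_calc` added.
#' @export
recomputeDeltaT <- function(tab) {
  tab$dt_calc <- tab$d0_mean - tab$sd1_mean
  tab$dt_high_calc <- (tab$d0_mean + tab$d0_sd) - (tab$sd1_mean - tab$sd1_sd)
  tab$dt_low_calc <- (tab$d0_mean - tab$d0_sd) - (tab$sd1_mean + tab$sd1_sd)
  tab
}

#' Packaged calibration profiles for the reaction-center fixture
#'
#' Two cross-calibrated profiles mirroring the published fossil
#' calibration set on the synthetic 74-taxon fixture of
#' [reactionCenterFixture()]: profile 1 puts the crown-Cyanobacteria
#' minimum at 2.45 Ga, profile 2 at 2.70 Ga. Soft bounds with 2.5% tail
#' mass per two-sided boundary and 5% for minimum-only bounds.
#'
#' @param profile 1 or 2.
#' @param rootMean,rootSd root prior (Ga).
#' @return A [CalibrationSet-class].
#' @export
fixtureCalibrations <- function(profile = 1, rootMean = 3.5, rootSd = 0.05) {
  f <- system.file("extdata",
                   sprintf("table5_calibration%d.txt", profile),
                   package = "photoclock")
  readCalibrations(f, rootMean = rootMean, rootSd = rootSd)
}
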