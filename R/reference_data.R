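# Bundled published reference table for the Poa alliance ITS analysis.

#' Published per-clade reference values for the Poa alliance
#'
#' The printed per-clade summary of the original bluegrass (*Poa* alliance)
#' ITS study: species numbers, nucleotide diversity with variance, crown
#' ages under the 20 and 25 Myr root calibrations with the 25 Myr 95% CI,
#' and crown-group net diversification rates (DR) under minimal and maximal
#' species numbers. These printed values serve as inputs for closed-form
#' reproduction checks: the DR, CI, extrapolated-richness and 20 Myr age
#' columns are all recomputable from the `n_min`, `n_max` and `age25`
#' columns (to printed precision; a handful of cells reflect the authors'
#' unrounded ages and differ by one unit in the last printed digit).
#'
#' The eight `Poa *` clades' `n_max` values are sampled-fraction
#' extrapolations (169 of ~500 *Poa* species sequenced); the other clades'
#' are literature species counts.
#'
#' @return A `data.frame` with one row per clade and columns `clade`,
#'   `n_min`, `n_max`, `n_seq`, `pi`, `var_pi`, `age20`, `dr20_min`,
#'   `dr20_max`, `age25`, `ci_low`, `ci_high`, `dr25_min`, `dr25_max`.
#' @export
poa_reference <- function() {
  path <- system.file("extdata", "poa_alliance_reference.tsv",
                      package = "radrate", mustWork = TRUE)
  read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
}

#' Calibration used by the Poa alliance study
#'
#' The secondary root calibration of the reference analysis: the
#' outgroup/ingroup split fixed at 25 Myr (conservative) or 20 Myr, with
#' the 95% CI 21.1-29.3 Myr attached to the 25 Myr calibration.
#'
#' @param root_age 25 (default) or 20.
#' @return A [calibration_spec()].
#' @export
poa_calibration <- function(root_age = 25) {
  if (root_age == 25) calibration_spec(25, 21.1, 29.3)
  else calibration_spec(root_age)
}
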