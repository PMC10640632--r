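#' Published validation recoveries for the five-analyte eye-drop assay
#'
#' Per-mixture validation recoveries reported for the original
#' instrument-based PLS and ANN calibrations of naphazoline HCl (NZ),
#' pheniramine maleate (PN) and their three official impurities. Shipped as
#' reference data so the package's summary arithmetic (mean +/- SD,
#' SEP/RMSEP and LOD/LOQ relations, t/F comparison) can be checked against
#' published results.
#'
#' @return Tibble with columns `mix`, `component`, `model` (`"pls"` or
#'   `"ann"`), `actual` (ug/mL) and `recovery` (%).
#' @export
reference_recoveries <- function() {
  path <- system.file("extdata", "reference_recoveries.csv", package = "specal")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published regression parameters of the validation sets
#'
#' Slope, intercept, correlation, LOD, LOQ, SEP and RMSEP per component and
#' model, as published for the same assay (see [reference_recoveries()]).
#'
#' @return Tibble with columns `component`, `model`, `slope`, `intercept`,
#'   `r`, `lod`, `loq`, `sep`, `rmsep`.
#' @export
reference_regression <- function() {
  path <- system.file("extdata", "reference_regression.csv", package = "specal")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published standard-addition recoveries in the dosage form
#'
#' Added-amount recoveries for NZ and PN spiked into the eye-drop matrix.
#'
#' @return Tibble with columns `model`, `component`, `taken`, `added`,
#'   `recovery`.
#' @export
reference_standard_addition <- function() {
  path <- system.file("extdata", "reference_standard_addition.csv",
                      package = "specal")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published method-comparison summaries
#'
#' Mean, SD and n of the chemometric models and of the official
#' chromatographic reference method for the two drugs, used for t/F
#' comparison.
#'
#' @return Tibble with columns `method`, `component`, `mean`, `sd`, `n`.
#' @export
reference_method_summaries <- function() {
  path <- system.file("extdata", "reference_method_summaries.csv",
                      package = "specal")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
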