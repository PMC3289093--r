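# Spectrophotometric chlorophyll quantification in 80% acetone extracts
# using MacKinney's absorbance coefficients at 645 and 663 nm.

#' Chlorophyll content from absorbance readings
#'
#' Extract concentrations (ug/mL) follow the MacKinney relations
#' `chl_a = 12.7 * OD663 - 2.69 * OD645` and
#' `chl_b = 22.9 * OD645 - 4.48 * OD663`, assuming a 1 cm path length.
#' Per-fresh-weight values scale by `volume_ml / mass_g` (the default
#' geometry, 1 mL of 80% acetone per 50 mg tissue, gives a factor of 20).
#' Readings implying a negative concentration are outside the model's
#' domain and are flagged invalid rather than truncated.
#'
#' @param od645,od663 Absorbance readings (vectorized, >= 0).
#' @param volume_ml Extraction volume (mL), > 0.
#' @param mass_g Tissue fresh weight (g), > 0.
#' @return A tibble: `chl_a_extract`, `chl_b_extract` (ug/mL), `chl_a_fw`,
#'   `chl_b_fw`, `total_fw` (ug/g FW), `ratio_ab` (NA when chlorophyll b is
#'   absent), `valid` (FALSE for readings outside the model's domain, whose
#'   per-FW values are NA).
#' @examples
#' od <- invert_mackinney(13.333, 3.887)
#' chlorophyll_from_od(od$od645, od$od663)  # total ~ 344.4 ug/g, a/b ~ 3.43
#' @export
chlorophyll_from_od <- function(od645, od663, volume_ml = 1.0, mass_g = 0.05) {
  if (any(volume_ml <= 0) || any(mass_g <= 0)) {
    stop("volume_ml and mass_g must be positive", call. = FALSE)
  }
  if (any(od645 < 0) || any(od663 < 0)) {
    stop("absorbance readings must be >= 0", call. = FALSE)
  }
  chl_a <- 12.7 * od663 - 2.69 * od645
  chl_b <- 22.9 * od645 - 4.48 * od663
  valid <- chl_a >= -1e-9 & chl_b >= -1e-9
  chl_a <- pmax(chl_a, 0) * ifelse(valid, 1, NA)
  chl_b <- pmax(chl_b, 0) * ifelse(valid, 1, NA)
  scale <- volume_ml / mass_g
  a_fw <- chl_a * scale
  b_fw <- chl_b * scale
  tibble::tibble(
    chl_a_extract = ifelse(valid, 12.7 * od663 - 2.69 * od645, NA_real_),
    chl_b_extract = ifelse(valid, 22.9 * od645 - 4.48 * od663, NA_real_),
    chl_a_fw = a_fw, chl_b_fw = b_fw,
    total_fw = a_fw + b_fw,
    ratio_ab = ifelse(valid & b_fw > 0, a_fw / b_fw, NA_real_),
    valid = valid)
}

#' Process a table of spectrophotometer readings
#'
#' @param readings Tibble with columns `sample_id`, `od645`, `od663` and
#'   optional `volume_ml`, `mass_g` (defaults 1 mL / 0.05 g).
#' @return The readings joined with the [chlorophyll_from_od()] results.
#' @export
pigment_table <- function(readings) {
  stopifnot(all(c("sample_id", "od645", "od663") %in% names(readings)))
  vol <- if ("volume_ml" %in% names(readings)) readings$volume_ml else rep(1.0, nrow(readings))
  mass <- if ("mass_g" %in% names(readings)) readings$mass_g else rep(0.05, nrow(readings))
  res <- chlorophyll_from_od(readings$od645, readings$od663, vol, mass)
  dplyr::bind_cols(readings[, c("sample_id", "od645", "od663")], res)
}
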