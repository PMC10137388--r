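#' Radical-scavenging inhibition percentage
#'
#' Converts DPPH/ABTS plate absorbances into percent inhibition:
#' `100 * (AbsRadical - (AbsSample - AbsControl)) / AbsRadical`, where
#' AbsRadical is the radical-only well, AbsSample the extract-plus-radical
#' well and AbsControl the extract-plus-ethanol well (corrects for the
#' extract's own absorbance). Invariant under a common rescaling of all
#' three absorbances.
#'
#' @param abs_radical Absorbance of the radical-only well (> 0).
#' @param abs_sample Absorbance of the sample + radical well.
#' @param abs_control Absorbance of the sample + ethanol well.
#' @return Percent inhibition (vectorised).
#' @examples
#' inhibition_percent(0.9, 0.5, 0.05) # 50
#' @export
inhibition_percent <- function(abs_radical, abs_sample, abs_control) {
  if (any(abs_radical <= 0)) {
    stop("`abs_radical` must be positive", call. = FALSE)
  }
  100 * (abs_radical - (abs_sample - abs_control)) / abs_radical
}

#' Average a dose-response series into a curve
#'
#' Collapses replicate inhibition readings into one mean inhibition per
#' concentration, sorted by concentration. By default the origin (zero
#' concentration, zero inhibition) is prepended as an anchor: the assay's
#' radical-only well defines 0% inhibition at zero dose, which lets
#' [estimate_icx()] bracket inhibition levels below the lowest tested
#' concentration (needed e.g. for potent reference antioxidants).
#'
#' @param concentration Concentrations (ug/mL).
#' @param inhibition Percent inhibition (same length).
#' @param include_origin Prepend the (0, 0) anchor point (default `TRUE`).
#' @return A tibble with `concentration` (strictly increasing) and
#'   `inhibition` (replicate mean).
#' @export
dose_response_curve <- function(concentration, inhibition,
                                include_origin = TRUE) {
  stopifnot(length(concentration) == length(inhibition))
  if (any(concentration < 0)) stop("concentrations must be non-negative", call. = FALSE)
  curve <- tibble::tibble(concentration = concentration,
                          inhibition = inhibition) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(inhibition = mean(.data$inhibition), .groups = "drop") |>
    dplyr::arrange(.data$concentration)
  if (include_origin && !any(curve$concentration == 0)) {
    curve <- dplyr::bind_rows(
      tibble::tibble(concentration = 0, inhibition = 0), curve)
  }
  curve
}

#' Inhibitory concentration ICx by linear interpolation
#'
#' The concentration producing `x` percent inhibition, found by piecewise
#' linear interpolation between the two adjacent observed points bracketing
#' `x`. No extrapolation is performed: when the curve never reaches `x`
#' within the observed range (e.g. extracts that never exceed ~10%
#' inhibition), the ICx is "not reached" and `NA` is returned rather than an
#' error. A point lying exactly at `x` returns its concentration.
#'
#' @param curve A tibble from [dose_response_curve()] (columns
#'   `concentration`, `inhibition`, concentration strictly increasing).
#' @param x Target inhibition percentage (e.g. 20 or 50).
#' @return The interpolated concentration (ug/mL), or `NA_real_` if `x` is
#'   not bracketed by the observed inhibitions.
#' @examples
#' estimate_icx(dose_response_curve(c(100, 200), c(10, 30),
#'                                  include_origin = FALSE), 20) # 150
#' @export
estimate_icx <- function(curve, x) {
  stopifnot(all(c("concentration", "inhibition") %in% names(curve)),
            is.numeric(x), length(x) == 1)
  conc <- curve$concentration
  inh <- curve$inhibition
  if (is.unsorted(conc, strictly = TRUE)) {
    stop("curve concentrations must be strictly increasing", call. = FALSE)
  }
  exact <- which(inh == x)
  if (length(exact) > 0) return(conc[exact[1]])
  crosses <- which((inh[-length(inh)] - x) * (inh[-1] - x) < 0)
  if (length(crosses) == 0) return(NA_real_) # not reached within range
  i <- crosses[1]
  conc[i] + (x - inh[i]) * (conc[i + 1] - conc[i]) / (inh[i + 1] - inh[i])
}

#' Trolox-equivalent antioxidant activity
#'
#' Expresses an extract's scavenging activity relative to Trolox, using the
#' ICx of the extract and of Trolox measured in the same assay batch:
#' `TE = (ICx_Trolox / ICx_sample) * 1e6 / molar_mass` umol Trolox per gram
#' of extract. Both ICx values are mass concentrations (ug/mL); the factor
#' `1e6 / molar_mass` converts the Trolox mass ratio into micromoles per
#' gram (250.29 g/mol for Trolox). For two extracts sharing a Trolox
#' calibration, `TE1 * IC1 = TE2 * IC2` (cross-ratio identity).
#'
#' @param icx_sample ICx of the extract (ug/mL), positive.
#' @param icx_trolox ICx of Trolox at the same inhibition level (ug/mL),
#'   positive.
#' @param molar_mass Molar mass of the reference antioxidant (g/mol;
#'   default Trolox, 250.29).
#' @return Activity in umol Trolox per g of extract.
#' @export
trolox_equivalents <- function(icx_sample, icx_trolox, molar_mass = 250.29) {
  if (any(icx_sample <= 0) || any(icx_trolox <= 0)) {
    stop("ICx values must be positive", call. = FALSE)
  }
  (icx_trolox / icx_sample) * 1e6 / molar_mass
}

#' COX-2 inhibition percentage
#'
#' Percent inhibition of cyclooxygenase-2 from the prostaglandin readout:
#' `100 * (1 - activity_sample / activity_reference)`, where the reference
#' is the uninhibited (100% activity) well.
#'
#' @param activity_sample Prostaglandin readout with extract present.
#' @param activity_reference Uninhibited reference readout (> 0).
#' @return Percent COX-2 inhibition (vectorised).
#' @export
cox2_inhibition <- function(activity_sample, activity_reference) {
  if (any(activity_reference <= 0)) {
    stop("`activity_reference` must be positive", call. = FALSE)
  }
  100 * (1 - activity_sample / activity_reference)
}

#' Read a plate-layout assay file
#'
#' Long-format delimited file with columns `assay`, `extract`,
#' `concentration`, `replicate`, `abs_radical`, `abs_sample`, `abs_control`.
#'
#' @param file Path to the delimited file.
#' @return A tibble.
#' @export
read_assay_plate <- function(file) {
  delim <- if (grepl("\\.tsv$", file)) "\t" else ","
  readr::read_delim(file, delim = delim, show_col_types = FALSE)
}

#' Summarise an assay plate into ICx and Trolox-equivalent values
#'
#' Computes inhibition percentages per well, averages replicates into a
#' dose-response curve per extract, interpolates the requested ICx, and, if
#' the plate contains a `"Trolox"` extract, converts to Trolox equivalents.
#'
#' @param plate A tibble as returned by [read_assay_plate()] (one assay).
#' @param x Target inhibition percentage (default 20).
#' @param trolox_id Extract identifier of the Trolox calibration series.
#' @return A tibble with one row per extract: `extract`, `icx`, `te`
#'   (`NA` where the level is not reached).
#' @export
assay_icx_table <- function(plate, x = 20, trolox_id = "Trolox") {
  stopifnot(length(unique(plate$assay)) == 1)
  plate <- dplyr::mutate(
    plate,
    inhibition = inhibition_percent(.data$abs_radical, .data$abs_sample,
                                    .data$abs_control))
  icx <- plate |>
    dplyr::group_by(.data$extract) |>
    dplyr::group_modify(function(d, key) {
      curve <- dose_response_curve(d$concentration, d$inhibition)
      tibble::tibble(icx = estimate_icx(curve, x))
    }) |>
    dplyr::ungroup()
  icx_trolox <- icx$icx[icx$extract == trolox_id]
  out <- dplyr::filter(icx, .data$extract != trolox_id)
  out$te <- NA_real_
  if (length(icx_trolox) == 1 && !is.na(icx_trolox)) {
    ok <- !is.na(out$icx)
    out$te[ok] <- trolox_equivalents(out$icx[ok], icx_trolox)
  }
  out
}
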