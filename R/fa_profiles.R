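#' Relative-abundance fatty-acid profiles from GC-MS peak areas
#'
#' Converts integrated FAME peak areas into per-sample relative abundances.
#' Each analyte area is first normalized by the internal-standard (IS) area of
#' its sample and then expressed as a percentage of the summed normalized
#' areas, so the IS cancels algebraically and the result equals the percent of
#' total non-IS area. The IS row itself never enters the total.
#'
#' @param peaks A tibble in long format with columns `sample_id`, `fa`
#'   (shorthand, see [parse_fa_shorthand()]), `area`, and a logical
#'   `is_standard` column flagging the internal-standard row of each sample.
#' @return A tibble with columns `sample_id`, `fa`, the parsed identity
#'   columns (`carbons`, `double_bonds`, `omega_family`, `saturation_class`)
#'   and `abundance` (percent of total FA signal; sums to 100 per sample).
#'   Any extra grouping columns in `peaks` (e.g. `strain`) are carried along.
#' @export
fa_relative_abundance <- function(peaks) {
  required <- c("sample_id", "fa", "area", "is_standard")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("`peaks` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(peaks$area < 0)) stop("peak areas must be non-negative", call. = FALSE)

  is_rows <- dplyr::filter(peaks, .data$is_standard)
  if (any(is_rows$area <= 0)) {
    bad <- unique(is_rows$sample_id[is_rows$area <= 0])
    stop("internal-standard area is zero for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  analytes <- dplyr::filter(peaks, !.data$is_standard)
  if (nrow(analytes) == 0) stop("no analyte rows in `peaks`", call. = FALSE)

  is_area <- dplyr::select(is_rows, "sample_id", is_area = "area")
  out <- analytes |>
    dplyr::left_join(is_area, by = "sample_id") |>
    dplyr::mutate(norm_area = .data$area / .data$is_area) |>
    dplyr::group_by(.data$sample_id)
  totals <- dplyr::summarise(out, total = sum(.data$norm_area))
  if (any(totals$total <= 0 | is.na(totals$total))) {
    bad <- totals$sample_id[totals$total <= 0 | is.na(totals$total)]
    stop("all analyte areas are zero (or IS missing) for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(abundance = 100 * .data$norm_area / sum(.data$norm_area)) |>
    dplyr::ungroup() |>
    dplyr::select(-"area", -"is_area", -"norm_area", -"is_standard")

  parsed <- parse_fa_shorthand(out$fa)
  dplyr::bind_cols(
    dplyr::select(out, -"abundance"),
    dplyr::select(parsed, -"shorthand"),
    abundance = out$abundance
  ) |>
    dplyr::mutate(fa = parsed$shorthand)
}

#' Saturation-class, omega-family and unsaturation-bin sums
#'
#' Summarises a fatty-acid profile into the class totals conventionally
#' reported alongside FA composition tables: sums of saturated (SFA),
#' monounsaturated (MUFA) and polyunsaturated (PUFA) fatty acids; the omega-3
#' and omega-6 totals over PUFA members; and percentages binned by
#' double-bond count (monoenoic through hexaenoic), which feed the
#' peroxidation index.
#'
#' @param profile A tibble as returned by [fa_relative_abundance()] (needs
#'   `sample_id`, `double_bonds`, `omega_family`, `saturation_class`,
#'   `abundance`).
#' @return One row per sample: `sfa`, `mufa`, `pufa`, `n3`, `n6`, and
#'   `monoenoic` ... `hexaenoic` percentages. `sfa + mufa + pufa` always
#'   equals the profile total (100 for a closed profile).
#' @export
fa_class_sums <- function(profile) {
  stopifnot(all(c("sample_id", "double_bonds", "omega_family",
                  "saturation_class", "abundance") %in% names(profile)))
  bin_names <- c("monoenoic", "dienoic", "trienoic", "tetraenoic",
                 "pentaenoic", "hexaenoic")
  profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      sfa = sum(.data$abundance[.data$saturation_class == "SFA"]),
      mufa = sum(.data$abundance[.data$saturation_class == "MUFA"]),
      pufa = sum(.data$abundance[.data$saturation_class == "PUFA"]),
      n3 = sum(.data$abundance[.data$saturation_class == "PUFA" &
                                 .data$omega_family == "n-3"]),
      n6 = sum(.data$abundance[.data$saturation_class == "PUFA" &
                                 .data$omega_family == "n-6"]),
      !!!stats::setNames(
        lapply(1:6, function(k) {
          rlang::quo(sum(.data$abundance[.data$double_bonds == !!k]))
        }),
        bin_names
      ),
      .groups = "drop"
    )
}

#' Gravimetric lipid extraction yield
#'
#' Yield of total lipid extract as a percentage of dry biomass weight:
#' `100 * extract_mg / biomass_mg`.
#'
#' @param extract_mg Weight of the dried lipid extract (mg), non-negative.
#' @param biomass_mg Weight of dry biomass extracted (mg), positive.
#' @return Yield in percent of dry weight.
#' @examples
#' lipid_yield(1.845, 25) # 7.38
#' @export
lipid_yield <- function(extract_mg, biomass_mg) {
  if (any(biomass_mg <= 0)) stop("`biomass_mg` must be positive", call. = FALSE)
  if (any(extract_mg < 0)) stop("`extract_mg` must be non-negative", call. = FALSE)
  100 * extract_mg / biomass_mg
}

#' Read a long-format FA peak table
#'
#' Reads a delimited file with columns `sample_id`, `fa`, `area` and
#' `is_standard` (logical or 0/1), one internal-standard row per sample.
#'
#' @param file Path to a CSV/TSV file (delimiter guessed by extension).
#' @return A tibble suitable for [fa_relative_abundance()].
#' @export
read_fa_peaks <- function(file) {
  delim <- if (grepl("\\.tsv$", file)) "\t" else ","
  peaks <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
  peaks$is_standard <- as.logical(peaks$is_standard)
  peaks
}

#' Per-group mean and SD composition table
#'
#' Collapses per-replicate fatty-acid profiles into the wide
#' "mean ± SD per strain" layout used in composition reports.
#'
#' @param profile Long profile tibble with a grouping column.
#' @param group Name of the grouping column (default `"strain"`).
#' @param value Name of the value column (default `"abundance"`).
#' @param feature Name of the feature column (default `"fa"`).
#' @param digits Decimal places for display (default 1).
#' @return A wide tibble, one row per feature, one `mean ± sd` character
#'   column per group.
#' @export
fa_summary_table <- function(profile, group = "strain", value = "abundance",
                             feature = "fa", digits = 1) {
  profile |>
    dplyr::group_by(.data[[group]], .data[[feature]]) |>
    dplyr::summarise(
      cell = sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                     mean(.data[[value]]), stats::sd(.data[[value]])),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(group),
                       values_from = "cell")
}
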