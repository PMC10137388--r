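#' Reference fatty-acid composition of four Chlorella vulgaris strains
#'
#' Strain-mean fatty-acid compositions (percent of total FA signal, mean and
#' SD over five replicates) reported for four edible *Chlorella vulgaris*
#' strains: one autotrophic (C-Auto) and three heterotrophic (C-Hetero,
#' C-Honey, C-White). Fourteen fatty acids were identified in all strains.
#' These values serve two purposes: as a worked reference panel for the
#' nutritional quality indices, and as the default templates of
#' [generate_fa_table()].
#'
#' @return A tibble with columns `strain`, `fa` (canonical shorthand),
#'   `mean_pct` and `sd_pct`.
#' @export
reference_fa_profiles <- function() {
  fa <- c("C14:0", "C15:0", "C16:0", "C16:1(n-9)", "C16:1(n-7)",
          "C16:2(n-6)", "C17:0", "C16:3(n-3)", "C18:0", "C18:1(n-9)",
          "C18:1(n-7)", "C18:2(n-6)", "C18:3(n-3)", "C20:0")
  vals <- list(
    `C-Auto` = list(
      mean = c(0.2, 0.4, 15.6, 1.1, 2.9, 7.2, 0.7, 14.8, 5.5, 4.5, 2.7, 18.0, 26.3, 0.1),
      sd   = c(0.0, 0.0, 0.3, 0.0, 0.1, 0.2, 0.0, 0.5, 2.4, 0.4, 0.1, 0.5, 0.8, 0.0)),
    `C-Hetero` = list(
      mean = c(0.2, 0.1, 23.7, 2.1, 0.2, 7.1, 0.3, 3.4, 5.6, 16.6, 0.8, 32.7, 6.9, 0.2),
      sd   = c(0.0, 0.0, 0.4, 0.0, 0.0, 0.2, 0.0, 0.1, 2.2, 0.7, 0.1, 0.7, 0.1, 0.0)),
    `C-Honey` = list(
      mean = c(0.2, 0.1, 24.7, 2.7, 0.2, 3.8, 0.8, 4.7, 9.6, 18.0, 0.4, 25.5, 9.0, 0.4),
      sd   = c(0.0, 0.0, 0.4, 0.1, 0.0, 0.2, 1.0, 0.3, 0.4, 0.2, 0.0, 0.3, 0.2, 0.0)),
    `C-White` = list(
      mean = c(0.2, 0.1, 26.3, 2.8, 0.1, 8.6, 0.2, 1.0, 12.7, 15.3, 0.3, 30.5, 1.8, 0.2),
      sd   = c(0.0, 0.0, 0.6, 0.2, 0.0, 0.6, 0.0, 0.1, 3.4, 0.8, 0.1, 1.8, 0.1, 0.1))
  )
  purrr::imap_dfr(vals, function(v, strain) {
    tibble::tibble(strain = strain, fa = fa, mean_pct = v$mean, sd_pct = v$sd)
  })
}

#' Reference antioxidant-activity results for the four strains
#'
#' Interpolated inhibitory concentrations (IC20 or IC50, ug/mL of lipid
#' extract) and the corresponding Trolox-equivalent activities (umol Trolox
#' per g extract) reported for DPPH and ABTS radical-scavenging assays on the
#' four strains' lipid extracts. Strains whose extracts never exceeded ~10%
#' inhibition have no ICx (`NA`). Used as generator defaults and to fix the
#' Trolox-equivalent unit convention (see [trolox_equivalents()]).
#'
#' @return A tibble with columns `assay`, `strain`, `x` (the inhibition level
#'   of the ICx), `icx_ug_ml`, `te_umol_g`.
#' @export
reference_antioxidant_results <- function() {
  tibble::tribble(
    ~assay,  ~strain,    ~x, ~icx_ug_ml, ~te_umol_g,
    "DPPH",  "C-Auto",   20,      108.2,       93.1,
    "DPPH",  "C-Honey",  20,      228.9,       44.0,
    "DPPH",  "C-Hetero", NA,         NA,         NA,
    "DPPH",  "C-White",  NA,         NA,         NA,
    "ABTS",  "C-Auto",   50,      230.7,      854.0,
    "ABTS",  "C-Hetero", 20,      190.7,       42.1,
    "ABTS",  "C-Honey",  20,      147.4,       53.8,
    "ABTS",  "C-White",  NA,         NA,         NA
  )
}

#' Reference COX-2 inhibition of the four strains' lipid extracts
#'
#' Mean and SD (n = 3) percentage inhibition of cyclooxygenase-2 at
#' 125 ug/mL of lipid extract.
#'
#' @return A tibble with columns `strain`, `mean_pct`, `sd_pct`.
#' @export
reference_cox2_results <- function() {
  tibble::tribble(
    ~strain,    ~mean_pct, ~sd_pct,
    "C-Auto",        79.1,     7.7,
    "C-Hetero",      76.8,     5.9,
    "C-Honey",       13.6,    10.5,
    "C-White",       34.9,     1.5
  )
}
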