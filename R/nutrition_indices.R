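#' @name nutrition-indices
#' @title Lipid nutritional quality indices
#'
#' @description
#' Composition-based indices of the nutritional and oxidative quality of a
#' fatty-acid profile, computed from relative abundances (percent of total
#' FA). All take a single-sample profile tibble as returned by
#' [fa_relative_abundance()] (or any tibble with columns `fa` and
#' `abundance`; identities are re-parsed from `fa`).
#'
#' * `atherogenic_index()` (AI), after Ulbricht and Southgate:
#'   `[C12:0 + 4*C14:0 + C16:0] / [MUFA + n-6 + n-3]`.
#' * `thrombogenic_index()` (TI):
#'   `[C14:0 + C16:0 + C18:0] /
#'    [0.5*MUFA + 0.5*n-6 + 3*n-3 + (n-3)/(n-6)]`.
#' * `hypo_hyper_ratio()` (h/H), the
#'   hypocholesterolemic/hypercholesterolemic ratio:
#'   `[cis-C18:1 + PUFA] / [C12:0 + C14:0 + C16:0]`, where cis-C18:1 is the
#'   sum of all C18:1 isomers present (n-9 plus n-7).
#' * `peroxidation_index()` (PoxI), an unsaturation-weighted susceptibility
#'   score: `0.025*monoenoic + 1*dienoic + 2*trienoic + 4*tetraenoic +
#'   6*pentaenoic + 8*hexaenoic` (percent in each double-bond bin).
#' * `omega_ratio()`: the n-6/n-3 ratio.
#'
#' Fatty acids absent from the profile (e.g. C12:0 in a panel without lauric
#' acid) contribute zero to every term, so the indices are computable on any
#' panel. AI, TI, h/H and the n-6/n-3 ratio are ratios of linear forms and
#' therefore invariant under a uniform rescaling of all abundances; PoxI is
#' homogeneous of degree one.
#'
#' @param profile A one-sample tibble with columns `fa` and `abundance`.
#' @return A single numeric value.
NULL

index_terms <- function(profile) {
  stopifnot(all(c("fa", "abundance") %in% names(profile)))
  parsed <- parse_fa_shorthand(profile$fa)
  ab <- profile$abundance
  comp <- function(carbons, db) {
    sum(ab[parsed$carbons == carbons & parsed$double_bonds == db])
  }
  bins <- vapply(1:6, function(k) sum(ab[parsed$double_bonds == k]), numeric(1))
  list(
    c12_0 = comp(12, 0), c14_0 = comp(14, 0), c16_0 = comp(16, 0),
    c18_0 = comp(18, 0),
    c18_1 = comp(18, 1), # all C18:1 isomers
    mufa = sum(ab[parsed$saturation_class == "MUFA"]),
    pufa = sum(ab[parsed$saturation_class == "PUFA"]),
    n3 = sum(ab[parsed$saturation_class == "PUFA" & parsed$omega_family == "n-3"]),
    n6 = sum(ab[parsed$saturation_class == "PUFA" & parsed$omega_family == "n-6"]),
    bins = bins
  )
}

#' @rdname nutrition-indices
#' @export
atherogenic_index <- function(profile) {
  t <- index_terms(profile)
  denom <- t$mufa + t$n6 + t$n3
  if (denom <= 0) {
    stop("atherogenic index undefined: MUFA + n-6 + n-3 is zero", call. = FALSE)
  }
  (t$c12_0 + 4 * t$c14_0 + t$c16_0) / denom
}

#' @rdname nutrition-indices
#' @export
thrombogenic_index <- function(profile) {
  t <- index_terms(profile)
  if (t$n6 <= 0) {
    stop("thrombogenic index undefined: the (n-3)/(n-6) term requires a ",
         "non-zero n-6 total", call. = FALSE)
  }
  denom <- 0.5 * t$mufa + 0.5 * t$n6 + 3 * t$n3 + t$n3 / t$n6
  if (denom <= 0) stop("thrombogenic index denominator is zero", call. = FALSE)
  (t$c14_0 + t$c16_0 + t$c18_0) / denom
}

#' @rdname nutrition-indices
#' @export
hypo_hyper_ratio <- function(profile) {
  t <- index_terms(profile)
  denom <- t$c12_0 + t$c14_0 + t$c16_0
  if (denom <= 0) {
    stop("h/H ratio undefined: C12:0 + C14:0 + C16:0 is zero", call. = FALSE)
  }
  (t$c18_1 + t$pufa) / denom
}

#' @rdname nutrition-indices
#' @export
peroxidation_index <- function(profile) {
  t <- index_terms(profile)
  sum(t$bins * c(0.025, 1, 2, 4, 6, 8))
}

#' @rdname nutrition-indices
#' @export
omega_ratio <- function(profile) {
  t <- index_terms(profile)
  if (t$n3 <= 0) stop("n-6/n-3 ratio undefined: n-3 total is zero", call. = FALSE)
  t$n6 / t$n3
}

#' All five quality indices for a set of profiles
#'
#' Computes the n-6/n-3 ratio, atherogenic index, thrombogenic index, h/H
#' ratio and peroxidation index per sample. Indices are computed per
#' replicate; group-level values should be summarised as mean ± SD over
#' replicates afterwards (see [fa_summary_table()]), not computed on a mean
#' profile.
#'
#' @param profile A long profile tibble (`sample_id`, `fa`, `abundance`, plus
#'   any grouping columns, which are carried through).
#' @param digits Optional rounding for reporting; `NULL` (default) keeps full
#'   precision.
#' @return One row per sample with columns `n6_n3`, `ai`, `ti`, `hh`, `poxi`.
#' @export
quality_indices <- function(profile, digits = NULL) {
  extra <- intersect(c("strain", "group"), names(profile))
  out <- profile |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", extra)))) |>
    dplyr::group_modify(function(p, key) {
      tibble::tibble(
        n6_n3 = omega_ratio(p),
        ai = atherogenic_index(p),
        ti = thrombogenic_index(p),
        hh = hypo_hyper_ratio(p),
        poxi = peroxidation_index(p)
      )
    }) |>
    dplyr::ungroup()
  if (!is.null(digits)) {
    out <- dplyr::mutate(
      out, dplyr::across(c("n6_n3", "ai", "ti", "hh", "poxi"), ~ round(.x, digits)))
  }
  out
}
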