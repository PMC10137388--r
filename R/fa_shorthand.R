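#' Parse fatty-acid shorthand notation
#'
#' Parses identifiers of the form `C<carbons>:<double bonds>` with an optional
#' omega-family suffix `(n-k)`, as used in GC-MS FAME reports (e.g.
#' `"C18:3(n-3)"`, `"C16:0"`). Both the ASCII hyphen and the Unicode minus
#' (U+2212) are accepted in the omega suffix; the canonical form emitted in
#' the `shorthand` column always uses the ASCII hyphen. Whitespace between the
#' `C:DB` part and the suffix is tolerated.
#'
#' The saturation class follows the standard convention: SFA for zero double
#' bonds, MUFA for exactly one, PUFA for two or more.
#'
#' @param x Character vector of shorthand identifiers.
#' @return A tibble with one row per input: `shorthand` (canonical form),
#'   `carbons`, `double_bonds`, `omega_family` (one of `"n-3"`, `"n-6"`,
#'   `"n-7"`, `"n-9"`, `"none"`), and `saturation_class` (`"SFA"`, `"MUFA"`,
#'   `"PUFA"`).
#' @examples
#' parse_fa_shorthand(c("C18:3(n-3)", "C16:0"))
#' @export
parse_fa_shorthand <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  norm <- normalize_minus(x)
  m <- regexec("^\\s*C(\\d+):(\\d+)\\s*(?:\\(n-(\\d+)\\))?\\s*$", norm)
  parts <- regmatches(norm, m)
  bad <- lengths(parts) == 0
  if (any(bad)) {
    stop("malformed fatty-acid shorthand: ",
         paste(sQuote(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  carbons <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  db <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  fam_k <- vapply(parts, function(p) p[4], character(1))
  omega_family <- ifelse(fam_k == "", "none", paste0("n-", fam_k))
  if (any(carbons <= 0)) {
    stop("carbon number must be positive in: ",
         paste(sQuote(x[carbons <= 0]), collapse = ", "), call. = FALSE)
  }
  if (any(db == 0 & omega_family != "none")) {
    stop("a saturated fatty acid cannot carry an omega-family suffix: ",
         paste(sQuote(x[db == 0 & omega_family != "none"]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    shorthand = format_fa_shorthand(carbons, db, omega_family),
    carbons = carbons,
    double_bonds = db,
    omega_family = omega_family,
    saturation_class = saturation_class(db)
  )
}

#' Canonical fatty-acid shorthand
#'
#' Formats parsed fatty-acid identities back into canonical shorthand with
#' ASCII hyphens, the inverse of [parse_fa_shorthand()].
#'
#' @param carbons Integer vector of chain lengths.
#' @param double_bonds Integer vector of double-bond counts.
#' @param omega_family Character vector (`"n-3"` etc., or `"none"`).
#' @return Character vector of canonical shorthand.
#' @export
format_fa_shorthand <- function(carbons, double_bonds, omega_family = "none") {
  suffix <- ifelse(omega_family == "none", "", paste0("(", omega_family, ")"))
  paste0("C", carbons, ":", double_bonds, suffix)
}

saturation_class <- function(double_bonds) {
  dplyr::case_when(
    double_bonds == 0 ~ "SFA",
    double_bonds == 1 ~ "MUFA",
    TRUE ~ "PUFA"
  )
}

# U+2212 (minus) and U+2013 (en dash) occasionally leak out of typeset tables
normalize_minus <- function(x) {
  gsub("−|–", "-", x)
}
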