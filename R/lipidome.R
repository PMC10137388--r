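#' Lipid classes recognised by the lipidome tools
#'
#' Glycolipids (MGDG, DGDG, SQDG), phospholipids (PC, LPC, PE, PG, PI),
#' ceramides (Cer) and neutral lipids (DG, TG).
#'
#' @return Character vector of class abbreviations.
#' @export
lipid_classes <- function() {
  c("MGDG", "DGDG", "SQDG", "PC", "LPC", "PE", "PG", "PI", "Cer", "DG", "TG")
}

glycolipid_classes <- function() c("MGDG", "DGDG", "SQDG")
phospholipid_classes <- function() c("PC", "LPC", "PE", "PG", "PI")

#' Parse lipid-species shorthand
#'
#' Parses identifiers of the form `CLASS(C:DB)` with an optional trailing
#' variant letter distinguishing acyl-combination isomers, e.g.
#' `"MGDG(34:1)"`, `"TG(52:2) B"`. Whitespace around the parenthesis is
#' tolerated.
#'
#' @param x Character vector of species identifiers.
#' @return A tibble with columns `shorthand` (canonical `CLASS(C:DB)` plus
#'   variant letter where present), `lipid_class`, `total_carbons`,
#'   `total_db`, `variant` (`NA` when absent).
#' @examples
#' parse_lipid_shorthand(c("MGDG(34:1)", "TG(52:2) B"))
#' @export
parse_lipid_shorthand <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  m <- regexec("^\\s*([A-Za-z]+)\\s*\\((\\d+):(\\d+)\\)\\s*([A-Z])?\\s*$", x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) == 0
  if (any(bad)) {
    stop("malformed lipid shorthand: ", paste(sQuote(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  cls <- vapply(parts, function(p) p[2], character(1))
  unknown <- !cls %in% lipid_classes()
  if (any(unknown)) {
    stop("unknown lipid class in ",
         paste(sQuote(x[unknown]), collapse = ", "),
         "; accepted classes: ", paste(lipid_classes(), collapse = ", "),
         call. = FALSE)
  }
  carbons <- vapply(parts, function(p) as.integer(p[3]), integer(1))
  db <- vapply(parts, function(p) as.integer(p[4]), integer(1))
  variant <- vapply(parts, function(p) if (p[5] == "") NA_character_ else p[5],
                    character(1))
  tibble::tibble(
    shorthand = paste0(cls, "(", carbons, ":", db, ")",
                       ifelse(is.na(variant), "", paste0(" ", variant))),
    lipid_class = cls,
    total_carbons = carbons,
    total_db = db,
    variant = variant
  )
}

#' Assemble a lipidome peak-table object
#'
#' Bundles a species table, its raw peak-area matrix and the spiked
#' internal-standard information into a `lipidome` list used by the
#' normalization and aggregation steps.
#'
#' @param species Tibble with columns `species` (shorthand), `rt` (retention
#'   time, minutes); identity columns are derived via
#'   [parse_lipid_shorthand()].
#' @param areas Numeric matrix of raw peak areas, rows = species (in the
#'   order of `species$species`), columns = samples (named).
#' @param standards Tibble with columns `name`, `rt`, `amount_ug`.
#' @param standard_areas Numeric matrix of internal-standard peak areas,
#'   rows = standards (order of `standards$name`), columns matching `areas`.
#' @return A list of class `lipidome` with elements `species`, `areas`,
#'   `standards`, `standard_areas`.
#' @export
lipidome <- function(species, areas, standards, standard_areas) {
  stopifnot(nrow(species) == nrow(areas),
            nrow(standards) == nrow(standard_areas),
            identical(colnames(areas), colnames(standard_areas)),
            all(areas >= 0), all(standard_areas > 0),
            all(standards$amount_ug > 0))
  parsed <- parse_lipid_shorthand(species$species)
  species <- dplyr::bind_cols(
    dplyr::select(species, "species", "rt"),
    dplyr::select(parsed, -"shorthand")
  )
  rownames(areas) <- species$species
  rownames(standard_areas) <- standards$name
  structure(
    list(species = species, areas = areas, standards = standards,
         standard_areas = standard_areas),
    class = "lipidome"
  )
}

#' Match each species to its internal standard by retention time
#'
#' Each lipid species is normalized against the internal standard eluting
#' closest to it; the assignment is purely by retention time, not by lipid
#' class. Ties are broken toward the lower-RT standard (deterministic).
#'
#' @param species_rt Numeric vector of species retention times (minutes).
#' @param standards Tibble with columns `name` and `rt`.
#' @return Character vector: the assigned standard name per species.
#' @export
assign_internal_standard <- function(species_rt, standards) {
  if (nrow(standards) == 0) stop("no internal standards supplied", call. = FALSE)
  ord <- order(standards$rt)
  std_rt <- standards$rt[ord]
  std_name <- standards$name[ord]
  vapply(species_rt, function(rt) {
    d <- abs(rt - std_rt)
    std_name[which.min(d)] # which.min takes the first i.e. lower-RT tie
  }, character(1))
}

#' Internal-standard normalization of the peak-area matrix
#'
#' Adds a `normalized` layer: each species' area divided, per sample, by the
#' area of its assigned (closest-RT) internal standard.
#'
#' @param x A `lipidome` object.
#' @return `x` with elements `assigned_standard` (per species) and
#'   `normalized` (matrix) added.
#' @export
normalize_species <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  if (any(x$standard_areas <= 0)) {
    idx <- which(x$standard_areas <= 0, arr.ind = TRUE)[1, ]
    stop("internal standard ", sQuote(rownames(x$standard_areas)[idx[1]]),
         " has non-positive area in sample ",
         sQuote(colnames(x$standard_areas)[idx[2]]), call. = FALSE)
  }
  assigned <- assign_internal_standard(x$species$rt, x$standards)
  x$assigned_standard <- assigned
  x$normalized <- x$areas / x$standard_areas[assigned, , drop = FALSE]
  x
}

#' Per-sample relative abundances of lipid species
#'
#' Adds a `relative` layer: each species' normalized area divided by the
#' per-sample sum of all normalized areas. Columns sum to one.
#'
#' @param x A `lipidome` object with a `normalized` layer (see
#'   [normalize_species()]).
#' @return `x` with a `relative` matrix added.
#' @export
relative_abundance_matrix <- function(x) {
  stopifnot(inherits(x, "lipidome"))
  if (is.null(x$normalized)) x <- normalize_species(x)
  totals <- colSums(x$normalized)
  if (any(totals <= 0)) {
    stop("per-sample total normalized area is zero for sample(s): ",
         paste(colnames(x$normalized)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  x$relative <- sweep(x$normalized, 2, totals, "/")
  x
}

#' Aggregate species abundances into classes and main lipid groups
#'
#' Sums per-sample relative abundances into the eleven lipid classes and the
#' three main groups: glycolipids (GL = MGDG + DGDG + SQDG), phospholipids
#' (PL = PC + LPC + PE + PG + PI) and triacylglycerols (TG). Ceramides and
#' diacylglycerols belong to none of the three groups and are reported
#' separately.
#'
#' @param x A `lipidome` object (the `relative` layer is computed if absent).
#' @param denominator `"all"` (default) keeps fractions of the full lipidome;
#'   `"groups_only"` renormalises so that GL + PL + TG = 1, i.e. Cer and DG
#'   are dropped from the denominator.
#' @return A list with tibbles `classes` (`sample_id`, `lipid_class`,
#'   `abundance`) and `groups` (`sample_id`, `group` in GL/PL/TG/Cer/DG,
#'   `abundance`).
#' @export
aggregate_groups <- function(x, denominator = c("all", "groups_only")) {
  stopifnot(inherits(x, "lipidome"))
  denominator <- match.arg(denominator)
  if (is.null(x$relative)) x <- relative_abundance_matrix(x)

  long <- tibble::as_tibble(x$relative, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "sample_id",
                        values_to = "abundance") |>
    dplyr::left_join(dplyr::select(x$species, "species", "lipid_class"),
                     by = "species")

  classes <- long |>
    dplyr::group_by(.data$sample_id, .data$lipid_class) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")

  groups <- classes |>
    dplyr::mutate(group = dplyr::case_when(
      .data$lipid_class %in% glycolipid_classes() ~ "GL",
      .data$lipid_class %in% phospholipid_classes() ~ "PL",
      .data$lipid_class == "TG" ~ "TG",
      TRUE ~ .data$lipid_class
    )) |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    tidyr::complete(.data$sample_id,
                    group = c("GL", "PL", "TG"),
                    fill = list(abundance = 0))

  if (denominator == "groups_only") {
    groups <- groups |>
      dplyr::filter(.data$group %in% c("GL", "PL", "TG")) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(abundance = .data$abundance / sum(.data$abundance)) |>
      dplyr::ungroup()
  }
  list(classes = classes, groups = groups)
}

#' Read a wide lipid peak table and a standards table
#'
#' `read_lipid_peaks()` expects a delimited file whose first columns are
#' `species` and `rt`, followed by one numeric column per sample.
#' `read_lipid_standards()` expects `name`, `rt`, `amount_ug`, followed by
#' one area column per sample (same sample columns as the peak table).
#'
#' @param file Path to the delimited file (CSV, or TSV by extension).
#' @return For peaks: a list with `species` (tibble) and `areas` (matrix);
#'   for standards: a list with `standards` (tibble) and `areas` (matrix).
#' @export
read_lipid_peaks <- function(file) {
  delim <- if (grepl("\\.tsv$", file)) "\t" else ","
  tab <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
  species <- dplyr::select(tab, "species", "rt")
  areas <- as.matrix(dplyr::select(tab, -"species", -"rt"))
  rownames(areas) <- species$species
  list(species = species, areas = areas)
}

#' @rdname read_lipid_peaks
#' @export
read_lipid_standards <- function(file) {
  delim <- if (grepl("\\.tsv$", file)) "\t" else ","
  tab <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
  standards <- dplyr::select(tab, "name", "rt", "amount_ug")
  areas <- as.matrix(dplyr::select(tab, -"name", -"rt", -"amount_ug"))
  rownames(areas) <- standards$name
  list(standards = standards, areas = areas)
}
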