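test_that("lipid shorthand parses class, composition and variant letter", {
  p <- parse_lipid_shorthand(c("MGDG(34:1)", "TG(52:2) B", "LPC(18:1)"))
  expect_equal(p$lipid_class, c("MGDG", "TG", "LPC"))
  expect_equal(p$total_carbons, c(34L, 52L, 18L))
  expect_equal(p$total_db, c(1L, 2L, 1L))
  expect_equal(p$variant, c(NA, "B", NA))
  expect_equal(p$shorthand[2], "TG(52:2) B")
  expect_error(parse_lipid_shorthand("XYZ(10:0)"), "accepted classes")
  expect_error(parse_lipid_shorthand("MGDG[34:1]"), "malformed")
})

test_that("internal standards are assigned by nearest retention time, ties low", {
  standards <- tibble::tibble(name = c("low", "high"), rt = c(5, 10))
  expect_equal(assign_internal_standard(6, standards), "low")
  expect_equal(assign_internal_standard(8.2, standards), "high")
  expect_equal(assign_internal_standard(7.5, standards), "low") # tie rule
  one <- tibble::tibble(name = "only", rt = 3)
  expect_equal(assign_internal_standard(c(1, 30), one), c("only", "only"))
  expect_error(assign_internal_standard(1, standards[0, ]), "no internal")
})

tiny_lipidome <- function(areas, std_areas = NULL) {
  n <- nrow(areas)
  species <- tibble::tibble(
    species = c("MGDG(34:1)", "DGDG(36:6)", "SQDG(32:0)", "PC(34:2)",
                "TG(52:2)")[seq_len(n)],
    rt = c(9, 8, 6, 12, 20)[seq_len(n)])
  standards <- tibble::tibble(name = c("dMPC", "Cer(d18:1/17:0)"),
                              rt = c(9, 14), amount_ug = c(0.04, 0.08))
  if (is.null(std_areas)) {
    std_areas <- matrix(50, 2, ncol(areas))
  }
  colnames(areas) <- colnames(std_areas) <- paste0("s", seq_len(ncol(areas)))
  lipidome(species, areas, standards, std_areas)
}

test_that("normalization divides by the assigned standard per sample", {
  x <- tiny_lipidome(matrix(100, 1, 1))
  x <- normalize_species(x)
  expect_equal(unname(x$normalized[1, 1]), 2) # 100 / 50
  # 2 species x 2 samples hand case
  areas <- matrix(c(10, 20, 40, 80), 2, 2) # species x samples
  std <- matrix(c(5, 10, 20, 40), 2, 2)
  y <- tiny_lipidome(areas, std)
  y <- normalize_species(y)
  # species rt 9 -> dMPC (row 1), rt 8 -> dMPC (row 1)
  expect_equal(unname(y$normalized), areas / rbind(std[1, ], std[1, ]))
  # joint doubling of raw and IS areas leaves ratios unchanged
  y2 <- tiny_lipidome(2 * areas, 2 * std)
  expect_equal(normalize_species(y2)$normalized, y$normalized)
})

test_that("zero standard area is reported with sample and standard name", {
  x <- tiny_lipidome(matrix(1, 1, 1), matrix(c(50, 1), 2, 1))
  x$standard_areas[2, 1] <- 0
  expect_error(normalize_species(x), "Cer\\(d18:1/17:0\\).*s1")
})

test_that("relative abundances close to one and ignore species order", {
  set.seed(9)
  areas <- matrix(stats::runif(15, 1, 100), 5, 3)
  x <- relative_abundance_matrix(tiny_lipidome(areas))
  expect_equal(unname(colSums(x$relative)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(x$relative >= 0))
  # ratios {1, 3} -> {0.25, 0.75}
  y <- relative_abundance_matrix(tiny_lipidome(matrix(c(50, 150), 2, 1)))
  expect_equal(unname(y$relative[, 1]), c(0.25, 0.75))
  # permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  xp <- relative_abundance_matrix(tiny_lipidome(areas[perm, , drop = FALSE]))
  expect_equal(xp$relative, x$relative[perm, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("IS-scale invariance: scaling a standard and its species cancels", {
  areas <- matrix(stats::runif(10, 1, 100), 5, 2)
  x <- normalize_species(tiny_lipidome(areas))
  scaled <- tiny_lipidome(areas)
  c_scale <- 3.7
  which_std <- x$assigned_standard == "dMPC"
  scaled$areas[which_std, ] <- scaled$areas[which_std, ] * c_scale
  scaled$standard_areas["dMPC", ] <- scaled$standard_areas["dMPC", ] * c_scale
  expect_equal(relative_abundance_matrix(scaled)$relative,
               relative_abundance_matrix(x)$relative)
})

test_that("group aggregation sums GL, PL and TG and can renormalise", {
  # hand-built 5-species, 1-sample table with equal normalized signal
  x <- relative_abundance_matrix(tiny_lipidome(matrix(50, 5, 1)))
  ag <- aggregate_groups(x)
  g <- stats::setNames(ag$groups$abundance, ag$groups$group)
  expect_equal(g[["GL"]], 3 / 5) # MGDG + DGDG + SQDG
  expect_equal(g[["PL"]], 1 / 5)
  expect_equal(g[["TG"]], 1 / 5)
  expect_equal(sum(ag$groups$abundance), 1, tolerance = 1e-12)
  expect_equal(sum(ag$classes$abundance), 1, tolerance = 1e-12)
  # an SQDG-only lipidome is all glycolipid
  sq <- lipidome(tibble::tibble(species = c("SQDG(32:0)", "SQDG(32:1)"),
                                rt = c(6, 6.5)),
                 matrix(c(10, 30), 2, 1, dimnames = list(NULL, "s1")),
                 tibble::tibble(name = "dMPG", rt = 7.5, amount_ug = 0.024),
                 matrix(40, 1, 1, dimnames = list(NULL, "s1")))
  agq <- aggregate_groups(relative_abundance_matrix(sq))
  expect_equal(agq$groups$abundance[agq$groups$group == "GL"], 1)
})

test_that("groups_only denominator drops Cer and DG and recloses", {
  species <- tibble::tibble(
    species = c("MGDG(34:1)", "TG(52:2)", "Cer(34:1)", "DG(36:2)"),
    rt = c(9, 20, 13, 15))
  standards <- tibble::tibble(name = "dMPA", rt = 11, amount_ug = 0.16)
  x <- lipidome(species, matrix(c(10, 10, 20, 10), 4, 1,
                                dimnames = list(NULL, "s1")),
                standards, matrix(10, 1, 1, dimnames = list(NULL, "s1")))
  ag <- aggregate_groups(relative_abundance_matrix(x), denominator = "groups_only")
  expect_setequal(ag$groups$group, c("GL", "PL", "TG"))
  expect_equal(sum(ag$groups$abundance), 1)
  expect_equal(ag$groups$abundance[ag$groups$group == "TG"], 0.5)
})

test_that("lipid peak and standards tables survive a write/read round trip", {
  sim <- generate_lipidome(replicates = 2, seed = 4)
  x <- sim$lipidome
  peaks_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_cols(x$species[, c("species", "rt")],
                                    tibble::as_tibble(x$areas)), peaks_path)
  back <- read_lipid_peaks(peaks_path)
  expect_equal(back$areas, x$areas, tolerance = 1e-12)
  std_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::bind_cols(x$standards,
                                    tibble::as_tibble(x$standard_areas)), std_path)
  back_std <- read_lipid_standards(std_path)
  expect_equal(back_std$areas, x$standard_areas, tolerance = 1e-12)
  expect_equal(back_std$standards$amount_ug, x$standards$amount_ug)
})
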