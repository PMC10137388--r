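#' Default strain templates for the synthetic-data generators
#'
#' Bundles the per-strain generator parameters: the reference fatty-acid
#' composition (mean/SD per strain, five replicates), the lipidome design
#' (species counts per class, planted differential-species patterns whose
#' high abundances also produce the strain-level class-composition
#' differences: the autotrophic strain glycolipid-rich, the two
#' TG-accumulating heterotrophic strains, and the phospholipid-rich white
#' strain), and the dose-response parameters of the scavenging assays
#' (maximum inhibition and the target ICx of each extract, with the Trolox
#' calibration implied by the reported Trolox-equivalent activities).
#'
#' @return A named list with elements `fa`, `lipidome`, `dose_response`,
#'   `cox2`.
#' @export
strain_templates <- function() {
  strains <- c("C-Auto", "C-Hetero", "C-Honey", "C-White")

  lipidome <- list(
    class_counts = c(MGDG = 32, DGDG = 28, SQDG = 30, PC = 40, LPC = 12,
                     PE = 30, PG = 24, PI = 14, Cer = 8, DG = 14, TG = 84),
    # per-species mean intensity scale by class (arbitrary units)
    # chosen so that after closest-RT internal-standard normalization (which
    # inflates classes assigned to low-amount standards) the TG classes of
    # the heterotrophic strains clearly exceed their glycolipids
    class_base = c(MGDG = 0.95, DGDG = 0.75, SQDG = 0.65, PC = 1.0, LPC = 0.4,
                   PE = 0.8, PG = 0.7, PI = 0.7, Cer = 0.45, DG = 0.65, TG = 2.0),
    # carbon / double-bond ranges and retention-time windows per class
    class_ranges = tibble::tribble(
      ~lipid_class, ~c_min, ~c_max, ~db_min, ~db_max, ~rt_min, ~rt_max,
      "MGDG", 32L, 36L, 0L, 7L,  8, 14,
      "DGDG", 32L, 36L, 0L, 7L,  6, 12,
      "SQDG", 30L, 34L, 0L, 5L,  5, 10,
      "PC",   32L, 40L, 0L, 8L,  8, 16,
      "LPC",  16L, 22L, 0L, 4L,  1,  4,
      "PE",   32L, 40L, 0L, 8L,  8, 15,
      "PG",   32L, 36L, 0L, 6L,  7, 12,
      "PI",   32L, 36L, 0L, 4L,  5,  9,
      "Cer",  32L, 42L, 0L, 2L, 12, 18,
      "DG",   32L, 38L, 0L, 6L, 12, 18,
      "TG",   48L, 56L, 1L, 6L, 18, 25
    ),
    # planted differential species: how many from which classes, and the
    # per-strain abundance fold of each pattern (order: strains above)
    effects = tibble::tribble(
      ~pattern,        ~classes,                          ~n_per_class,
      "up_auto_gl",    list(c(MGDG = 9, DGDG = 3, SQDG = 2)), NA,
      "up_hetero_tg",  list(c(TG = 10)),                      NA,
      "up_white_pl",   list(c(PC = 4, PE = 2, PI = 1, PG = 1)), NA,
      "up_hetero_sqdg", list(c(SQDG = 4)),                    NA,
      "up_auto_misc",  list(c(DG = 2, Cer = 1, LPC = 1)),     NA
    )[, c("pattern", "classes")],
    # per-strain abundance folds per pattern, balanced so that the planted
    # species' expected total share of the lipidome is similar in every
    # strain (equal lipid mass is loaded per sample, and closure would
    # otherwise shift every unplanted species' relative abundance)
    effect_folds = list(
      up_auto_gl     = c(`C-Auto` = 2.4,  `C-Hetero` = 0.55, `C-Honey` = 0.45, `C-White` = 0.33),
      up_hetero_tg   = c(`C-Auto` = 0.42, `C-Hetero` = 2.1,  `C-Honey` = 1.6,  `C-White` = 0.50),
      up_white_pl    = c(`C-Auto` = 0.65, `C-Hetero` = 0.50, `C-Honey` = 0.80, `C-White` = 2.9),
      up_hetero_sqdg = c(`C-Auto` = 0.9,  `C-Hetero` = 2.4,  `C-Honey` = 0.65, `C-White` = 0.55),
      up_auto_misc   = c(`C-Auto` = 3.0,  `C-Hetero` = 1.0,  `C-Honey` = 0.80, `C-White` = 0.50)
    ),
    planted_base_boost = 1.5, # planted species sit among the abundant ones
    cv = 0.25,              # lognormal replicate CV of species abundances
    cv_standard = 0.03,     # residual per-sample IS area noise
    standards = tibble::tribble(
      ~name,              ~rt, ~amount_ug,
      "LPC(19:0)",        2.5,      0.04,
      "dPPI",             6.5,      0.08,
      "dMPG",             7.5,      0.024,
      "dMPS",             8.0,      0.08,
      "dMPE",             8.5,      0.04,
      "dMPC",             9.0,      0.04,
      "SM(d18:1/17:0)",  10.0,      0.04,
      "dMPA",            11.0,      0.16,
      "CL(14:0)4",       13.0,      0.16,
      "Cer(d18:1/17:0)", 14.0,      0.08
    )
  )

  anti <- reference_antioxidant_results()
  trolox_icx <- function(assay, x) {
    rows <- anti[anti$assay == assay & !is.na(anti$x) & anti$x == x, ]
    mean(rows$te_umol_g * rows$icx_ug_ml * 250.29 / 1e6)
  }
  dose_response <- dplyr::bind_rows(
    dplyr::transmute(anti, .data$assay, extract = .data$strain,
                     imax = dplyr::case_when(
                       assay == "DPPH" & strain == "C-Auto" ~ 45,
                       assay == "DPPH" & strain == "C-Honey" ~ 35,
                       assay == "ABTS" & strain == "C-Auto" ~ 75,
                       assay == "ABTS" & strain == "C-Hetero" ~ 32,
                       assay == "ABTS" & strain == "C-Honey" ~ 34,
                       TRUE ~ 9 # extracts that never exceed ~10% inhibition
                     ),
                     x = .data$x, icx_target = .data$icx_ug_ml),
    tibble::tibble(assay = c("DPPH", "ABTS"), extract = "Trolox",
                   imax = c(99.5, 75), x = c(20, 50),
                   icx_target = c(trolox_icx("DPPH", 20),
                                  trolox_icx("ABTS", 50)))
  )

  list(
    strains = strains,
    fa = reference_fa_profiles(),
    lipidome = lipidome,
    dose_response = dose_response,
    cox2 = reference_cox2_results()
  )
}

#' Synthetic GC-MS fatty-acid peak table
#'
#' Draws per-replicate relative abundances from each strain's template
#' (normal around the template mean with the template SD, truncated at zero
#' and renormalised to 100) and converts them to peak areas with a
#' per-sample total-signal factor; one methyl nonadecanoate (C19:0)
#' internal-standard row is added per sample. With all SDs zero the
#' recomputed profiles equal the renormalised template means exactly.
#'
#' @param templates Output of [strain_templates()].
#' @param replicates Replicates per strain (default 5).
#' @param seed Integer seed fixing all randomness.
#' @return A long tibble (`sample_id`, `strain`, `fa`, `area`,
#'   `is_standard`) suitable for [fa_relative_abundance()].
#' @export
generate_fa_table <- function(templates = strain_templates(), replicates = 5,
                              seed = 1) {
  stopifnot(replicates >= 1)
  fa_tpl <- templates$fa
  if (any(fa_tpl$sd_pct < 0) || any(fa_tpl$mean_pct < 0)) {
    stop("invalid FA template: negative mean or SD", call. = FALSE)
  }
  set.seed(seed)
  purrr::map_dfr(unique(fa_tpl$strain), function(s) {
    tpl <- fa_tpl[fa_tpl$strain == s, ]
    purrr::map_dfr(seq_len(replicates), function(r) {
      pct <- pmax(stats::rnorm(nrow(tpl), tpl$mean_pct, tpl$sd_pct), 0)
      pct <- 100 * pct / sum(pct)
      total_area <- stats::rlnorm(1, log(2e6), 0.15)
      is_area <- stats::rlnorm(1, log(1.5e5), 0.1)
      sample_id <- sprintf("%s_r%d", s, r)
      dplyr::bind_rows(
        tibble::tibble(sample_id = sample_id, strain = s, fa = tpl$fa,
                       area = pct / 100 * total_area, is_standard = FALSE),
        tibble::tibble(sample_id = sample_id, strain = s, fa = "C19:0",
                       area = is_area, is_standard = TRUE)
      )
    })
  })
}

#' Synthetic LC-MS lipidome with planted differential species
#'
#' Builds a species panel (default 316 species across the eleven classes,
#' with class-typical carbon/double-bond ranges and retention times),
#' lognormal base abundances, and a set of planted differential species
#' whose strain-specific abundance folds create both the univariate
#' signal for the recovery tests and the strain-level differences in
#' class composition. The remaining species have no strain effect (their
#' relative abundances vary only through closure). Ten spiked internal
#' standards with spread retention times are included.
#'
#' @param templates Output of [strain_templates()].
#' @param replicates Replicates per strain (default 5).
#' @param seed Integer seed fixing all randomness.
#' @param effect_scale Scales the planted log-folds; 0 gives a strain-null
#'   lipidome (default 1).
#' @return A list with `lipidome` (a [lipidome()] object), `samples`
#'   (tibble `sample_id`, `strain`) and `truth` (tibble of planted species:
#'   `species`, `pattern`).
#' @export
generate_lipidome <- function(templates = strain_templates(), replicates = 5,
                              seed = 1, effect_scale = 1) {
  tpl <- templates$lipidome
  strains <- templates$strains
  set.seed(seed)

  # species panel
  species <- purrr::map_dfr(names(tpl$class_counts), function(cls) {
    n <- tpl$class_counts[[cls]]
    rng <- tpl$class_ranges[tpl$class_ranges$lipid_class == cls, ]
    tibble::tibble(
      lipid_class = cls,
      total_carbons = sample(seq(rng$c_min, rng$c_max, by = 2), n, replace = TRUE),
      total_db = sample(rng$db_min:rng$db_max, n, replace = TRUE),
      rt = round(stats::runif(n, rng$rt_min, rng$rt_max), 2)
    )
  })
  species <- species |>
    dplyr::group_by(.data$lipid_class, .data$total_carbons, .data$total_db) |>
    dplyr::mutate(variant = if (dplyr::n() > 1) LETTERS[seq_len(dplyr::n())] else NA_character_) |>
    dplyr::ungroup() |>
    dplyr::mutate(species = paste0(
      .data$lipid_class, "(", .data$total_carbons, ":", .data$total_db, ")",
      ifelse(is.na(.data$variant), "", paste0(" ", .data$variant))))

  base <- tpl$class_base[species$lipid_class] *
    stats::rlnorm(nrow(species), 0, 0.6)

  # plant the differential species: the most abundant of each class carry
  # the strain effects (so they also shape the class composition)
  species$pattern <- NA_character_
  for (pat in names(tpl$effect_folds)) {
    counts <- tpl$effects$classes[[which(tpl$effects$pattern == pat)]][[1]]
    for (cls in names(counts)) {
      free <- which(species$lipid_class == cls & is.na(species$pattern))
      take <- free[order(base[free], decreasing = TRUE)][seq_len(counts[[cls]])]
      species$pattern[take] <- pat
    }
  }
  planted <- !is.na(species$pattern)
  base[planted] <- base[planted] * tpl$planted_base_boost

  folds <- matrix(1, nrow(species), length(strains),
                  dimnames = list(species$species, strains))
  for (pat in names(tpl$effect_folds)) {
    rows <- which(species$pattern == pat)
    folds[rows, ] <- rep(tpl$effect_folds[[pat]][strains]^effect_scale,
                         each = length(rows))
  }

  mu_strain <- base * folds
  # pin each strain's realized planted total to its design expectation, so
  # that sampling variability of the species panel does not leak
  # strain-specific totals into the unplanted background through closure
  # (the fold patterns themselves are near-balanced across strains)
  expected_base <- tpl$class_base[species$lipid_class[planted]] *
    tpl$planted_base_boost * exp(0.6^2 / 2)
  design_totals <- colSums(expected_base * folds[planted, , drop = FALSE])
  pt <- colSums(mu_strain[planted, , drop = FALSE])
  mu_strain[planted, ] <- sweep(mu_strain[planted, , drop = FALSE], 2,
                                pt / design_totals, "/")

  samples <- tidyr::expand_grid(strain = strains, rep = seq_len(replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$strain, .data$rep)) |>
    dplyr::select("sample_id", "strain")

  sdlog <- sqrt(log(1 + tpl$cv^2))
  loading <- stats::rlnorm(nrow(samples), log(1e4), 0.1) # per-sample signal
  areas <- sapply(seq_len(nrow(samples)), function(j) {
    mu_strain[, samples$strain[j]] * loading[j] *
      stats::rlnorm(nrow(species), 0, sdlog)
  })
  colnames(areas) <- samples$sample_id

  standards <- tpl$standards
  response <- stats::rlnorm(nrow(standards), log(5e4), 0.2) # per-standard response
  std_noise <- sqrt(log(1 + tpl$cv_standard^2))
  standard_areas <- sapply(seq_len(nrow(samples)), function(j) {
    standards$amount_ug * response * loading[j] *
      stats::rlnorm(nrow(standards), 0, std_noise)
  })
  colnames(standard_areas) <- samples$sample_id

  list(
    lipidome = lipidome(
      species = dplyr::select(species, "species", "rt"),
      areas = areas,
      standards = standards,
      standard_areas = standard_areas
    ),
    samples = samples,
    truth = species |>
      dplyr::filter(!is.na(.data$pattern)) |>
      dplyr::select("species", "pattern")
  )
}

# solve the half-saturation constant of I(c) = imax * c / (c + K) so that
# the ICx obtained by linear interpolation over the tested concentrations
# equals the target (i.e. calibrated to the measurement design)
solve_hyperbola_k <- function(imax, icx_target, x, concentrations) {
  stopifnot(imax > x)
  interp_icx <- function(k) {
    inh <- imax * concentrations / (concentrations + k)
    estimate_icx(dose_response_curve(concentrations, inh), x)
  }
  f <- function(logk) {
    v <- interp_icx(exp(logk))
    if (is.na(v)) return(1e8) # not reached at this K: push the root lower
    v - icx_target
  }
  stats::uniroot(f, lower = log(1e-4), upper = log(1e5), tol = 1e-12)$root |>
    exp()
}

#' Synthetic radical-scavenging assay plates
#'
#' Generates triplicate DPPH and ABTS plate readouts for the four strains'
#' lipid extracts (25, 125, 250, 500 ug/mL) and a Trolox calibration series
#' (12.5, 62.5, 125, 250 ug/mL). Each extract follows a saturating
#' inhibition curve `I(c) = imax * c / (c + K)`; for extracts with a target
#' ICx, K is calibrated so that the ICx recovered by linear interpolation at
#' the tested concentrations equals the template value exactly in the
#' noiseless limit. Absorbances are built around a radical-only well of
#' ~0.9 with additive Gaussian noise.
#'
#' @param templates Output of [strain_templates()].
#' @param seed Integer seed.
#' @param replicates Wells per concentration (default 3).
#' @param noise_sd SD of the additive absorbance noise (default 0.005; use 0
#'   for exact round-trips).
#' @return A long tibble: `assay`, `extract`, `concentration`, `replicate`,
#'   `abs_radical`, `abs_sample`, `abs_control`.
#' @export
generate_dose_response <- function(templates = strain_templates(), seed = 1,
                                   replicates = 3, noise_sd = 0.005) {
  dr <- templates$dose_response
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(dr)), function(i) {
    row <- dr[i, ]
    conc <- if (row$extract == "Trolox") c(12.5, 62.5, 125, 250) else c(25, 125, 250, 500)
    k <- if (is.na(row$icx_target)) {
      6 * max(conc) # saturates far beyond the tested range; ICx never reached
    } else {
      solve_hyperbola_k(row$imax, row$icx_target, row$x, conc)
    }
    inh <- row$imax * conc / (conc + k)
    grid <- tidyr::expand_grid(concentration = conc,
                               replicate = seq_len(replicates))
    inh_w <- inh[match(grid$concentration, conc)]
    n <- nrow(grid)
    abs_radical <- 0.9 + stats::rnorm(n, 0, noise_sd)
    abs_control <- 0.03 + 2e-5 * grid$concentration + stats::rnorm(n, 0, noise_sd)
    abs_sample <- abs_control + 0.9 * (1 - inh_w / 100) +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(assay = row$assay, extract = row$extract,
                   concentration = grid$concentration,
                   replicate = grid$replicate,
                   abs_radical = abs_radical, abs_sample = abs_sample,
                   abs_control = abs_control)
  })
}

#' Synthetic COX-2 inhibition readouts
#'
#' Triplicate prostaglandin readouts at 125 ug/mL of extract: the
#' uninhibited reference activity is 1 and each strain's residual activity
#' follows its template inhibition mean/SD.
#'
#' @param templates Output of [strain_templates()].
#' @param seed Integer seed.
#' @param replicates Replicates per strain (default 3).
#' @return A tibble: `extract`, `concentration`, `replicate`,
#'   `activity_sample`, `activity_reference`.
#' @export
generate_cox2_readouts <- function(templates = strain_templates(), seed = 1,
                                   replicates = 3) {
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(templates$cox2)), function(i) {
    row <- templates$cox2[i, ]
    inh <- stats::rnorm(replicates, row$mean_pct, row$sd_pct)
    tibble::tibble(extract = row$strain, concentration = 125,
                   replicate = seq_len(replicates),
                   activity_sample = 1 - inh / 100,
                   activity_reference = 1)
  })
}
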