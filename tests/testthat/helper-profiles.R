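# build a one-sample FA profile tibble from a named percent vector
profile_of <- function(...) {
  v <- c(...)
  tibble::tibble(fa = names(v), abundance = unname(v))
}

# the bundled reference composition of one strain as a one-sample profile
reference_profile <- function(strain) {
  ref <- reference_fa_profiles()
  ref <- ref[ref$strain == strain, ]
  tibble::tibble(fa = ref$fa, abundance = ref$mean_pct)
}

# a long peak table (one sample) with an internal-standard row appended
peaks_of <- function(areas, is_area = 5, sample_id = "s1") {
  dplyr::bind_rows(
    tibble::tibble(sample_id = sample_id, fa = names(areas),
                   area = unname(areas), is_standard = FALSE),
    tibble::tibble(sample_id = sample_id, fa = "C19:0", area = is_area,
                   is_standard = TRUE)
  )
}

# brute-force Lance-Williams agglomeration for Ward linkage on unsquared
# Euclidean distances (the classic "ward.D" convention); returns the merge
# heights in order
ward_bruteforce_heights <- function(points) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1)) {
        i <- active[a]; j <- active[b]
        if (d[i, j] < best_d) {
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d_new <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
      d[i, k] <- d[k, i] <- d_new
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}
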