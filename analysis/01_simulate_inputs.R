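#!/usr/bin/env Rscript
# Step 1 -- simulate the study's instrument inputs.
#
# The raw GC-MS and LC-MS data of the four-strain comparison are not
# publicly deposited, so the workflow runs on seeded synthetic inputs that
# emulate the study design: 4 strains x 5 replicates of FAME peak areas
# drawn around the published strain compositions, a 316-species lipidome
# with 10 spiked internal standards and 40 planted differential species,
# and triplicate DPPH/ABTS dose-response plates plus COX-2 readouts.

suppressMessages(library(algalipids))

seed <- 1
out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fa_peaks <- generate_fa_table(seed = seed)
readr::write_csv(fa_peaks, file.path(out_dir, "fa_peaks.csv"))

sim <- generate_lipidome(seed = seed)
x <- sim$lipidome
readr::write_csv(
  dplyr::bind_cols(x$species[, c("species", "rt")], tibble::as_tibble(x$areas)),
  file.path(out_dir, "lipid_peaks.csv"))
readr::write_csv(
  dplyr::bind_cols(x$standards, tibble::as_tibble(x$standard_areas)),
  file.path(out_dir, "lipid_standards.csv"))
readr::write_csv(sim$samples, file.path(out_dir, "samples.csv"))
readr::write_csv(sim$truth, file.path(out_dir, "planted_species.csv"))

plates <- generate_dose_response(seed = seed)
readr::write_csv(plates, file.path(out_dir, "assay_plates.csv"))
cox2 <- generate_cox2_readouts(seed = seed)
readr::write_csv(cox2, file.path(out_dir, "cox2_readouts.csv"))

cat("Simulated inputs written to", out_dir, "\n")
cat(sprintf(" - FA peak table: %d rows (%d samples)\n", nrow(fa_peaks),
            length(unique(fa_peaks$sample_id))))
cat(sprintf(" - lipidome: %d species x %d samples, %d standards, %d planted\n",
            nrow(x$areas), ncol(x$areas), nrow(x$standards), nrow(sim$truth)))
cat(sprintf(" - assay plates: %d wells; COX-2 readouts: %d\n",
            nrow(plates), nrow(cox2)))
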