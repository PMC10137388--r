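#!/usr/bin/env Rscript
# Step 4 -- antioxidant and anti-inflammatory activity.
#
# Converts plate absorbances into inhibition percentages, interpolates the
# IC20 (DPPH) and IC50/IC20 (ABTS) per extract, expresses activities as
# Trolox equivalents against the Trolox series of the same plate, and
# summarises COX-2 inhibition at 125 ug/mL.

suppressMessages(library(algalipids))

plates <- read_assay_plate("results/simulated/assay_plates.csv")

tabs <- list(
  DPPH_IC20 = assay_icx_table(plates[plates$assay == "DPPH", ], x = 20),
  ABTS_IC50 = assay_icx_table(plates[plates$assay == "ABTS", ], x = 50),
  ABTS_IC20 = assay_icx_table(plates[plates$assay == "ABTS", ], x = 20)
)
ic_table <- dplyr::bind_rows(tabs, .id = "measure")
readr::write_csv(ic_table, "results/antioxidant_icx_te.csv")

cox2 <- readr::read_csv("results/simulated/cox2_readouts.csv",
                        show_col_types = FALSE)
cox2$inhibition <- cox2_inhibition(cox2$activity_sample, cox2$activity_reference)
cox2_table <- cox2 |>
  dplyr::group_by(.data$extract) |>
  dplyr::summarise(mean_inhibition = mean(.data$inhibition),
                   sd = stats::sd(.data$inhibition), .groups = "drop")
readr::write_csv(cox2_table, "results/cox2_inhibition.csv")

cat("ICx and Trolox equivalents (NA = inhibition level not reached):\n")
print(as.data.frame(ic_table), digits = 4)
cat("\nCOX-2 inhibition at 125 ug/mL (mean +/- SD, n = 3):\n")
print(as.data.frame(cox2_table), digits = 3)
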