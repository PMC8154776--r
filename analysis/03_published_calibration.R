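#!/usr/bin/env Rscript
# Worked values from the published 4-knot calibrations bundled with the
# package: forward prediction of the median uACR at uPCR 0.15 and 0.50
# g/gCr, inversion at the microalbuminuria boundary (uACR 30 mg/gCr), and
# the slope change across the knot at 60 mg/gCr.

suppressPackageStartupMessages(library(microalb))

dir.create("results/calibration", recursive = TRUE, showWarnings = FALSE)
rows <- list()
for (pop in c("all", "non_diabetic", "diabetic")) {
  m <- load_calibration(pop)
  rows[[pop]] <- data.frame(
    population = pop,
    uacr_at_upcr_150 = round(predict_median_uacr(m, 150)),
    uacr_at_upcr_500 = round(predict_median_uacr(m, 500)),
    upcr_at_uacr_30_g = round(invert_median_uacr(m, 30) / 1000, 3),
    slope_change_knot60 = round(m$segments$slope[3] - m$segments$slope[2], 2)
  )
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/calibration/published_calibration_queries.csv",
                 row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nA uPCR of ~0.077 g/gCr (not the conventional 0.15) already corresponds\n")
cat("to a median uACR of 30 mg/gCr under the combined-population calibration.\n")
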