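#!/usr/bin/env Rscript
# Per-diet GF-vs-FMT body-weight contrasts: ANCOVA line comparison, the two
# microbiota-attributable weight differences, and weight gain per day.

suppressMessages(library(gnotolink))

dir <- file.path("results", "cohort")
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first: ", dir, " is missing")
coh <- read_cohort(dir)
diets <- unique(coh$metadata$diet)

ct <- diet_contrasts(coh$growth, coh$metadata, diets)
write_table_tsv(ct[, c("diet", "delta_bw_abs", "delta_bw_slope",
                       "p_slope", "p_elev")],
                file.path("results", "diet_contrasts.tsv"))
gpd <- gain_per_day(coh$growth, coh$metadata)
write_table_tsv(gpd, file.path("results", "gain_per_day.tsv"))

cat("Per-diet FMT - GF contrasts (grams / grams-per-week):\n")
print(ct[, c("diet", "delta_bw_abs", "delta_bw_slope", "p_elev")], digits = 3)
cat("\nIn every diet the FMT group gains more weight; the ANCOVA elevation",
    "p-values quantify the line separation per diet.\n")
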