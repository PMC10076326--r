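#!/usr/bin/env Rscript
# Differential-expression screen per tissue x diet (Welch test on log2
# expression, p < 0.05 with any directional fold change), then the
# cross-diet and cross-tissue intersections.

suppressMessages(library(gnotolink))

dir <- file.path("results", "cohort")
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first: ", dir, " is missing")
coh <- read_cohort(dir)
diets <- unique(coh$metadata$diet)
tissues <- names(coh$expression)

recs <- deg_screen(coh$expression, coh$metadata, diets = diets, tissues = tissues)
write_table_tsv(recs, file.path("results", "deg_records.tsv"))

inter <- intersect_degs(recs, diets = diets, tissues = tissues)
counts <- data.frame(tissue = rownames(inter$counts), inter$counts,
                     check.names = FALSE)
write_table_tsv(counts, file.path("results", "deg_intersections.tsv"))

cat("DEG counts per tissue x diet (last column: common across all diets):\n")
print(inter$counts)
cat("\nGenes differential in every diet within a tissue are the candidates",
    "for the weight-linkage screen.\n")
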