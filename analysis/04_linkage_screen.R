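#!/usr/bin/env Rscript
# The core linkage chain: diet-common DEGs -> cross-diet correlation of
# their expression shifts with the weight contrasts -> taxon-gene screen at
# species and family rank -> taxon-weight regression per individual mouse.

suppressMessages(library(gnotolink))

dir <- file.path("results", "cohort")
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first: ", dir, " is missing")
coh <- read_cohort(dir)
diets <- unique(coh$metadata$diet)

ct <- diet_contrasts(coh$growth, coh$metadata, diets)
linkage <- list()
dgel_sel <- list()
for (tis in names(coh$expression)) {
  pl <- run_linkage_pipeline(coh$expression[[tis]], coh$metadata, coh$growth,
                             tis, diets = diets, contrasts = ct)
  linkage[[tis]] <- pl$linkage
  sel <- pl$linkage$gene[pl$linkage$selected]
  if (length(sel)) dgel_sel[[tis]] <- pl$delta_gel[sel, , drop = FALSE]
}
linkage <- do.call(rbind, linkage)
write_table_tsv(linkage, file.path("results", "gene_linkage.tsv"))
cat(sum(linkage$selected), "gene-tissue pairs selected at |r| >= 0.70",
    "out of", nrow(linkage), "diet-common candidates\n")

# taxon screens use the first tissue's selected shifts (diet order is shared)
dg <- dgel_sel[[1]]
for (rk in c("species", "family")) {
  tg <- taxon_gene_screen(coh$abundance, coh$taxonomy, coh$metadata, dg,
                          rank = rk, diets = diets)
  write_table_tsv(tg, file.path("results", paste0("taxon_gene_", rk, ".tsv")))
  cat("\ntop", rk, "level taxa by count of correlated genes (|r| > 0.8):\n")
  print(utils::head(tg[, c("taxon", "gene_count", "correlated_genes")], 3))
}

tb <- rbind(
  taxon_bw_regression(coh$abundance, coh$taxonomy, coh$metadata, coh$growth,
                      rank = "species"),
  taxon_bw_regression(coh$abundance, coh$taxonomy, coh$metadata, coh$growth,
                      rank = "family"))
write_table_tsv(tb, file.path("results", "taxon_bw_regression.tsv"))
cat("\nstrongest taxon-weight regressions (R^2 of BW on relative abundance):\n")
print(utils::head(tb[order(-tb$r_squared),
                     c("taxon", "rank", "slope", "r_squared")], 5))
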