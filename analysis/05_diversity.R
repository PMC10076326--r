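#!/usr/bin/env Rscript
# Microbiome diversity analytics of the FMT mice: alpha diversity per sample
# (observed taxa, Chao1, Shannon), Jensen-Shannon PCoA, and UPGMA clustering
# on unweighted UniFrac.

suppressMessages(library(gnotolink))

dir <- file.path("results", "cohort")
if (!dir.exists(dir)) stop("run analysis/01_simulate.R first: ", dir, " is missing")
coh <- read_cohort(dir)
md <- coh$metadata[coh$metadata$tissue == "feces" &
                     coh$metadata$colonization == "FMT", ]
counts <- coh$abundance[, md$sample_id]

div <- alpha_diversity(counts)
div$diet <- md$diet[match(div$sample, md$sample_id)]
write_table_tsv(div, file.path("results", "alpha_diversity.tsv"))
cat("alpha diversity by diet (means):\n")
print(aggregate(cbind(observed, chao1, shannon) ~ diet, div, mean), digits = 4)

# two-way layout sanity check on Shannon: diet effect across samples
rel <- sweep(counts, 2, colSums(counts), "/")
dm <- jsd_matrix(rel)
write_matrix_tsv(dm, file.path("results", "jsd_distance.tsv"), id_name = "sample")
ord <- pcoa(dm, k = 2)
coords <- data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                     diet = md$diet)
write_table_tsv(coords, file.path("results", "pcoa_coordinates.tsv"))
cat("\nPCoA proportion explained (first two axes):",
    round(ord$proportion_explained[1:2], 3), "\n")

uf <- unweighted_unifrac(counts, coh$tree)
tr <- upgma(uf)
ape::write.tree(tr, file.path("results", "upgma_unifrac.nwk"))
cat("UPGMA tree over", length(tr$tip.label), "samples written",
    "(unweighted UniFrac distances)\n")

phyla <- aggregate_rank(counts, coh$taxonomy, "phylum")
comp <- sweep(phyla, 2, colSums(phyla), "/")
write_matrix_tsv(comp, file.path("results", "phylum_composition.tsv"),
                 id_name = "phylum")
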