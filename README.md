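# gnotolink

Multi-layer linkage analysis for gnotobiotic feeding studies: which gut
bacteria influence body weight, and through which host genes?

## The problem

Germ-free (GF) mice and GF mice given a fecal microbiota transplant (FMT)
differ, within a diet group, only in the presence of a microbiota — so any
FMT − GF difference is microbiota-attributable. When the same cohorts are
fed several diets, the *magnitude* of that difference varies with diet, and
that variation is an analytical lever: a host gene whose
microbiota-attributable expression shift tracks the microbiota-attributable
weight gain across diets is a candidate mediator, and a taxon whose
abundance tracks those gene shifts (and individual body weight) is a
candidate driver. `gnotolink` implements this chain for people analysing
GF-vs-FMT designs: weight contrasts, a differential-expression screen with
cross-diet intersections, the cross-diet correlation screens, taxon-level
regressions, and the standard microbiome diversity analytics, plus a
synthetic-cohort generator with recorded ground truth so the whole pipeline
can be validated end to end without animal data.

## The statistics

Per diet *d*, two weight contrasts: ΔBW(g) = mean(FMT week-0→8 gain) −
mean(GF gain), and ΔBW(s) = pooled OLS slope difference (g/week); growth
lines are compared by nested-model ANCOVA (slope homogeneity and elevation
F tests). Per tissue, genes differentially expressed between GF and FMT in
**every** diet (Welch test on log2 expression, p < 0.05, any directional
fold change) enter the screen; for each such gene the per-diet shift
ΔGEL(d) = mean FMT − mean GF expression is correlated across the n = 6
diets with both ΔBW vectors, and the gene is selected when
max(|r_abs|, |r_slope|) ≥ 0.70 at two-decimal precision. At n = 6 the
two-sided p for a Pearson r has the closed form 1 − (3/2)|r| + (1/2)|r|³.
Taxon counts (FMT mice only) aggregated to any rank are screened against the
selected genes' ΔGEL at |r| > 0.8, and week-8 body weight is regressed on
relative abundance across individual mice (R²). Diversity analytics:
observed taxa, bias-corrected Chao1, Shannon entropy, Jensen–Shannon
distance with PCoA, UPGMA clustering, unweighted UniFrac.

## Worked example

```r
library(gnotolink)

coh <- generate_cohort(cohort_config(seed = 1))   # 6 diets x GF/FMT, 60 mice
ct  <- diet_contrasts(coh$growth, coh$metadata, coh$config$diets)
ct[, c("diet", "delta_bw_abs", "delta_bw_slope", "p_elev")]
#>    diet delta_bw_abs delta_bw_slope   p_elev
#> 1    ND         5.86          0.787 8.70e-06
#> 2 StaHC         6.22          0.686 1.39e-16
#> 3 SucHC         8.12          1.037 8.33e-10
#> 4 FruHC         4.10          0.446 2.83e-07
#> 5  SaHF         5.16          0.610 1.41e-08
#> 6 USaHF         7.14          0.923 6.72e-16
```

FMT mice gain 4–8 g more than GF mice by week 8 depending on diet
(`delta_bw_abs`, grams; `delta_bw_slope` in g/week), and the ANCOVA
elevation p-values show the growth lines are separated in every diet. The
gene screen then chains diet-common differential expression into the
cross-diet correlation:

```r
pl <- run_linkage_pipeline(coh$expression$eWAT, coh$metadata, coh$growth,
                           "eWAT", diets = coh$config$diets, contrasts = ct)
pl$linkage[pl$linkage$selected, c("gene", "r_abs", "r_slope")]
#>       gene r_abs r_slope
#> 1  gene014  0.70    0.79
#> 2  gene021  0.74    0.81
#> ...
#> 10 gene187 -0.82   -0.91
```

All ten genes recovered here are exactly the planted ones
(`names(coh$truth$planted_genes)`); no unplanted gene is selected. The
taxon layers close the chain:

```r
tg <- taxon_gene_screen(coh$abundance, coh$taxonomy, coh$metadata,
                        pl$delta_gel, rank = "family")
head(tg[, c("taxon", "gene_count")], 3)
#>             taxon gene_count
#> 1 Ruminococcaceae          9
#> 2           Fam02          7
#> 3           Fam09          7

tb <- taxon_bw_regression(coh$abundance, coh$taxonomy, coh$metadata,
                          coh$growth, rank = "family")
head(tb[, c("taxon", "slope", "r_squared")], 1)
#>              taxon slope r_squared
#> 21 Ruminococcaceae  21.6     0.445
```

The planted family tops the gene-count ranking (correlated with 9 of the 10
weight-linked genes at |r| > 0.8) and shows the strongest positive
abundance–weight regression. The small-sample p-value arithmetic used
throughout is exposed directly, e.g. `pearson_pvalue(0.83, 6)$p` returns
`0.0409`.

The numbered scripts under `analysis/` run the same chain as a narrated
workflow (simulate → growth contrasts → DEG screen → linkage screens →
diversity → published-table validation), writing tables under `results/`.

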