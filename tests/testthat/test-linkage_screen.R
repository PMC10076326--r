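test_that("delta GEL is zero for identical groups and constant for offsets", {
  genes <- c("g1", "g2")
  diets <- c("d1", "d2", "d3")
  ids <- as.vector(outer(c("GF1", "GF2", "FMT1", "FMT2"), diets, paste, sep = "_"))
  md <- data.frame(sample_id = ids,
                   mouse_id = ids,
                   colonization = rep(rep(c("GF", "FMT"), each = 2), 3),
                   diet = rep(diets, each = 4), tissue = "liver", week = 8)
  base <- matrix(rep(c(10, 20), 12), nrow = 2, dimnames = list(genes, ids))
  expect_true(all(compute_delta_gel(base, md, diets) == 0))
  shifted <- base
  shifted["g1", md$sample_id[md$colonization == "FMT"]] <-
    shifted["g1", md$sample_id[md$colonization == "FMT"]] + 3.5
  dg <- compute_delta_gel(shifted, md, diets)
  expect_equal(unname(dg["g1", ]), rep(3.5, 3))
  expect_equal(unname(dg["g2", ]), rep(0, 3))
  # missing group leaves an undefined column
  md_miss <- md[!(md$diet == "d3" & md$colonization == "GF"), ]
  dg_miss <- compute_delta_gel(shifted[, md_miss$sample_id], md_miss, diets)
  expect_true(all(is.na(dg_miss[, "d3"])))
})

toy_contrasts <- function(bw_abs, bw_slope = bw_abs / 8) {
  data.frame(diet = paste0("d", seq_along(bw_abs)),
             delta_bw_abs = bw_abs, delta_bw_slope = bw_slope)
}

test_that("a shift vector equal to the weight contrast is selected with r = 1", {
  bw <- c(4.2, 3.1, 5.0, 2.2, 2.9, 4.8)
  ct <- toy_contrasts(bw)
  dg <- rbind(hit = bw, noiselike = c(1, -2, 0.5, 2, -1, 0.3))
  colnames(dg) <- ct$diet
  res <- gene_weight_screen(dg, ct)
  hit <- res[res$gene == "hit", ]
  expect_equal(hit$r_abs, 1)
  expect_equal(hit$p_abs, 0)
  expect_true(hit$selected)
  expect_false(res$selected[res$gene == "noiselike"])
})

test_that("selection is inclusive at two-decimal precision and uses both columns", {
  expect_true(select_by_r(0.695, 0))    # prints as 0.70
  expect_false(select_by_r(0.694, 0))   # prints as 0.69
  expect_true(select_by_r(0, -0.71))    # slope column qualifies alone
  expect_true(select_by_r(-0.86, -0.2)) # negative r selects by absolute value
  expect_false(select_by_r(0.69, 0.69))
})

test_that("selection is invariant to positive rescaling of either side", {
  set.seed(81)
  ct <- toy_contrasts(runif(6, 1, 5))
  dg <- matrix(rnorm(60), nrow = 10,
               dimnames = list(paste0("g", 1:10), ct$diet))
  r1 <- gene_weight_screen(dg, ct)
  ct2 <- ct
  ct2$delta_bw_abs <- ct2$delta_bw_abs * 0.37
  ct2$delta_bw_slope <- ct2$delta_bw_slope * 12
  r2 <- gene_weight_screen(dg * 5.3, ct2)
  expect_equal(r1$r_abs, r2$r_abs, tolerance = 1e-12)
  expect_identical(r1$selected, r2$selected)
})

test_that("zero-variance shift vectors are excluded and few diets error", {
  ct <- toy_contrasts(c(1, 2, 3, 4, 5, 6))
  dg <- rbind(flat = rep(2, 6), ok = c(1, 2, 3, 4, 5, 7))
  colnames(dg) <- ct$diet
  res <- gene_weight_screen(dg, ct)
  expect_equal(res$gene, "ok")
  expect_equal(attr(res, "excluded"), "flat")
  expect_error(gene_weight_screen(dg[, 1:2], ct[1:2, ]), "3 usable diets")
})

test_that("rank aggregation sums counts, conserves totals and is identity at species", {
  tx <- data.frame(taxon_id = c("t1", "t2", "t3"),
                   phylum = c("P1", "P1", "P2"),
                   class = c("C1", "C1", "C2"), order = c("O1", "O1", "O2"),
                   family = c("F1", "F1", "F2"),
                   genus = c("G1", "G2", "G3"),
                   species = c("t1_s", "t2_s", "t3_s"))
  ab <- matrix(c(3, 5, 2, 1, 0, 4), nrow = 3,
               dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  fam <- aggregate_rank(ab, tx, "family")
  expect_equal(unname(fam["F1", ]), c(3 + 5, 1 + 0))
  expect_equal(colSums(fam), colSums(ab))
  sp <- aggregate_rank(ab, tx, "species")
  expect_equal(unname(sp[tx$species, ]), unname(ab[tx$taxon_id, ]))
  expect_error(aggregate_rank(ab, tx, "kingdom"), "unknown rank")
  set.seed(82)
  coh <- generate_cohort(small_config(seed = 82))
  for (rk in c("phylum", "order", "genus")) {
    agg <- aggregate_rank(coh$abundance, coh$taxonomy, rk)
    expect_equal(colSums(agg), colSums(coh$abundance))
  }
})

test_that("taxon-gene screen counts genes above the threshold", {
  coh <- generate_cohort(small_config(seed = 9))
  # plant a fake gene whose shift equals a real taxon's diet-mean abundance
  dm <- diet_mean_abundance(coh$abundance, coh$taxonomy, coh$metadata,
                            rank = "species", diets = coh$config$diets)
  target <- rownames(dm)[which.max(apply(dm, 1, var))]
  dg <- rbind(mirror = dm[target, ])
  colnames(dg) <- coh$config$diets
  res <- taxon_gene_screen(coh$abundance, coh$taxonomy, coh$metadata, dg,
                           rank = "species")
  row <- res[res$taxon == target, ]
  expect_equal(row$gene_count, 1L)
  expect_equal(row$correlated_genes, "mirror")
  expect_equal(attr(res, "r_matrix")[target, "mirror"], 1, tolerance = 1e-12)
  # an unattainable threshold empties every count
  res2 <- taxon_gene_screen(coh$abundance, coh$taxonomy, coh$metadata, dg,
                            rank = "species", r_select = 1.01)
  expect_true(all(res2$gene_count == 0))
})

test_that("taxon-weight regression recovers exact linear structure", {
  coh <- generate_cohort(small_config(seed = 10))
  md <- coh$metadata[coh$metadata$tissue == "feces" &
                       coh$metadata$colonization == "FMT", ]
  rel <- sweep(coh$abundance[, md$sample_id], 2,
               colSums(coh$abundance[, md$sample_id]), "/")
  target <- rownames(rel)[which.max(apply(rel, 1, var))]
  growth <- coh$growth
  # rewrite week-8 weights as an exact line in the target species' abundance
  sp <- coh$taxonomy$species[match(target, coh$taxonomy$taxon_id)]
  w8 <- match(paste(md$mouse_id, 8), paste(growth$mouse_id, growth$week))
  growth$bw_g[w8] <- 20 + 30 * rel[target, ]
  res <- taxon_bw_regression(coh$abundance, coh$taxonomy, coh$metadata,
                             growth, rank = "species")
  expect_equal(res$r_squared[res$taxon == sp], 1, tolerance = 1e-9)
  expect_equal(res$slope[res$taxon == sp], 30, tolerance = 1e-6)
  expect_true(all(res$r_squared >= 0 & res$r_squared <= 1 + 1e-12))
})

test_that("permutation-null R-squared has expectation 1/(n-1)", {
  set.seed(83)
  n <- 12
  a <- runif(n)
  bw <- rnorm(n, 25, 2)
  r2 <- replicate(1000, ols_line(a, sample(bw))$r_squared)
  mc_se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 3 * mc_se)
})

test_that("the chained pipeline recovers planted genes and little else", {
  coh <- generate_cohort(small_config(seed = 12))
  pl <- run_linkage_pipeline(coh$expression$eWAT, coh$metadata, coh$growth,
                             "eWAT", diets = coh$config$diets)
  planted <- names(coh$truth$planted_genes)
  sel <- pl$linkage$gene[pl$linkage$selected]
  expect_gte(length(intersect(sel, planted)), 3)  # 4 planted in this config
  expect_lte(length(setdiff(sel, planted)), 1)
  expect_true(all(pl$candidate_genes %in% rownames(coh$expression$eWAT)))
})
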