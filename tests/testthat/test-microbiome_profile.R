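test_that("alpha diversity matches hand-computed toy samples", {
  m <- cbind(uniform = c(5, 5, 5, 5))
  d <- alpha_diversity(m)
  expect_equal(d$observed, 4)
  expect_equal(d$chao1, 4)            # no singletons
  expect_equal(d$shannon, log(4), tolerance = 1e-12)
  # bias-corrected Chao1: 4 + F1(F1-1)/(2(F2+1)) = 4 + 2*1/4 = 4.5
  d2 <- alpha_diversity(cbind(s = c(1, 1, 2, 3)))
  expect_equal(d2$chao1, 4.5)
  d3 <- alpha_diversity(cbind(s = 7))
  expect_equal(d3$observed, 1)
  expect_equal(d3$shannon, 0)
  expect_equal(alpha_diversity(cbind(s = c(5, 5, 5, 5)), base = 2)$shannon, 2)
  expect_error(alpha_diversity(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
  expect_error(alpha_diversity(cbind(a = c(0.5, 1))), "integers")
})

test_that("Jensen-Shannon divergence matches hand-evaluated cases", {
  p <- c(0.5, 0.5, 0)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)          # disjoint supports, base 2
  expect_equal(jsd(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_error(jsd(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  expect_error(jsd(c(0.2, 0.2), c(0.5, 0.5)), "sum to 1")
  profiles <- cbind(a = c(0.5, 0.5, 0), b = c(0, 0.5, 0.5), c = c(1, 0, 0))
  dm <- jsd_matrix(profiles)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_equal(dm["a", "b"], sqrt(0.5), tolerance = 1e-12)
})

test_that("sqrt-JSD satisfies the triangle inequality on random profiles", {
  set.seed(91)
  for (i in 1:1000) {
    pr <- matrix(rgamma(15, 0.5), nrow = 5)
    pr <- sweep(pr, 2, colSums(pr), "/")
    d_ab <- sqrt(jsd(pr[, 1], pr[, 2]))
    d_bc <- sqrt(jsd(pr[, 2], pr[, 3]))
    d_ac <- sqrt(jsd(pr[, 1], pr[, 3]))
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("PCoA embeds collinear points and round-trips Euclidean clouds", {
  pts <- c(0, 1, 3)
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  ax1 <- res$coordinates[, 1]
  expect_equal(as.matrix(dist(ax1)), d, ignore_attr = TRUE, tolerance = 1e-8)
  # spectral identity: eigenvalues sum to the trace of the centered matrix
  b <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  expect_lte(sum(res$eigenvalues[res$eigenvalues > 0]), sum(diag(b)) + 1e-10)
  set.seed(92)
  cloud <- matrix(rnorm(30), ncol = 3)
  dc <- as.matrix(dist(cloud))
  rec <- pcoa(dc, k = 3)
  expect_equal(as.matrix(dist(rec$coordinates)), dc, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA reproduces the one-step hand example", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 6)
  expect_equal(cp["B", "C"], 6)
  # root-to-leaf depths all 3: ((A:1,B:1):2,C:3)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(3, 3))
})

test_that("UPGMA output is ultrametric and fixed on ultrametric input", {
  set.seed(93)
  pts <- matrix(rnorm(12), ncol = 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  tr <- upgma(d)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(max(depths) - min(depths), 1e-10)
  # rerunning on the tree's own cophenetic matrix reproduces it exactly
  cp <- ape::cophenetic.phylo(tr)
  tr2 <- upgma(cp[rownames(d), colnames(d)])
  cp2 <- ape::cophenetic.phylo(tr2)
  expect_equal(cp2[rownames(cp), colnames(cp)], cp, tolerance = 1e-12)
})

test_that("UPGMA ties break toward the lexicographically smallest pair", {
  d <- matrix(2, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(d) <- 0
  tr <- upgma(d)
  nw <- ape::write.tree(tr)
  expect_match(nw, "\\(A:1,B:1\\)")   # A,B merged first despite input order
  expect_identical(ape::write.tree(upgma(d)), nw)  # deterministic
})

test_that("unweighted UniFrac matches hand-computed branch fractions", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  counts <- matrix(c(1, 0, 0, 0,
                     0, 1, 0, 0,
                     0, 0, 1, 0,
                     1, 0, 0, 0), nrow = 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3", "s4"), c("A", "B", "C", "D")))
  counts <- t(counts)
  d <- unweighted_unifrac(counts, tree)
  expect_equal(d["s1", "s2"], 2 / 3)  # unique A+B over union incl. shared stem
  expect_equal(d["s1", "s3"], 1.0)    # no shared observed branches
  expect_equal(d["s1", "s4"], 0)      # identical presence sets
  expect_equal(d, t(d))
  expect_error(unweighted_unifrac(rbind(counts, E = c(1, 1, 1, 1)), tree),
               "E")
})

test_that("UniFrac is zero exactly for equal presence sets on random data", {
  set.seed(94)
  tree <- ape::rtree(12, br = rexp)
  comm <- matrix(rbinom(48, 1, 0.5), nrow = 4,
                 dimnames = list(paste0("s", 1:4), tree$tip.label))
  comm[2, ] <- comm[1, ]  # duplicate presence set
  d <- unweighted_unifrac(t(comm), tree)
  expect_equal(d["s1", "s2"], 0)
  off <- d[upper.tri(d)]
  pres_equal <- outer(1:4, 1:4, Vectorize(function(i, j) all(comm[i, ] == comm[j, ])))
  expect_identical(unname(d == 0), pres_equal)
})

test_that("rarefaction hits the target depth deterministically", {
  coh <- generate_cohort(small_config(seed = 13))
  md <- coh$metadata[coh$metadata$tissue == "feces" &
                       coh$metadata$colonization == "FMT", ]
  counts <- coh$abundance[, md$sample_id]
  r1 <- rarefy_counts(counts, depth = 5000, seed = 4)
  expect_true(all(colSums(r1) == 5000))
  expect_identical(r1, rarefy_counts(counts, depth = 5000, seed = 4))
  low <- counts
  low[, 1] <- 0
  expect_warning(r2 <- rarefy_counts(low, depth = 5000, seed = 4), "below depth")
  expect_equal(ncol(r2), ncol(counts) - 1)
})

test_that("diversity and ordination run end to end on a synthetic cohort", {
  coh <- generate_cohort(small_config(seed = 14))
  md <- coh$metadata[coh$metadata$tissue == "feces" &
                       coh$metadata$colonization == "FMT", ]
  counts <- coh$abundance[, md$sample_id]
  div <- alpha_diversity(counts)
  expect_true(all(div$chao1 >= div$observed))
  expect_true(all(div$shannon >= 0))
  rel <- sweep(counts, 2, colSums(counts), "/")
  dm <- jsd_matrix(rel)
  ord <- pcoa(dm, k = 2)
  expect_equal(nrow(ord$coordinates), ncol(counts))
  tr <- upgma(unweighted_unifrac(counts, coh$tree))
  expect_setequal(tr$tip.label, colnames(counts))
})
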