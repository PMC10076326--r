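#' Alpha diversity per sample
#'
#' Observed taxa, bias-corrected Chao1 richness and Shannon entropy for each
#' sample (column) of a count table. Chao1 uses the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (defined even when there are no
#' doubletons); Shannon is `-sum p_i log p_i` in natural log by default.
#' All-zero samples are an error: germ-free samples must be filtered out
#' upstream.
#'
#' @param counts Taxa x samples matrix of non-negative integer counts.
#' @param base Logarithm base for Shannon (default `exp(1)` for nats).
#' @return Data frame: `sample`, `observed`, `chao1`, `shannon`.
#' @examples
#' alpha_diversity(matrix(c(5, 5, 5, 5), 4, dimnames = list(NULL, "s1")))
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "),
         " (filter germ-free samples before diversity analysis)")
  est <- vegan::estimateR(t(counts))
  shannon <- vegan::diversity(t(counts), index = "shannon", base = base)
  data.frame(sample = colnames(counts),
             observed = unname(est["S.obs", ]),
             chao1 = unname(est["S.chao1", ]),
             shannon = unname(shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Jensen-Shannon divergence between two profiles
#'
#' `JSD(P, Q) = KL(P||M)/2 + KL(Q||M)/2` with `M = (P + Q)/2`, log base 2,
#' and the convention `0 log 0 = 0`, so JSD lies in `[0, 1]` and equals 1
#' for disjoint supports.
#'
#' @param p,q Non-negative profiles, each summing to 1 (within `1e-6`).
#' @return The divergence (not its square root).
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("profiles must have the same length")
  if (any(p < 0) || any(q < 0)) stop("profiles must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("profiles must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Jensen-Shannon distance matrix
#'
#' Pairwise distances between sample profiles. The default distance is
#' `sqrt(JSD)` (a metric satisfying the triangle inequality); the raw
#' divergence is available with `sqrt = FALSE`.
#'
#' @param profiles Taxa x samples matrix of relative abundances (each
#'   column summing to 1 within `1e-6`).
#' @param sqrt_dist Return `sqrt(JSD)` (default) or raw JSD.
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
jsd_matrix <- function(profiles, sqrt_dist = TRUE) {
  n <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- jsd(profiles[, i], profiles[, j])
      d[i, j] <- d[j, i] <- if (sqrt_dist) sqrt(v) else v
    }
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical multidimensional scaling of a distance matrix: eigendecompose
#' the double-centered `-D^2/2`, take coordinates `eigvec * sqrt(eigval)`
#' on the positive eigenvalues. Negative eigenvalues (non-Euclidean input)
#' are reported, with a warning when their magnitude is substantial, never
#' silently dropped or corrected.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of coordinates (default `n - 1`, trimmed to the positive
#'   eigenvalues).
#' @return A list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending) and `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  if (is.null(k)) k <- n - 1
  if (k > n - 1) stop("k must be at most n - 1")
  fit <- stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE)
  eig <- fit$eig
  neg <- eig[eig < 0]
  if (length(neg) && max(abs(neg)) > 0.01 * max(eig))
    warning(sprintf("negative eigenvalues up to %.3g (%.1f%% of the largest); input is non-Euclidean",
                    max(abs(neg)), 100 * max(abs(neg)) / max(eig)))
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- fit$points[, seq_len(min(k, sum(pos))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration: repeatedly merge the closest pair of
#' clusters, updating distances as the size-weighted average, with node
#' heights at half the merge distance, so the output tree is ultrametric
#' and its cophenetic distances reproduce an ultrametric input exactly.
#' Ties between candidate pairs are broken toward the lexicographically
#' smallest label pair, making the output deterministic.
#'
#' @param d Symmetric distance matrix with labels (or `dist`).
#' @return An [ape::phylo] rooted ultrametric tree.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 items")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  # active clusters: newick fragment, size, height, representative label
  newick <- as.list(labels)
  size <- rep(1, n)
  height <- rep(0, n)
  rep_lab <- labels
  active <- rep(TRUE, n)
  dm <- m
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    best_d <- Inf
    for (a in idx) {
      for (b in idx) {
        if (b <= a) next
        dd <- dm[a, b]
        better <- dd < best_d - 1e-15
        tie <- abs(dd - best_d) <= 1e-15
        if (better || (tie && !is.null(best) &&
                       lex_less(rep_lab[c(a, b)], rep_lab[best]))) {
          best <- c(a, b)
          best_d <- min(dd, best_d)
        }
      }
    }
    a <- best[1]; b <- best[2]
    h <- dm[a, b] / 2
    frag <- sprintf("(%s:%.17g,%s:%.17g)", newick[[a]], h - height[a],
                    newick[[b]], h - height[b])
    # size-weighted average distance to the merged cluster
    for (cc in idx) {
      if (cc == a || cc == b) next
      dm[a, cc] <- dm[cc, a] <-
        (size[a] * dm[a, cc] + size[b] * dm[b, cc]) / (size[a] + size[b])
    }
    newick[[a]] <- frag
    size[a] <- size[a] + size[b]
    height[a] <- h
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    active[b] <- FALSE
  }
  ape::read.tree(text = paste0(newick[[which(active)]], ";"))
}

lex_less <- function(pair_a, pair_b) {
  pa <- sort(pair_a)
  pb <- sort(pair_b)
  if (pa[1] != pb[1]) return(pa[1] < pb[1])
  pa[2] < pb[2]
}

#' Unweighted UniFrac distance matrix
#'
#' Fraction of phylogenetic branch length leading to taxa observed in
#' exactly one of the two communities, over the branch length leading to
#' taxa observed in either. Presence/absence only; computed with
#' [picante::unifrac()] after validating that every observed taxon is a tip
#' of the tree.
#'
#' @param counts Taxa x samples matrix (counts or presence).
#' @param tree Rooted [ape::phylo] with non-negative branch lengths whose
#'   tips cover every taxon observed in `counts`.
#' @return Symmetric samples x samples distance matrix.
#' @export
unweighted_unifrac <- function(counts, tree) {
  counts <- as.matrix(counts)
  observed <- rownames(counts)[rowSums(counts > 0) > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing))
    stop("taxa observed but missing from the tree: ",
         paste(missing, collapse = ", "))
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  comm <- t(counts)
  keep <- intersect(colnames(comm), tree$tip.label)
  d <- picante::unifrac(comm[, keep, drop = FALSE],
                        ape::keep.tip(tree, keep))
  as.matrix(d)
}

#' Rarefy a count table to equal depth
#'
#' Optional seeded subsampling of each sample to a fixed number of reads
#' (without replacement), mirroring the fixed-depth subsampling used in 16S
#' pipelines. Samples below the target depth are dropped with a warning.
#'
#' @param counts Taxa x samples integer matrix.
#' @param depth Reads to keep per sample.
#' @param seed Integer seed.
#' @return Rarefied taxa x samples matrix.
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  low <- tot < depth
  if (any(low)) {
    warning("dropping samples below depth ", depth, ": ",
            paste(colnames(counts)[low], collapse = ", "))
    counts <- counts[, !low, drop = FALSE]
  }
  set.seed(seed)
  t(vegan::rrarefy(t(counts), sample = depth))
}
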