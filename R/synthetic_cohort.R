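#' Configuration for a synthetic gnotobiotic cohort
#'
#' Builds and validates the configuration of the synthetic-cohort generator.
#' The generator emulates a two-arm gnotobiotic feeding study: germ-free
#' (GF) mice and fecal-microbiota-transplant (FMT) mice fed six diets, with
#' weekly body weights, endpoint tissue transcriptomes, and endpoint fecal
#' 16S profiles. A subset of genes and taxa is "planted": their FMT-vs-GF
#' shift scales with a per-diet effect `u_d`, the same quantity that drives
#' the extra FMT growth, so the planted features are recoverable by the
#' downstream correlation screens and everything else is null.
#'
#' Defaults mirror the study design the package models: 2 colonization
#' states x 6 diets, group sizes (4, 7, 4, 7, 4, 4), weekly weights over
#' weeks 0-8, seven tissues, and a fecal sample per mouse at week 8.
#'
#' @param diets Character vector of diet labels (order is the canonical diet
#'   order used by every downstream vector).
#' @param n_mice_per_cell Integer vector, mice per colonization x diet cell,
#'   recycled along `diets`.
#' @param weeks Strictly increasing non-negative observation weeks.
#' @param tissues Tissue labels for the expression layer.
#' @param n_genes,n_planted_genes Genes per tissue and how many carry a
#'   planted diet-scaled FMT shift.
#' @param n_taxa,n_planted_taxa Taxa in the abundance table and how many
#'   carry a planted diet-scaled abundance shift.
#' @param planted_family_size How many planted taxa share the planted family
#'   (the rest get families of their own).
#' @param diet_effect Named (or ordered) numeric vector `u_d`, one
#'   dimensionless effect per diet; drives FMT extra growth, planted gene
#'   shifts and planted taxon shifts alike.
#' @param base_slope_gf Named or ordered numeric vector, GF growth slope per
#'   diet (g/week).
#' @param effect_scale_bw Extra FMT slope per unit diet effect (g/week).
#' @param effect_scale_gel Planted-gene shift scale: in diet `d` a planted
#'   gene's FMT mean is `base * (1 + effect_scale_gel * g_k * u_d)` with
#'   signed gain `g_k`, so the cross-diet expression shift is exactly
#'   proportional to `u_d`.
#' @param noise_sd_bw Body-weight residual SD (g).
#' @param noise_cv_expr Coefficient of variation of expression replicates.
#' @param taxon_effect_scale Planted-taxon shift scale `h` (log abundance per
#'   unit diet effect).
#' @param library_size Reads per microbiome sample.
#' @param dirichlet_conc Concentration of the per-sample Dirichlet draw
#'   around the diet composition (larger = less compositional noise).
#' @param diet_wobble_sd Log-normal SD of the per-taxon, per-diet tilt applied
#'   to the base composition (diet-driven variation of non-planted taxa).
#' @param baseline_bw_mean,baseline_bw_sd Mouse baseline weight (g) at week 0.
#' @param seed Integer seed; all sub-generators derive fixed-offset
#'   substreams from it.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(diets = c("ND", "StaHC", "SucHC", "FruHC", "SaHF", "USaHF"),
                          n_mice_per_cell = c(4L, 7L, 4L, 7L, 4L, 4L),
                          weeks = 0:8,
                          tissues = c("iWAT", "eWAT", "BAT", "muscle",
                                      "liver", "duodenum", "ileum"),
                          n_genes = 200L,
                          n_planted_genes = 10L,
                          n_taxa = 150L,
                          n_planted_taxa = 5L,
                          planted_family_size = 3L,
                          diet_effect = c(ND = 1.0, StaHC = 0.85, SucHC = 1.3,
                                          FruHC = 0.55, SaHF = 0.75, USaHF = 1.15),
                          base_slope_gf = c(ND = 0.35, StaHC = 0.33, SucHC = 0.34,
                                            FruHC = 0.30, SaHF = 0.38, USaHF = 0.37),
                          effect_scale_bw = 0.8,
                          effect_scale_gel = 0.7,
                          noise_sd_bw = 0.5,
                          noise_cv_expr = 0.1,
                          taxon_effect_scale = 1.5,
                          library_size = 20000L,
                          dirichlet_conc = 150,
                          diet_wobble_sd = 0.1,
                          baseline_bw_mean = 20,
                          baseline_bw_sd = 1,
                          seed = 1L) {
  stopifnot(length(diets) >= 1, !anyDuplicated(diets))
  n_mice_per_cell <- as.integer(rep_len(n_mice_per_cell, length(diets)))
  if (any(n_mice_per_cell < 1)) stop("invalid config: n_mice_per_cell must be >= 1")
  if (length(weeks) < 2 || any(diff(weeks) <= 0))
    stop("invalid config: weeks must be strictly increasing")
  if (any(weeks < 0)) stop("invalid config: weeks must be non-negative")
  counts <- c(n_genes = n_genes, n_planted_genes = n_planted_genes,
              n_taxa = n_taxa, n_planted_taxa = n_planted_taxa,
              library_size = library_size)
  if (any(counts < 0) || n_genes < 1 || n_taxa < 1)
    stop("invalid config: counts must be positive")
  if (n_planted_genes > n_genes)
    stop("invalid config: n_planted_genes exceeds n_genes")
  if (n_planted_taxa > n_taxa)
    stop("invalid config: n_planted_taxa exceeds n_taxa")
  if (n_planted_taxa > 0 && planted_family_size < 1)
    stop("invalid config: planted taxa require planted_family_size >= 1")
  if (planted_family_size > max(n_planted_taxa, 0))
    stop("invalid config: planted_family_size exceeds n_planted_taxa")
  if (noise_sd_bw < 0 || noise_cv_expr < 0 || diet_wobble_sd < 0)
    stop("invalid config: noise parameters must be >= 0")
  if (dirichlet_conc <= 0) stop("invalid config: dirichlet_conc must be > 0")
  diet_effect <- align_diet_vector(diet_effect, diets, "diet_effect")
  base_slope_gf <- align_diet_vector(base_slope_gf, diets, "base_slope_gf")
  if (abs(effect_scale_gel) * max(abs(diet_effect)) >= 1)
    stop("invalid config: |effect_scale_gel * u_d| must stay below 1 so planted means remain positive")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || abs(seed) >= 2^31 - 16)
    stop("invalid config: seed must be a 32-bit integer")
  structure(list(
    diets = diets, n_mice_per_cell = n_mice_per_cell, weeks = weeks,
    tissues = tissues, n_genes = as.integer(n_genes),
    n_planted_genes = as.integer(n_planted_genes),
    n_taxa = as.integer(n_taxa), n_planted_taxa = as.integer(n_planted_taxa),
    planted_family_size = as.integer(planted_family_size),
    diet_effect = diet_effect, base_slope_gf = base_slope_gf,
    effect_scale_bw = effect_scale_bw, effect_scale_gel = effect_scale_gel,
    noise_sd_bw = noise_sd_bw, noise_cv_expr = noise_cv_expr,
    taxon_effect_scale = taxon_effect_scale,
    library_size = as.integer(library_size),
    dirichlet_conc = dirichlet_conc, diet_wobble_sd = diet_wobble_sd,
    baseline_bw_mean = baseline_bw_mean, baseline_bw_sd = baseline_bw_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

align_diet_vector <- function(v, diets, what) {
  if (!is.null(names(v))) {
    if (!all(diets %in% names(v)))
      stop("invalid config: ", what, " is missing diets ",
           paste(setdiff(diets, names(v)), collapse = ", "))
    v <- v[diets]
  } else {
    v <- stats::setNames(rep_len(v, length(diets)), diets)
  }
  v
}

# Fixed seed offsets for the per-table substreams: adding a table never
# perturbs the draws of another.
.seed_offsets <- c(truth = 0L, growth = 1L, expression = 2L,
                   abundance = 3L, tree = 4L)

substream_seed <- function(config, table) {
  config$seed + .seed_offsets[[table]]
}

#' Ground truth of a synthetic cohort
#'
#' Draws the planted structure: which genes and taxa carry diet-scaled
#' shifts, their signed gains, the planted family, and the true growth
#' slopes per diet x colonization cell. The FMT minus GF true slope in diet
#' `d` equals `effect_scale_bw * u_d` by construction.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"ground_truth"` with `diet_effect`,
#'   `planted_genes` (named gains `g_k`), `planted_taxa` (named gains `h_j`),
#'   `planted_family`, and `bw_slopes` (diet x colonization true slopes).
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config, "truth"))
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  taxon_ids <- sprintf("t%03d", seq_len(config$n_taxa))
  pg <- sort(sample(gene_ids, config$n_planted_genes))
  gains <- stats::setNames(
    sample(c(-1, 1), length(pg), replace = TRUE) * stats::runif(length(pg), 0.8, 1.0),
    pg)
  pt <- sort(sample(taxon_ids, config$n_planted_taxa))
  h <- stats::setNames(
    stats::runif(length(pt), 0.9, 1.1) * config$taxon_effect_scale, pt)
  in_family <- pt[seq_len(min(config$planted_family_size, length(pt)))]
  slopes <- expand.grid(diet = config$diets, colonization = c("GF", "FMT"),
                        stringsAsFactors = FALSE)
  slopes$slope <- config$base_slope_gf[slopes$diet] +
    ifelse(slopes$colonization == "FMT",
           config$effect_scale_bw * config$diet_effect[slopes$diet], 0)
  structure(list(
    diet_effect = config$diet_effect,
    planted_genes = gains,
    planted_taxa = h,
    planted_family = "Ruminococcaceae",
    planted_in_family = in_family,
    gene_ids = gene_ids,
    taxon_ids = taxon_ids,
    bw_slopes = slopes
  ), class = "ground_truth")
}

#' Sample metadata for a synthetic cohort
#'
#' One mouse per colonization x diet x replicate; one expression sample per
#' mouse and tissue; one fecal microbiome sample per mouse, collected at the
#' final observation week.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `sample_id`, `mouse_id`,
#'   `colonization`, `diet`, `tissue`, `week`. Mouse-level rows can be
#'   recovered with `unique()` over `mouse_id`.
#' @export
make_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rows <- list()
  final_week <- max(config$weeks)
  for (di in seq_along(config$diets)) {
    diet <- config$diets[di]
    n <- config$n_mice_per_cell[di]
    for (col in c("GF", "FMT")) {
      mice <- sprintf("%s_%s_m%02d", diet, col, seq_len(n))
      for (tis in config$tissues) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(mice, tis, sep = "."), mouse_id = mice,
          colonization = col, diet = diet, tissue = tis,
          week = final_week, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste(mice, "feces", sep = "."), mouse_id = mice,
        colonization = col, diet = diet, tissue = "feces",
        week = final_week, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate body-weight growth series
#'
#' Per-mouse linear growth `BW_i(t) = b0_i + s_{d,c} t + e`, with
#' `e ~ N(0, noise_sd_bw^2)`, baseline `b0_i ~ N(baseline_bw_mean,
#' baseline_bw_sd^2)` truncated positive, and true slopes from the ground
#' truth (so the FMT minus GF slope gap in diet `d` is exactly
#' `effect_scale_bw * u_d`).
#'
#' @param config A [cohort_config()].
#' @param truth A [make_ground_truth()] result for the same config.
#' @param metadata Optional precomputed [make_metadata()] result.
#' @return A data.frame with columns `mouse_id`, `week`, `bw_g`.
#' @export
generate_growth <- function(config, truth, metadata = make_metadata(config)) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "ground_truth"))
  set.seed(substream_seed(config, "growth"))
  mice <- unique(metadata[, c("mouse_id", "colonization", "diet")])
  slope_key <- paste(truth$bw_slopes$diet, truth$bw_slopes$colonization)
  slopes <- stats::setNames(truth$bw_slopes$slope, slope_key)
  out <- vector("list", nrow(mice))
  for (i in seq_len(nrow(mice))) {
    b0 <- stats::rnorm(1, config$baseline_bw_mean, config$baseline_bw_sd)
    while (b0 <= 0) b0 <- stats::rnorm(1, config$baseline_bw_mean, config$baseline_bw_sd)
    s <- slopes[[paste(mice$diet[i], mice$colonization[i])]]
    bw <- b0 + s * config$weeks +
      stats::rnorm(length(config$weeks), 0, config$noise_sd_bw)
    out[[i]] <- data.frame(mouse_id = mice$mouse_id[i], week = config$weeks,
                           bw_g = bw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$bw_g <= 0))
    stop("generated non-positive body weight; reduce noise_sd_bw or raise baseline_bw_mean")
  res
}

#' Generate per-tissue expression matrices
#'
#' Log-normal expression around gene- and tissue-specific baselines.
#' Non-planted genes have identical GF and FMT means. A planted gene `k`
#' with signed gain `g_k` has its FMT mean multiplied by
#' `1 + effect_scale_gel * g_k * u_d` in diet `d`, making the cross-diet
#' FMT minus GF mean shift exactly proportional to the diet effect `u_d`.
#' Replicate noise is a mean-one log-normal with coefficient of variation
#' `noise_cv_expr`, so expectations are exact.
#'
#' @inheritParams generate_growth
#' @return A named list, one `genes x samples` numeric matrix per tissue.
#' @export
generate_expression <- function(config, truth, metadata = make_metadata(config)) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "ground_truth"))
  set.seed(substream_seed(config, "expression"))
  sdlog <- sqrt(log(1 + config$noise_cv_expr^2))
  gene_ids <- truth$gene_ids
  planted <- truth$planted_genes
  u <- truth$diet_effect
  out <- list()
  for (tis in config$tissues) {
    md <- metadata[metadata$tissue == tis, ]
    base <- exp(stats::rnorm(config$n_genes, mean = 3, sd = 1))
    names(base) <- gene_ids
    m <- matrix(0, nrow = config$n_genes, ncol = nrow(md),
                dimnames = list(gene_ids, md$sample_id))
    for (j in seq_len(nrow(md))) {
      mu <- base
      if (md$colonization[j] == "FMT" && length(planted)) {
        shift <- 1 + config$effect_scale_gel * planted * u[[md$diet[j]]]
        if (any(shift <= 0)) stop("invalid config: planted FMT mean would be non-positive")
        mu[names(planted)] <- mu[names(planted)] * shift
      }
      noise <- if (sdlog > 0)
        exp(stats::rnorm(config$n_genes, -sdlog^2 / 2, sdlog)) else rep(1, config$n_genes)
      m[, j] <- mu * noise
    }
    out[[tis]] <- m
  }
  out
}

# Draw one Dirichlet vector with parameter alpha (via normalized gammas).
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate taxon count table, taxonomy map and phylogeny
#'
#' FMT samples draw `counts ~ multinomial(library_size, p)` with
#' `p ~ Dirichlet(conc * p_d)`, where the diet composition `p_d` is the base
#' composition tilted per taxon by a log-normal diet wobble and, for planted
#' taxon `j`, scaled by `exp(h_j * u_d)`. GF mice carry no microbiota and
#' get all-zero columns (they are excluded from diversity and linkage
#' stages downstream). Planted taxa are assigned to the planted family
#' (`planted_family_size` of them) or to singleton families of their own.
#' The phylogeny is a random bifurcating tree over all taxa with
#' exponential(1) branch lengths; only its branch-set structure is used by
#' unweighted UniFrac.
#'
#' @inheritParams generate_growth
#' @return A list with `abundance` (taxa x samples integer matrix, fecal
#'   samples only), `taxonomy` (data.frame: `taxon_id`, ranks `phylum` ...
#'   `species`, `lineage`), and `tree` (an [ape::phylo] with tip labels
#'   matching taxon ids).
#' @export
generate_abundance <- function(config, truth, metadata = make_metadata(config)) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "ground_truth"))
  if (config$library_size < config$n_taxa)
    warning("library_size is below n_taxa; many taxa will be unobserved")
  taxonomy <- make_taxonomy(config, truth)
  set.seed(substream_seed(config, "tree"))
  tree <- ape::rtree(config$n_taxa, rooted = TRUE, tip.label = truth$taxon_ids,
                     br = stats::rexp)
  set.seed(substream_seed(config, "abundance"))
  base <- exp(stats::rnorm(config$n_taxa, 0, 1.5))
  names(base) <- truth$taxon_ids
  # members of the planted family get a solid, narrowly jittered base so the
  # family sits well above the count-noise floor; solo planted taxa keep
  # ordinary random bases and stay diluted inside their host families
  base[truth$planted_in_family] <-
    exp(stats::rnorm(length(truth$planted_in_family), 1.5, 0.3))
  wobble <- matrix(exp(stats::rnorm(config$n_taxa * length(config$diets),
                                    0, config$diet_wobble_sd)),
                   nrow = config$n_taxa,
                   dimnames = list(truth$taxon_ids, config$diets))
  md <- metadata[metadata$tissue == "feces", ]
  counts <- matrix(0L, nrow = config$n_taxa, ncol = nrow(md),
                   dimnames = list(truth$taxon_ids, md$sample_id))
  for (d in config$diets) {
    p_d <- base * wobble[, d]
    if (length(truth$planted_taxa)) {
      p_d[names(truth$planted_taxa)] <-
        p_d[names(truth$planted_taxa)] *
        exp(truth$planted_taxa * truth$diet_effect[[d]])
    }
    p_d <- p_d / sum(p_d)
    for (j in which(md$diet == d)) {
      if (md$colonization[j] != "FMT") next
      p <- rdirichlet1(config$dirichlet_conc * p_d)
      counts[, j] <- stats::rmultinom(1, config$library_size, p)[, 1]
    }
  }
  list(abundance = counts, taxonomy = taxonomy, tree = tree)
}

# Deterministic synthetic taxonomy: a small rank hierarchy with the planted
# family fixed to Ruminococcaceae (Bacillota; Clostridia; Clostridiales).
make_taxonomy <- function(config, truth) {
  set.seed(substream_seed(config, "truth") + 7L)
  phyla <- c("Bacillota", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia")
  n_fam <- 20L
  fam_ids <- sprintf("Fam%02d", seq_len(n_fam))
  fam_phylum <- sample(phyla, n_fam, replace = TRUE)
  fam_class <- paste0(fam_phylum, "_c", sample(1:2, n_fam, replace = TRUE))
  fam_order <- paste0(fam_class, "_o", sample(1:2, n_fam, replace = TRUE))
  taxon_ids <- truth$taxon_ids
  planted <- names(truth$planted_taxa)
  in_family <- truth$planted_in_family
  fam <- sample(fam_ids, config$n_taxa, replace = TRUE)
  names(fam) <- taxon_ids
  phylum <- stats::setNames(stats::setNames(fam_phylum, fam_ids)[fam], taxon_ids)
  cls <- stats::setNames(stats::setNames(fam_class, fam_ids)[fam], taxon_ids)
  ord <- stats::setNames(stats::setNames(fam_order, fam_ids)[fam], taxon_ids)
  fam_lab <- fam
  # planted family: fixed lineage. The remaining planted taxa keep their
  # random family assignment, so at family rank they are diluted among null
  # co-members while the planted family concentrates its members' signal.
  fam_lab[in_family] <- "Ruminococcaceae"
  phylum[in_family] <- "Bacillota"
  cls[in_family] <- "Clostridia"
  ord[in_family] <- "Clostridiales"
  genus <- paste0(fam_lab, "_g", 1 + (seq_len(config$n_taxa) %% 2))
  species <- paste0(taxon_ids, "_s")
  data.frame(
    taxon_id = taxon_ids, phylum = unname(phylum), class = unname(cls),
    order = unname(ord), family = unname(fam_lab), genus = genus,
    species = species,
    lineage = paste(phylum, cls, ord, fam_lab, genus, species, sep = ";"),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Runs all sub-generators under fixed-offset substreams of one seed and
#' returns every layer plus the recorded ground truth. Identical
#' configuration and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"gnoto_cohort"` with `config`, `truth`,
#'   `metadata`, `growth`, `expression` (list of matrices per tissue),
#'   `abundance`, `taxonomy`, `tree`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_genes = 20, n_taxa = 30,
#'                                      tissues = "liver", seed = 42))
#' str(coh$truth$planted_genes)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- make_ground_truth(config)
  metadata <- make_metadata(config)
  growth <- generate_growth(config, truth, metadata)
  expression <- generate_expression(config, truth, metadata)
  ab <- generate_abundance(config, truth, metadata)
  structure(list(config = config, truth = truth, metadata = metadata,
                 growth = growth, expression = expression,
                 abundance = ab$abundance, taxonomy = ab$taxonomy,
                 tree = ab$tree),
            class = "gnoto_cohort")
}

#' @export
print.gnoto_cohort <- function(x, ...) {
  cat(sprintf("Synthetic gnotobiotic cohort: %d diets x 2 colonizations, %d mice\n",
              length(x$config$diets), length(unique(x$growth$mouse_id))))
  cat(sprintf("  tissues: %s\n", paste(x$config$tissues, collapse = ", ")))
  cat(sprintf("  genes: %d (%d planted), taxa: %d (%d planted, family %s)\n",
              x$config$n_genes, length(x$truth$planted_genes),
              x$config$n_taxa, length(x$truth$planted_taxa),
              x$truth$planted_family))
  invisible(x)
}
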