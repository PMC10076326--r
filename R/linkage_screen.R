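#' Per-diet expression shift matrix (delta GEL)
#'
#' For one tissue, the microbiota-attributable expression shift of every
#' gene in every diet: mean over FMT samples minus mean over GF samples, on
#' the expression scale of the input (no log). This is the gene-side vector
#' of the cross-diet correlation screen.
#'
#' @param expr Genes x samples matrix for one tissue.
#' @param metadata Sample metadata.
#' @param diets Diet order of the columns; defaults to order of appearance.
#' @param log_scale If `TRUE`, means are taken on `log2(x + 1)` instead of
#'   the input scale.
#' @return Genes x diets numeric matrix. A diet missing either colonization
#'   group yields an all-`NA` column (genes with any undefined diet are
#'   dropped later by the screen).
#' @export
compute_delta_gel <- function(expr, metadata, diets = NULL, log_scale = FALSE) {
  if (is.null(diets)) diets <- unique(metadata$diet)
  md <- metadata[metadata$sample_id %in% colnames(expr), ]
  x <- if (log_scale) log2(expr + 1) else expr
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = length(diets),
                dimnames = list(rownames(expr), diets))
  for (d in diets) {
    fmt <- md$sample_id[md$diet == d & md$colonization == "FMT"]
    gf <- md$sample_id[md$diet == d & md$colonization == "GF"]
    if (length(fmt) == 0 || length(gf) == 0) next
    out[, d] <- rowMeans(x[, fmt, drop = FALSE]) - rowMeans(x[, gf, drop = FALSE])
  }
  out
}

#' Cross-diet gene-weight correlation screen
#'
#' The core linkage computation: per gene, the Pearson correlation across
#' diets between the expression shift vector (delta GEL) and each of the
#' two microbiota-attributable weight differences — absolute gain
#' (`delta_bw_abs`, g) and slope difference (`delta_bw_slope`, g/week).
#' A gene is selected when `max(|r_abs|, |r_slope|)` reaches `r_select` at
#' two-decimal precision (inclusive, so a printed 0.70 qualifies); negative
#' correlations select by absolute value.
#'
#' @param delta_gel Genes x diets matrix from [compute_delta_gel()].
#' @param contrasts Per-diet contrast table from [diet_contrasts()] (or any
#'   data.frame with `diet`, `delta_bw_abs`, `delta_bw_slope`).
#' @param r_select Selection threshold on |r| (default 0.70).
#' @return Data frame: `gene`, `r_abs`, `p_abs`, `r_slope`, `p_slope`,
#'   `selected`. Genes with an undefined diet column or zero-variance shift
#'   vector are excluded; their ids and the reason are attached as
#'   attribute `"excluded"`.
#' @export
gene_weight_screen <- function(delta_gel, contrasts, r_select = 0.70) {
  diets <- colnames(delta_gel)
  if (!all(diets %in% contrasts$diet))
    stop("contrast table is missing diets: ",
         paste(setdiff(diets, contrasts$diet), collapse = ", "))
  bw_abs <- contrasts$delta_bw_abs[match(diets, contrasts$diet)]
  bw_slope <- contrasts$delta_bw_slope[match(diets, contrasts$diet)]
  usable <- colSums(is.na(delta_gel)) == 0
  if (sum(usable) < ncol(delta_gel)) {
    delta_gel <- delta_gel[, usable, drop = FALSE]
    bw_abs <- bw_abs[usable]
    bw_slope <- bw_slope[usable]
  }
  if (ncol(delta_gel) < 3) stop("fewer than 3 usable diets")
  excluded <- character(0)
  rows <- lapply(rownames(delta_gel), function(g) {
    v <- delta_gel[g, ]
    if (stats::var(v) == 0) {
      excluded[[length(excluded) + 1L]] <<- g
      return(NULL)
    }
    ca <- pearson_cor(v, bw_abs)
    cs <- pearson_cor(v, bw_slope)
    data.frame(gene = g, r_abs = ca$r, p_abs = ca$p_two_sided,
               r_slope = cs$r, p_slope = cs$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), r_abs = numeric(0), p_abs = numeric(0),
                      r_slope = numeric(0), p_slope = numeric(0))
  }
  out$selected <- select_by_r(out$r_abs, out$r_slope, r_select)
  attr(out, "excluded") <- excluded
  attr(out, "n_diets") <- ncol(delta_gel)
  out
}

#' Gene selection rule of the cross-diet correlation screen
#'
#' A gene is selected when the larger of its two absolute correlations
#' (vs the absolute weight gain and vs the slope difference) reaches the
#' threshold at two-decimal precision — inclusive, so a correlation printed
#' as 0.70 qualifies, and negative correlations qualify by absolute value.
#'
#' @param r_abs,r_slope Correlation vectors against the two weight contrasts.
#' @param r_select Selection threshold (default 0.70).
#' @return Logical vector.
#' @export
select_by_r <- function(r_abs, r_slope, r_select = 0.70) {
  pmax(round(abs(r_abs), 2), round(abs(r_slope), 2)) >= r_select
}

#' Aggregate a taxon count table to a taxonomic rank
#'
#' Sums counts over taxa sharing the same label at the requested rank.
#' Taxa without an assignment at that rank are pooled into `"unclassified"`.
#' Column (sample) totals are conserved exactly at every rank; species-rank
#' aggregation with per-taxon species labels is the identity transform.
#'
#' @param abundance Taxa x samples count matrix (rownames = taxon ids).
#' @param taxonomy Data frame with `taxon_id` and rank columns
#'   (`phylum`, `class`, `order`, `family`, `genus`, `species`).
#' @param rank One of the rank column names.
#' @return Rank-labels x samples matrix.
#' @export
aggregate_rank <- function(abundance, taxonomy, rank) {
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  if (!rank %in% ranks)
    stop("unknown rank '", rank, "'; expected one of ", paste(ranks, collapse = ", "))
  if (!rank %in% colnames(taxonomy)) stop("taxonomy table lacks a '", rank, "' column")
  lab <- taxonomy[[rank]][match(rownames(abundance), taxonomy$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "unclassified"
  rowsum(abundance, group = lab)
}

relative_abundance <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) stop("all-zero sample column(s): ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/")
}

fmt_fecal_samples <- function(metadata) {
  md <- metadata[metadata$tissue == "feces" & metadata$colonization == "FMT", ]
  if (nrow(md) == 0) stop("no FMT fecal samples in metadata")
  md
}

#' Per-diet mean relative abundance at a rank (FMT mice only)
#'
#' @param abundance Taxa x samples count matrix.
#' @param taxonomy Taxonomy map (see [aggregate_rank()]).
#' @param metadata Sample metadata; only FMT fecal samples contribute.
#' @param rank Taxonomic rank to aggregate to.
#' @param diets Diet order; default order of appearance.
#' @return Rank-labels x diets matrix of mean relative abundances.
#' @export
diet_mean_abundance <- function(abundance, taxonomy, metadata, rank = "species",
                                diets = NULL) {
  md <- fmt_fecal_samples(metadata)
  md <- md[md$sample_id %in% colnames(abundance), ]
  if (is.null(diets)) diets <- unique(md$diet)
  agg <- aggregate_rank(abundance[, md$sample_id, drop = FALSE], taxonomy, rank)
  rel <- relative_abundance(agg)
  vapply(diets, function(d)
    rowMeans(rel[, md$sample_id[md$diet == d], drop = FALSE]),
    numeric(nrow(rel)))
}

#' Taxon-gene correlation screen
#'
#' For each taxon at the requested rank, the Pearson correlation across
#' diets between its mean relative abundance in FMT mice and each selected
#' gene's expression shift (delta GEL). Genes with `|r| > r_select` are
#' counted as correlated with the taxon; taxa are ranked by that count.
#'
#' @inheritParams diet_mean_abundance
#' @param gene_delta_gel Genes x diets matrix restricted to the selected
#'   genes (same diet order as the abundance summary).
#' @param r_select Correlation threshold (strict `>`, default 0.8).
#' @return Data frame sorted by `gene_count` descending: `taxon`, `rank`,
#'   `gene_count`, `correlated_genes` (comma-separated), plus attribute
#'   `"r_matrix"` (taxa x genes correlation matrix). Taxa absent from all
#'   samples or with zero variance across diet means are excluded.
#' @export
taxon_gene_screen <- function(abundance, taxonomy, metadata, gene_delta_gel,
                              rank = "species", r_select = 0.8, diets = NULL) {
  if (is.null(dim(gene_delta_gel)) || nrow(gene_delta_gel) == 0)
    stop("gene_delta_gel must be a non-empty genes x diets matrix")
  if (is.null(diets)) diets <- colnames(gene_delta_gel)
  dm <- diet_mean_abundance(abundance, taxonomy, metadata, rank, diets)
  keep <- rowSums(dm) > 0 & apply(dm, 1, stats::var) > 0
  dm <- dm[keep, , drop = FALSE]
  rmat <- matrix(NA_real_, nrow = nrow(dm), ncol = nrow(gene_delta_gel),
                 dimnames = list(rownames(dm), rownames(gene_delta_gel)))
  for (i in seq_len(nrow(dm))) {
    for (g in rownames(gene_delta_gel)) {
      gv <- gene_delta_gel[g, diets]
      if (stats::var(gv) == 0) next
      rmat[i, g] <- pearson_cor(dm[i, ], gv)$r
    }
  }
  hits <- lapply(seq_len(nrow(rmat)), function(i) {
    r <- rmat[i, ]
    colnames(rmat)[!is.na(r) & abs(r) > r_select]
  })
  out <- data.frame(
    taxon = rownames(dm), rank = rank,
    gene_count = vapply(hits, length, integer(1)),
    correlated_genes = vapply(hits, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$gene_count, out$taxon), ]
  rownames(out) <- NULL
  attr(out, "r_matrix") <- rmat
  out
}

#' Taxon abundance vs individual body weight regression
#'
#' Simple linear regression of body weight (g, at the endpoint week) on the
#' relative abundance of each taxon at the requested rank, across individual
#' FMT mice pooled over diets. The coefficient of determination is the
#' squared Pearson correlation.
#'
#' @inheritParams diet_mean_abundance
#' @param growth Growth table (`mouse_id`, `week`, `bw_g`).
#' @param week Week whose body weight is regressed (default 8).
#' @return Data frame: `taxon`, `rank`, `slope`, `intercept`, `r_squared`,
#'   `n`. Constant-abundance taxa are excluded.
#' @export
taxon_bw_regression <- function(abundance, taxonomy, metadata, growth,
                                rank = "species", week = 8) {
  md <- fmt_fecal_samples(metadata)
  md <- md[md$sample_id %in% colnames(abundance), ]
  bw <- growth[growth$week == week, ]
  bw_g <- bw$bw_g[match(md$mouse_id, bw$mouse_id)]
  if (anyNA(bw_g))
    stop("missing week-", week, " body weight for mice: ",
         paste(md$mouse_id[is.na(bw_g)], collapse = ", "))
  if (nrow(md) < 3) stop("need at least 3 FMT mice")
  agg <- aggregate_rank(abundance[, md$sample_id, drop = FALSE], taxonomy, rank)
  rel <- relative_abundance(agg)
  rows <- lapply(rownames(rel), function(tx) {
    a <- rel[tx, ]
    if (stats::var(a) == 0) return(NULL)
    fit <- ols_line(a, bw_g)
    data.frame(taxon = tx, rank = rank, slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$r_squared,
               n = fit$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r_squared), ]
}

#' End-to-end gene linkage pipeline for one tissue
#'
#' Chains the screening stages the way the study design intends: genes must
#' first be differentially expressed between GF and FMT in *every* diet
#' (the cross-diet DEG intersection), and only those diet-common genes enter
#' the cross-diet correlation screen against the body-weight contrasts.
#' The intersection step is what controls false selections: a null gene
#' passes all six DEG cells with probability ~`p_cut^6`, so essentially no
#' unplanted gene reaches the correlation stage.
#'
#' @param expr Genes x samples matrix for one tissue.
#' @param metadata Sample metadata.
#' @param growth Growth table.
#' @param tissue Tissue label (used for DEG cell lookup and reporting).
#' @param diets Diet order; defaults to order of appearance in `metadata`.
#' @param deg_p DEG raw p threshold (default 0.05).
#' @param gene_r Selection threshold on |r| (default 0.70).
#' @param contrasts Optional precomputed [diet_contrasts()] table.
#' @return A list: `contrasts`, `deg_records`, `candidate_genes` (the
#'   cross-diet intersection), `delta_gel` (candidates x diets), and
#'   `linkage` (the [gene_weight_screen()] table with a `tissue` column).
#' @export
run_linkage_pipeline <- function(expr, metadata, growth, tissue,
                                 diets = NULL, deg_p = 0.05, gene_r = 0.70,
                                 contrasts = NULL) {
  if (is.null(diets)) diets <- unique(metadata$diet)
  if (is.null(contrasts)) contrasts <- diet_contrasts(growth, metadata, diets)
  recs <- deg_screen(stats::setNames(list(expr), tissue), metadata,
                     diets = diets, tissues = tissue, p_cut = deg_p)
  common <- intersect_degs(recs, diets = diets, tissues = tissue)$per_tissue[[tissue]]
  dg_all <- compute_delta_gel(expr, metadata, diets)
  if (length(common) == 0 || (length(common) == 1 && is.na(common))) {
    linkage <- data.frame(gene = character(0), r_abs = numeric(0),
                          p_abs = numeric(0), r_slope = numeric(0),
                          p_slope = numeric(0), selected = logical(0),
                          tissue = character(0))
    return(list(contrasts = contrasts, deg_records = recs,
                candidate_genes = common,
                delta_gel = dg_all[character(0), , drop = FALSE],
                linkage = linkage))
  }
  dg <- dg_all[common, , drop = FALSE]
  linkage <- gene_weight_screen(dg, contrasts, r_select = gene_r)
  linkage$tissue <- tissue
  list(contrasts = contrasts, deg_records = recs, candidate_genes = common,
       delta_gel = dg, linkage = linkage)
}
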