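#' Differential-expression call for one tissue x diet cell
#'
#' Screens genes for a GF-vs-FMT expression difference within one tissue and
#' diet. The fold change is `log2((mean FMT + eps) / (mean GF + eps))` on
#' the input (FPKM-like) scale; the p-value is a Welch two-sided t test on
#' `log2(value + eps)`; q is the Benjamini-Hochberg adjustment within the
#' tissue x diet family. A gene passes when `p < p_cut` and `|log2fc| > 0`,
#' i.e. any directional difference with nominal significance — the fold
#' change threshold "greater than 1" on the raw ratio scale. The pass filter
#' uses the raw p (q is reported alongside).
#'
#' @param expr Genes x samples numeric matrix for one tissue.
#' @param metadata Sample metadata (see [make_metadata()]).
#' @param tissue,diet Cell to screen.
#' @param p_cut Raw p-value threshold (default 0.05).
#' @param eps Pseudo-count added before the log (default 1).
#' @return Data frame: `gene`, `tissue`, `diet`, `log2fc`, `p`, `q`,
#'   `passes`. All-zero genes get `log2fc = 0`, `p = NA`, `passes = FALSE`.
#'   Returns `NULL` (with a warning) when either colonization group has
#'   fewer than 2 samples.
#' @export
call_degs <- function(expr, metadata, tissue, diet, p_cut = 0.05, eps = 1) {
  md <- metadata[metadata$tissue == tissue & metadata$diet == diet, ]
  md <- md[md$sample_id %in% colnames(expr), ]
  gf <- md$sample_id[md$colonization == "GF"]
  fmt <- md$sample_id[md$colonization == "FMT"]
  if (length(gf) < 2 || length(fmt) < 2) {
    warning("skipping cell ", tissue, " x ", diet,
            ": fewer than 2 samples in a colonization group")
    return(NULL)
  }
  if (any(expr[, c(gf, fmt)] < 0)) stop("expression values must be non-negative")
  x_gf <- expr[, gf, drop = FALSE]
  x_fmt <- expr[, fmt, drop = FALSE]
  m_gf <- rowMeans(x_gf)
  m_fmt <- rowMeans(x_fmt)
  log2fc <- log2((m_fmt + eps) / (m_gf + eps))
  all_zero <- m_gf == 0 & m_fmt == 0 &
    apply(x_gf, 1, function(r) all(r == 0)) &
    apply(x_fmt, 1, function(r) all(r == 0))
  log2fc[all_zero] <- 0
  lgf <- log2(x_gf + eps)
  lfmt <- log2(x_fmt + eps)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (all_zero[i]) return(NA_real_)
    welch_test(lfmt[i, ], lgf[i, ])$p_two_sided
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_adjust(p[ok])
  passes <- !is.na(p) & p < p_cut & abs(log2fc) > 0
  data.frame(gene = rownames(expr), tissue = tissue, diet = diet,
             log2fc = log2fc, p = p, q = q, passes = passes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DEG screen over all tissue x diet cells
#'
#' @param expression Named list of genes x samples matrices, one per tissue.
#' @inheritParams call_degs
#' @param diets,tissues Cells to screen; default every combination present.
#' @return One stacked data.frame of [call_degs()] records.
#' @export
deg_screen <- function(expression, metadata, diets = NULL, tissues = NULL,
                       p_cut = 0.05, eps = 1) {
  if (is.null(tissues)) tissues <- names(expression)
  if (is.null(diets)) diets <- unique(metadata$diet)
  rec <- list()
  for (tis in tissues) {
    for (d in diets) {
      r <- call_degs(expression[[tis]], metadata, tis, d, p_cut = p_cut, eps = eps)
      if (!is.null(r)) rec[[length(rec) + 1L]] <- r
    }
  }
  do.call(rbind, rec)
}

#' Cross-diet and cross-tissue DEG intersections
#'
#' Reproduces the set logic of a diet-common DEG table: per tissue, the
#' genes passing in every diet ("common across all diet groups"); per diet,
#' the genes passing in every tissue. A missing tissue x diet cell makes
#' the affected intersection undefined (`NA`) rather than silently empty.
#'
#' @param records Stacked DEG records from [deg_screen()].
#' @param diets,tissues Expected cells; default those present in `records`.
#' @return A list with `per_tissue` (named list of gene vectors, or `NA` if
#'   undefined), `per_diet` (same across tissues), and `counts`, a
#'   tissues x (diets + `all_diets`) matrix of per-cell passing counts with
#'   the cross-diet intersection in the last column and the cross-tissue
#'   intersection in the last row.
#' @export
intersect_degs <- function(records, diets = NULL, tissues = NULL) {
  if (is.null(diets)) diets <- unique(records$diet)
  if (is.null(tissues)) tissues <- unique(records$tissue)
  pass_sets <- list()
  for (tis in tissues) {
    for (d in diets) {
      cell <- records[records$tissue == tis & records$diet == d, ]
      pass_sets[[paste(tis, d)]] <- if (nrow(cell) == 0) NA else cell$gene[cell$passes]
    }
  }
  is_undef <- function(s) length(s) == 1 && is.logical(s) && is.na(s)
  inter <- function(sets) {
    if (any(vapply(sets, is_undef, logical(1)))) return(NA)
    Reduce(intersect, sets)
  }
  per_tissue <- lapply(stats::setNames(tissues, tissues), function(tis)
    inter(pass_sets[paste(tis, diets)]))
  per_diet <- lapply(stats::setNames(diets, diets), function(d)
    inter(pass_sets[paste(tissues, d)]))
  counts <- matrix(NA_integer_, nrow = length(tissues) + 1, ncol = length(diets) + 1,
                   dimnames = list(c(tissues, "all_tissues"), c(diets, "all_diets")))
  for (tis in tissues) for (d in diets) {
    s <- pass_sets[[paste(tis, d)]]
    counts[tis, d] <- if (is_undef(s)) NA_integer_ else length(s)
  }
  for (tis in tissues)
    counts[tis, "all_diets"] <- if (is_undef(per_tissue[[tis]]))
      NA_integer_ else length(per_tissue[[tis]])
  for (d in diets)
    counts["all_tissues", d] <- if (is_undef(per_diet[[d]]))
      NA_integer_ else length(per_diet[[d]])
  list(per_tissue = per_tissue, per_diet = per_diet, counts = counts)
}
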