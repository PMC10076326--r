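#' Read a numeric matrix from a tab-delimited file
#'
#' Reads a `rows x columns` numeric table (first column = row ids, header
#' row = column ids), validating that ids are unique and every cell is a
#' finite number. Used for expression (genes x samples) and abundance
#' (taxa x samples) tables.
#'
#' @param path Path to a TSV file with a header row.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus data columns: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn))
    stop("duplicate column id in ", path, ": ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric cells in ", path, ", column(s): ",
         paste(cn[bad], collapse = ", "))
  }
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value in ", path, " at row '", ids[idx[1]],
         "', column '", cn[idx[2]], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a numeric matrix to a tab-delimited file
#'
#' Inverse of [read_matrix_tsv()]: writes the matrix with its row names in a
#' leading id column at full decimal precision, so write-then-read
#' round-trips values exactly.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Header of the id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write plain data-frame tables (metadata, growth, taxonomy, results)
#'
#' @param path Path to a TSV with a header row.
#' @return A data.frame with `check.names = FALSE`.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table_tsv
#' @param df Data frame to write.
#' @export
write_table_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the cohort as the package's on-disk exchange formats: metadata and
#' growth TSVs, one expression TSV per tissue, abundance and taxonomy TSVs,
#' the phylogeny in newick, and the ground truth as a JSON sidecar. All
#' tables are tab-delimited UTF-8 with a header row.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gnoto_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_table_tsv(cohort$growth, file.path(dir, "growth.tsv"))
  for (tis in names(cohort$expression)) {
    write_matrix_tsv(cohort$expression[[tis]],
                     file.path(dir, paste0("expression_", tis, ".tsv")),
                     id_name = "gene")
  }
  write_matrix_tsv(cohort$abundance, file.path(dir, "abundance.tsv"),
                   id_name = "taxon_id")
  write_table_tsv(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(diet_effect = as.list(truth$diet_effect),
         planted_genes = as.list(truth$planted_genes),
         planted_taxa = as.list(truth$planted_taxa),
         planted_family = truth$planted_family,
         bw_slopes = truth$bw_slopes),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A list with `metadata`, `growth`, `expression` (list per tissue),
#'   `abundance`, `taxonomy`, `tree` and (if present) `truth`.
#' @export
read_cohort <- function(dir) {
  expr_files <- list.files(dir, pattern = "^expression_.*\\.tsv$", full.names = TRUE)
  tissues <- sub("^expression_(.*)\\.tsv$", "\\1", basename(expr_files))
  expression <- stats::setNames(lapply(expr_files, read_matrix_tsv), tissues)
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(metadata = read_table_tsv(file.path(dir, "metadata.tsv")),
       growth = read_table_tsv(file.path(dir, "growth.tsv")),
       expression = expression,
       abundance = read_matrix_tsv(file.path(dir, "abundance.tsv")),
       taxonomy = read_table_tsv(file.path(dir, "taxonomy.tsv")),
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       truth = truth)
}

#' Reference gene-weight correlation table
#'
#' The published screening table distributed with the package: 66
#' diet-common differentially expressed genes with their Pearson
#' correlations (and p-values) between the per-diet FMT minus GF expression
#' shift and the two microbiota-attributable body-weight differences
#' (absolute gain and slope), plus the published selection flag. Used to
#' validate the selection rule and the small-sample p-value computation.
#'
#' @return A data.frame with columns `gene`, `tissue`, `r_abs`, `r_slope`
#'   (printed two-decimal correlations), `p_abs`/`p_slope` (printed p-values
#'   as character; bounds like `<0.01` are kept verbatim), numeric helpers
#'   `p_abs_num`/`p_slope_num` (`NA` where only a bound was printed) and
#'   bound flags `p_abs_bound`/`p_slope_bound`, plus `published_selected`.
#'   One gene appears twice, as printed in the source table (66 rows).
#' @export
reference_gene_correlations <- function() {
  path <- system.file("extdata", "gene_bw_correlations.tsv",
                      package = "gnotolink", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric",
                                         "character", "numeric", "character",
                                         "logical"),
                          check.names = FALSE)
  for (col in c("p_abs", "p_slope")) {
    bound <- grepl("^<", df[[col]])
    df[[paste0(col, "_num")]] <- ifelse(bound, NA_real_, suppressWarnings(as.numeric(df[[col]])))
    df[[paste0(col, "_bound")]] <- ifelse(bound, as.numeric(sub("^<", "", df[[col]])), NA_real_)
  }
  df
}
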