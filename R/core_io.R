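#' Construct a CountMatrix
#'
#' The package's central container: a sparse genes x cells matrix of UMI
#' counts with gene identifiers, cell barcodes, and a per-cell sample
#' assignment. Counts must be non-negative integers; identifiers must be
#' unique; every barcode carries exactly one sample label.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts.
#' @param gene_ids character vector of gene identifiers, one per row.
#' @param barcodes character vector of cell barcodes, one per column.
#' @param samples character vector (one per cell) or named vector
#'   (barcode -> sample id) assigning each cell to a sample.
#' @return An object of class `CountMatrix` with elements `counts`
#'   (a `dgCMatrix`), `gene_ids`, `barcodes`, `sample_of_cell`.
#' @export
count_matrix <- function(counts, gene_ids, barcodes, samples) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  vals <- counts@x
  if (any(vals < 0)) stop("CountMatrix: negative counts are not allowed")
  if (any(vals != round(vals))) stop("CountMatrix: counts must be integral")
  if (length(gene_ids) != nrow(counts))
    stop("CountMatrix: length(gene_ids) != nrow(counts)")
  if (length(barcodes) != ncol(counts))
    stop("CountMatrix: length(barcodes) != ncol(counts)")
  if (anyDuplicated(gene_ids)) stop("CountMatrix: duplicate gene ids")
  if (anyDuplicated(barcodes)) stop("CountMatrix: duplicate barcodes")
  if (is.null(names(samples))) {
    if (length(samples) != length(barcodes))
      stop("CountMatrix: one sample assignment per barcode required")
    samples <- stats::setNames(as.character(samples), barcodes)
  } else {
    missing <- setdiff(barcodes, names(samples))
    if (length(missing))
      stop("CountMatrix: no sample assignment for barcodes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    samples <- stats::setNames(as.character(samples[barcodes]), barcodes)
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         barcodes = as.character(barcodes), sample_of_cell = samples),
    class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d samples, %.0f total UMIs\n",
              length(x$gene_ids), length(x$barcodes),
              length(unique(x$sample_of_cell)), sum(x$counts)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param m a `CountMatrix`.
#' @param genes gene ids or row indices (NULL keeps all).
#' @param cells barcodes or column indices (NULL keeps all).
#' @return A `CountMatrix` restricted to the requested rows/columns,
#'   order preserved as given.
#' @export
subset_cells <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else
    if (is.character(genes)) match(genes, m$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(m$barcodes) else
    if (is.character(cells)) match(cells, m$barcodes) else cells
  if (anyNA(gi)) stop("subset_cells: unknown gene id")
  if (anyNA(ci)) stop("subset_cells: unknown barcode")
  count_matrix(m$counts[gi, ci, drop = FALSE], m$gene_ids[gi],
               m$barcodes[ci], m$sample_of_cell[ci])
}

#' Sample metadata table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param age_group character vector, each element `"young"` or `"aged"`.
#' @param n_cells_loaded optional integer vector.
#' @return data.frame with class `SampleMeta`.
#' @export
sample_meta <- function(sample_id, age_group, n_cells_loaded = NA_integer_) {
  if (anyDuplicated(sample_id)) stop("SampleMeta: sample ids must be unique")
  age_group <- match.arg(as.character(age_group), c("young", "aged"),
                         several.ok = TRUE)
  if (length(age_group) != length(sample_id))
    stop("SampleMeta: age_group must match sample_id in length")
  out <- data.frame(sample_id = as.character(sample_id),
                    age_group = age_group,
                    n_cells_loaded = n_cells_loaded,
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleMeta", "data.frame")
  out
}

#' Cell-level QC thresholds
#'
#' Defaults are the atlas' stringent pre-filters: cells are eliminated when
#' UMI counts are < 1,000 or > 60,000, gene counts < 500 or > 2,500, or the
#' mitochondrial UMI fraction exceeds 10%. Because elimination is by strict
#' inequality, cells exactly at a threshold are kept.
#'
#' @param umi_min,umi_max bounds on per-cell total UMIs.
#' @param genes_min,genes_max bounds on per-cell detected genes.
#' @param mito_max maximum mitochondrial UMI fraction in `[0, 1]`.
#' @return list with class `QCThresholds`.
#' @export
qc_thresholds <- function(umi_min = 1000, umi_max = 60000,
                          genes_min = 500, genes_max = 2500,
                          mito_max = 0.10) {
  stopifnot(umi_min <= umi_max, genes_min <= genes_max,
            mito_max >= 0, mito_max <= 1)
  structure(list(umi_min = umi_min, umi_max = umi_max,
                 genes_min = genes_min, genes_max = genes_max,
                 mito_max = mito_max), class = "QCThresholds")
}

#' Differential-expression configuration
#'
#' Thresholds of the three-criteria consensus procedure: a grouped
#' young-vs-aged comparison must show at least a 1.5-fold change with
#' adjusted p < 0.05 in each engine, every young x aged per-sample pair
#' must show at least a 1.25-fold change in the same direction, and only
#' genes detected in at least 10% of cells in either age group enter the
#' analysis.
#'
#' @param fc_grouped_min grouped fold-change threshold (ratio > 1).
#' @param fc_persample_min per-sample fold-change threshold (ratio > 1).
#' @param alpha_adj adjusted p-value cutoff (strict `<`).
#' @param detect_frac_min detection fraction floor (inclusive `>=`).
#' @param fc_pseudocount pseudocount, in normalized-expression units, added
#'   to both group means before taking their ratio.
#' @param scale_factor library-size normalization target (counts per cell).
#' @param min_cells_per_sample minimum cells of the focal type a sample must
#'   contribute for its per-sample mean to be computable.
#' @return list with class `DEConfig`.
#' @export
de_config <- function(fc_grouped_min = 1.5, fc_persample_min = 1.25,
                      alpha_adj = 0.05, detect_frac_min = 0.10,
                      fc_pseudocount = 0.01, scale_factor = 10000,
                      min_cells_per_sample = 3) {
  stopifnot(fc_grouped_min > 1, fc_persample_min > 1,
            alpha_adj > 0, alpha_adj < 1,
            detect_frac_min >= 0, detect_frac_min < 1,
            fc_pseudocount > 0, scale_factor > 0)
  structure(list(fc_grouped_min = fc_grouped_min,
                 fc_persample_min = fc_persample_min,
                 alpha_adj = alpha_adj, detect_frac_min = detect_frac_min,
                 fc_pseudocount = fc_pseudocount, scale_factor = scale_factor,
                 min_cells_per_sample = min_cells_per_sample),
            class = "DEConfig")
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

find_10x_file <- function(dir_path, stems) {
  for (stem in stems) for (ext in c("", ".gz")) {
    f <- file.path(dir_path, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop("read_10x_mtx: missing file ", paste(stems, collapse = " / "),
       " in ", dir_path, call. = FALSE)
}

#' Read a 10x-style MatrixMarket directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or
#' `genes.tsv`), each optionally gzipped. Triplet indices are 1-based on
#' disk and map to 1-based R rows/columns unchanged; the feature table may
#' carry (id, symbol, type) triples and either the symbol column (default,
#' matching how marker genes are reported) or the id column becomes the
#' gene identifier.
#'
#' @param dir_path directory containing the three files.
#' @param sample_id sample label assigned to every cell (default: the
#'   directory's basename).
#' @param gene_column `"symbol"` (column 2 when present) or `"id"`
#'   (column 1).
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(dir_path, sample_id = basename(normalizePath(dir_path)),
                         gene_column = c("symbol", "id")) {
  gene_column <- match.arg(gene_column)
  mtx_f <- find_10x_file(dir_path, "matrix.mtx")
  bc_f <- find_10x_file(dir_path, "barcodes.tsv")
  ft_f <- find_10x_file(dir_path, c("features.tsv", "genes.tsv"))
  m <- Matrix::readMM(mtx_f)
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("read_10x_mtx: matrix has negative or non-integer entries")
  barcodes <- readLines(open_conn <- open_maybe_gz(bc_f)); close(open_conn)
  feats <- utils::read.table(ft_f, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  if (nrow(feats) != nrow(m))
    stop("read_10x_mtx: feature table has ", nrow(feats),
         " rows but matrix header declares ", nrow(m), " genes")
  if (length(barcodes) != ncol(m))
    stop("read_10x_mtx: barcode table has ", length(barcodes),
         " rows but matrix header declares ", ncol(m), " cells")
  gcol <- if (gene_column == "symbol" && ncol(feats) >= 2) 2L else 1L
  gene_ids <- make.unique(as.character(feats[[gcol]]))
  count_matrix(m, gene_ids, barcodes, rep(sample_id, length(barcodes)))
}

#' Write a CountMatrix as a 10x-style MatrixMarket directory
#'
#' Inverse of [read_10x_mtx()]: counts round-trip exactly, indices are
#' written 1-based per the MatrixMarket convention.
#'
#' @param m a `CountMatrix`.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_10x_mtx <- function(m, dir_path) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir_path, "matrix.mtx"))
  writeLines(m$barcodes, file.path(dir_path, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = m$gene_ids, symbol = m$gene_ids, type = "Gene Expression"),
    file.path(dir_path, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Read a dense genes x cells CSV count matrix (toy inputs)
#'
#' First column = gene ids, header row = barcodes.
#'
#' @param path CSV file.
#' @param sample_id sample label for all cells.
#' @return A [count_matrix()].
#' @export
read_counts_csv <- function(path, sample_id = "sample1") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(mat, genes, colnames(mat), rep(sample_id, ncol(mat)))
}

#' Concatenate per-sample CountMatrix objects
#'
#' Genes are taken as the union (in order of first appearance); missing
#' genes in a sample contribute zeros. Per-cell column sums and the total
#' cell count are preserved.
#'
#' @param mats list of `CountMatrix` objects with distinct barcodes.
#' @return A combined [count_matrix()].
#' @export
concat_count_matrices <- function(mats) {
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "CountMatrix")))
  genes <- unique(unlist(lapply(mats, `[[`, "gene_ids")))
  blocks <- lapply(mats, function(m) {
    tr <- Matrix::mat2triplet(m$counts)
    Matrix::sparseMatrix(i = match(m$gene_ids, genes)[tr$i], j = tr$j,
                         x = tr$x,
                         dims = c(length(genes), ncol(m$counts)))
  })
  counts <- do.call(cbind, blocks)
  count_matrix(counts, genes,
               unlist(lapply(mats, `[[`, "barcodes")),
               unlist(lapply(mats, `[[`, "sample_of_cell")))
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes.
#' Duplicate genes within a line are collapsed.
#'
#' @param path GMT file.
#' @param uppercase if TRUE, gene symbols are uppercased on read (useful
#'   after mouse-to-human homolog mapping).
#' @return list with class `GeneSetCollection`: `sets` (named list of
#'   character vectors) and `description` (named character).
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("read_gmt: empty collection in ", path)
    return(structure(list(sets = list(), description = character(0)),
                     class = "GeneSetCollection"))
  }
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("read_gmt: line ", i, " has fewer than 3 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (uppercase) genes <- toupper(genes)
    sets[[fields[1]]] <- genes
    descs[fields[1]] <- fields[2]
  }
  if (anyDuplicated(names(sets))) stop("read_gmt: duplicate set names")
  structure(list(sets = sets, description = descs),
            class = "GeneSetCollection")
}

#' Per-cell library sizes (total UMIs)
#' @param m a `CountMatrix`.
#' @return named numeric vector, one entry per barcode.
#' @export
library_sizes <- function(m) {
  stats::setNames(Matrix::colSums(m$counts), m$barcodes)
}

#' Identify mitochondrial genes by prefix
#' @param gene_ids character vector of gene ids.
#' @param prefix mitochondrial prefix, default the mouse convention `"mt-"`.
#' @return character vector of matching gene ids.
#' @export
mito_genes <- function(gene_ids, prefix = "mt-") {
  gene_ids[startsWith(gene_ids, prefix)]
}
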