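#' Construct a count matrix container
#'
#' Raw counts are stored cells x genes (cells in rows), the orientation in
#' which every per-cell covariate computation in the package operates.
#'
#' @param counts integer matrix or sparse `Matrix`, cells x genes, all
#'   entries non-negative.
#' @param cell_ids,gene_ids unique character identifiers matching the
#'   matrix dimensions; taken from `dimnames(counts)` when omitted.
#' @return An object of class `CountMatrix`: a list with elements
#'   `counts` (a `dgCMatrix`), `cell_ids` and `gene_ids`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  if (is.null(cell_ids) || is.null(gene_ids))
    stop_cider("cider_format_error", "cell and gene identifiers are required")
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (!methods::is(counts, "dMatrix"))
    counts <- methods::as(counts, "dMatrix")
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids))
    stop_cider("cider_format_error",
               "identifier counts do not match matrix dimensions (",
               nrow(counts), "x", ncol(counts), " vs ",
               length(cell_ids), " cells / ", length(gene_ids), " genes)")
  if (anyDuplicated(cell_ids))
    stop_cider("cider_format_error", "duplicate cell identifiers")
  if (anyDuplicated(gene_ids))
    stop_cider("cider_format_error", "duplicate gene identifiers")
  if (any(counts@x < 0))
    stop_cider("cider_format_error", "negative counts")
  if (any(counts@x != round(counts@x)))
    stop_cider("cider_format_error", "non-integer counts")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      format(Matrix::nnzero(x$counts), big.mark = ","), "nonzero entries\n")
  invisible(x)
}

#' Read a count matrix from Matrix Market or dense delimited text
#'
#' @param matrix_path path to a Matrix Market coordinate file (`.mtx`) or,
#'   when `genes_path` is `NULL`, a dense delimited file with a header row
#'   of gene ids and a first column of cell ids.
#' @param genes_path,cells_path one-column text files with gene / cell
#'   identifiers (MTX input only).
#' @param orientation `"genes_x_cells"` (the 10x sidecar convention; the
#'   matrix is transposed on read) or `"cells_x_genes"`.
#' @return A [count_matrix()] in cells x genes orientation.
#' @export
read_counts <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                        orientation = c("genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path))
    stop_cider("cider_format_error", "matrix file not found: ", matrix_path)
  if (is.null(genes_path)) {
    tab <- suppressWarnings(data.table::fread(matrix_path, header = TRUE))
    if (nrow(tab) == 0L || ncol(tab) < 2L)
      stop_cider("cider_format_error", "empty dense matrix file: ", matrix_path)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m))
      stop_cider("cider_format_error", "non-numeric entries in ", matrix_path)
    dimnames(m) <- list(ids, colnames(tab)[-1L])
    if (orientation == "genes_x_cells") m <- t(m)
    return(count_matrix(m))
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e)
    stop_cider("cider_format_error", "cannot parse ", matrix_path, ": ",
               conditionMessage(e)))
  if (length(m) == 0L && nrow(m) == 0L)
    stop_cider("cider_format_error", "empty matrix file: ", matrix_path)
  genes <- read_id_column(genes_path)
  cells <- read_id_column(cells_path)
  if (orientation == "genes_x_cells") {
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop_cider("cider_format_error",
                 "matrix is ", nrow(m), "x", ncol(m), " but ", genes_path,
                 " has ", length(genes), " genes and ", cells_path, " has ",
                 length(cells), " cells")
    m <- Matrix::t(m)
  } else if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop_cider("cider_format_error",
               "matrix is ", nrow(m), "x", ncol(m), " but ", cells_path,
               " has ", length(cells), " cells and ", genes_path, " has ",
               length(genes), " genes")
  }
  count_matrix(m, cell_ids = cells, gene_ids = genes)
}

read_id_column <- function(path) {
  if (!file.exists(path))
    stop_cider("cider_format_error", "identifier file not found: ", path)
  ids <- data.table::fread(path, header = FALSE)[[1L]]
  if (length(ids) == 0L)
    stop_cider("cider_format_error", "empty identifier file: ", path)
  as.character(ids)
}

#' Write a count matrix as Matrix Market plus identifier sidecars
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if needed); files `matrix.mtx`,
#'   `genes.tsv`, `cells.tsv` are written in genes x cells orientation.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Validate a cell-metadata table against a count matrix
#'
#' @param meta data.frame with one row per cell in `cm` order; must contain
#'   a `batch` column; may contain `annotation` and extra covariates.
#' @param cm a [count_matrix()].
#' @return `meta` with `batch` (and `annotation`, if present) as character.
#' @export
validate_meta <- function(meta, cm) {
  stopifnot(is.data.frame(meta))
  if (nrow(meta) != length(cm$cell_ids))
    stop_cider("cider_format_error", "metadata has ", nrow(meta),
               " rows but the matrix has ", length(cm$cell_ids), " cells")
  if (!"batch" %in% colnames(meta))
    stop_cider("cider_format_error", "metadata lacks a 'batch' column")
  meta$batch <- as.character(meta$batch)
  if (anyNA(meta$batch))
    stop_cider("cider_format_error", "missing batch labels")
  if ("annotation" %in% colnames(meta))
    meta$annotation <- as.character(meta$annotation)
  meta
}

#' Filter cells by number of detected genes
#'
#' @param cm a [count_matrix()].
#' @param meta optional metadata data.frame subset in lockstep.
#' @param min_genes keep cells with at least this many nonzero genes.
#' @return A list with elements `cm` and `meta`.
#' @export
filter_cells <- function(cm, meta = NULL, min_genes = 500) {
  stopifnot(inherits(cm, "CountMatrix"), min_genes >= 0)
  detected <- detected_genes(cm$counts)
  keep <- detected >= min_genes
  if (!any(keep))
    stop_cider("cider_filter_error",
               "no cells have >= ", min_genes, " detected genes")
  out <- count_matrix(cm$counts[keep, , drop = FALSE])
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  list(cm = out, meta = meta)
}

# per-cell number of nonzero genes, sparse-aware
detected_genes <- function(counts) {
  as.integer(Matrix::rowSums(counts != 0))
}

#' Library-size log-normalization
#'
#' `value[i, j] = log2(1 + scale * counts[i, j] / libsize_i)`; zeros stay
#' zero, so the sparsity pattern is preserved.
#'
#' @param cm a [count_matrix()].
#' @param scale scale factor (default 1e4).
#' @return An `ExpressionMatrix`: list with `values` (sparse, cells x
#'   genes), ids, and normalization metadata.
#' @export
lognormalize <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  libsize <- Matrix::rowSums(cm$counts)
  if (any(libsize == 0))
    stop_cider("cider_filter_error",
               "all-zero cells present; run filter_cells() first")
  v <- cm$counts
  # operate on the nonzero slots only: j-th slot belongs to row i = v@i + 1
  rows <- v@i + 1L
  v@x <- log2(1 + scale * v@x / libsize[rows])
  structure(list(values = v, cell_ids = cm$cell_ids, gene_ids = cm$gene_ids,
                 scale_factor = scale, pseudocount = 1),
            class = "ExpressionMatrix")
}

#' Construct an expression matrix directly
#'
#' For workflows whose normalized expression comes from elsewhere; most
#' users should use [lognormalize()].
#'
#' @param values numeric cells x genes matrix with dimnames.
#' @param scale_factor,pseudocount normalization metadata.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale_factor = NA_real_,
                              pseudocount = NA_real_) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_cider("cider_format_error", "values need cell and gene dimnames")
  if (!methods::is(values, "Matrix"))
    values <- Matrix::Matrix(values, sparse = TRUE)
  values <- methods::as(methods::as(values, "CsparseMatrix"),
                        "generalMatrix")
  if (any(!is.finite(values@x)))
    stop_cider("cider_format_error", "non-finite expression values")
  structure(list(values = values, cell_ids = rownames(values),
                 gene_ids = colnames(values), scale_factor = scale_factor,
                 pseudocount = pseudocount),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes; log2(1 + ", format(x$scale_factor), " * count / libsize)\n")
  invisible(x)
}

#' Cellular detection rate
#'
#' The number of genes detected per cell (raw) and its z-score over a set
#' of cells (scaled), used as a regression covariate so that differences
#' in per-cell complexity do not masquerade as group effects.
#'
#' @param cm a [count_matrix()] or `ExpressionMatrix`.
#' @param within integer or logical index of the cells over which the
#'   z-score is computed (defaults to all cells).
#' @return A list of class `CDRVector` with `raw` and `scaled` vectors
#'   over the `within` cells.
#' @export
compute_cdr <- function(cm, within = NULL) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm$values
  if (is.null(within)) within <- seq_len(nrow(m))
  if (length(within) == 0L)
    stop_cider("cider_input_error", "empty cell set for CDR")
  raw <- detected_genes(m[within, , drop = FALSE])
  s <- sd(raw)
  scaled <- if (length(raw) < 2L || s == 0) rep(0, length(raw))
            else (raw - mean(raw)) / s
  structure(list(raw = raw, scaled = scaled,
                 cells = rownames(m)[within] %||% within),
            class = "CDRVector")
}

#' Select highly variable genes
#'
#' Genes are ranked by standardized dispersion: the variance of the
#' log-normalized expression is z-scored within 20 equal-occupancy bins of
#' mean expression, which removes the mean-variance trend before ranking.
#' Ties break by gene id so the result is deterministic.
#'
#' @param em an `ExpressionMatrix`.
#' @param n number of genes to return (default 2000).
#' @param n_bins number of mean-expression bins.
#' @return Character vector of gene ids, highest dispersion first.
#' @export
select_hvgs <- function(em, n = 2000, n_bins = 20) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  G <- ncol(em$values)
  if (n > G) {
    warn_cider("cider_input_warning", "n = ", n, " exceeds ", G,
               " genes; returning all genes")
    n <- G
  }
  mu <- Matrix::colMeans(em$values)
  # E[x^2] - mu^2, with the n/(n-1) correction
  ex2 <- Matrix::colMeans(em$values^2)
  nc <- nrow(em$values)
  v <- (ex2 - mu^2) * nc / max(1, nc - 1)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, G), labels = FALSE)
  z <- numeric(G)
  for (b in unique(bins)) {
    idx <- which(bins == b)
    sb <- sd(v[idx])
    z[idx] <- if (length(idx) < 2L || sb == 0) 0 else (v[idx] - mean(v[idx])) / sb
  }
  ord <- order(-z, em$gene_ids)
  em$gene_ids[ord][seq_len(n)]
}

#' Principal component embedding of log-normalized expression
#'
#' Centered (not scaled) PCA on a gene subset. The sign of each component
#' is fixed so that its largest-magnitude gene loading is positive, making
#' repeated runs byte-comparable.
#'
#' @param em an `ExpressionMatrix`.
#' @param genes gene ids to use (default: all).
#' @param n_pcs number of components (default 10).
#' @return cells x `n_pcs` matrix of scores with a `"rotation"` attribute.
#' @export
compute_pca <- function(em, genes = NULL, n_pcs = 10) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  genes <- genes %||% em$gene_ids
  if (!all(genes %in% em$gene_ids))
    stop_cider("cider_input_error", "unknown gene ids in PCA gene set")
  x <- as.matrix(em$values[, genes, drop = FALSE])
  if (n_pcs > min(dim(x)))
    stop_cider("cider_input_error", "n_pcs = ", n_pcs,
               " exceeds min(cells, genes) = ", min(dim(x)))
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = n_pcs, nv = n_pcs)
  rot <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  for (j in seq_len(n_pcs)) {  # sign convention
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(em$cell_ids, paste0("PC", seq_len(n_pcs)))
  dimnames(rot) <- list(genes, colnames(scores))
  attr(scores, "rotation") <- rot
  attr(scores, "sdev") <- sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(x) - 1))
  scores
}
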