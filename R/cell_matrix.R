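#' Cells-by-genes expression container
#'
#' Bundles a nonnegative integer count matrix (rows = cells, columns = genes)
#' with per-cell metadata and, after [normalize_depth()], a depth-normalized
#' log1p expression layer. Mitochondrial content is read from genes whose name
#' starts with \code{"MT-"}.
#'
#' @param counts cells x genes matrix (base matrix or \code{Matrix::dgCMatrix})
#'   of nonnegative integers; rownames are cell barcodes, colnames gene names.
#' @param cell_meta data.frame with one row per cell. A \code{barcode} column
#'   is added from rownames when missing; \code{n_genes}, \code{n_umi} and
#'   \code{mito_fraction} are (re)computed from \code{counts};
#'   \code{doublet_flag} defaults to \code{FALSE}.
#' @return An object of class \code{CellMatrix}: a list with elements
#'   \code{counts}, \code{normalized} (NULL until normalized), \code{cell_meta}.
#' @export
CellMatrix <- function(counts, cell_meta = NULL) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%05d", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("gene names must be unique")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = rownames(counts),
                            stringsAsFactors = FALSE)
  }
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta rows must match count matrix rows")
  if (is.null(cell_meta$barcode)) cell_meta$barcode <- rownames(counts)
  if (is.null(cell_meta$doublet_flag)) cell_meta$doublet_flag <- FALSE
  cell_meta$n_umi <- Matrix::rowSums(counts)
  cell_meta$n_genes <- Matrix::rowSums(counts > 0)
  mt <- startsWith(colnames(counts), "MT-")
  cell_meta$mito_fraction <- if (any(mt)) {
    as.numeric(Matrix::rowSums(counts[, mt, drop = FALSE]) /
                 pmax(cell_meta$n_umi, 1))
  } else 0
  rownames(cell_meta) <- rownames(counts)
  structure(list(counts = counts, normalized = NULL, cell_meta = cell_meta),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "counts only" else "normalized"))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Gene names of a CellMatrix
#' @param m a \code{CellMatrix}
#' @return character vector of gene names
#' @export
gene_names <- function(m) colnames(m$counts)

#' Cell barcodes of a CellMatrix
#' @param m a \code{CellMatrix}
#' @return character vector of barcodes
#' @export
cell_barcodes <- function(m) rownames(m$counts)

#' Subset a CellMatrix by cells and/or genes
#'
#' @param m a \code{CellMatrix}
#' @param cells logical/integer/character index of cells to keep
#' @param genes logical/integer/character index of genes to keep
#' @param recompute_meta recompute n_genes/n_umi/mito_fraction over the kept
#'   genes (default TRUE)
#' @return a \code{CellMatrix}
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL, recompute_meta = TRUE) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(cells)) cells <- seq_len(nrow(m$counts))
  if (is.null(genes)) genes <- seq_len(ncol(m$counts))
  counts <- m$counts[cells, genes, drop = FALSE]
  meta <- m$cell_meta[cells, , drop = FALSE]
  out <- if (recompute_meta) CellMatrix(counts, meta) else {
    rownames(meta) <- rownames(counts)
    structure(list(counts = counts, normalized = NULL, cell_meta = meta),
              class = "CellMatrix")
  }
  if (!is.null(m$normalized))
    out$normalized <- m$normalized[cells, genes, drop = FALSE]
  out
}

#' Concatenate CellMatrix objects over the gene intersection
#'
#' @param ... two or more \code{CellMatrix} objects
#' @return a \code{CellMatrix} over the common genes, metadata row-bound
#'   (shared columns only)
#' @export
bind_cells <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 2L, all(vapply(ms, inherits, TRUE, "CellMatrix")))
  genes <- Reduce(intersect, lapply(ms, gene_names))
  if (length(genes) == 0L) stop("empty gene intersection between matrices")
  counts <- do.call(rbind, lapply(ms, function(m) m$counts[, genes, drop = FALSE]))
  cols <- Reduce(intersect, lapply(ms, function(m) names(m$cell_meta)))
  meta <- do.call(rbind, lapply(ms, function(m) m$cell_meta[, cols, drop = FALSE]))
  if (anyDuplicated(meta$barcode)) {
    meta$barcode <- make.unique(meta$barcode)
    rownames(counts) <- meta$barcode
  }
  CellMatrix(counts, meta)
}

#' Write a CellMatrix as MatrixMarket + gene/barcode/metadata TSVs
#'
#' Emits \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv} (10x triplet
#' layout, genes x cells) and \code{metadata.tsv} into \code{dir}.
#'
#' @param m a \code{CellMatrix}
#' @param dir output directory (created if absent)
#' @export
write_cellmatrix <- function(m, dir) {
  stopifnot(inherits(m, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  writeLines(gene_names(m), file.path(dir, "genes.tsv"))
  writeLines(cell_barcodes(m), file.path(dir, "barcodes.tsv"))
  utils::write.table(m$cell_meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a CellMatrix written by [write_cellmatrix()]
#' @param dir directory holding matrix.mtx / genes.tsv / barcodes.tsv and
#'   optionally metadata.tsv
#' @return a \code{CellMatrix}
#' @export
read_cellmatrix <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "genes.tsv"))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL
  CellMatrix(counts, meta)
}

#' Read a GMT gene-set file
#' @param path GMT file path
#' @return named list of character vectors (set name -> member genes)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)][nzchar(f[-(1:2)])])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
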