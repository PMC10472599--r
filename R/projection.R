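#' Build the cell-type reference for cosine projection
#'
#' For each type a one-vs-rest [wilcoxon_de()] contrast selects up to
#' \code{top_n} positive markers by average fold change among significant
#' genes; the reference centroid of a type is its per-gene mean normalized
#' expression over the union of all marker genes.
#'
#' @param healthy a normalized \code{CellMatrix}
#' @param types per-cell type labels
#' @param top_n markers per type (default 100)
#' @param q_max BH-adjusted significance cutoff for marker candidacy
#' @param lfc_min minimum log fold change for marker candidacy
#' @param similarity_threshold minimum cosine similarity for assignment
#' @return list of class \code{CellTypeReference}: \code{markers} (named
#'   list), \code{centroids} (genes x types matrix over the marker union),
#'   \code{similarity_threshold}
#' @export
build_reference <- function(healthy, types, top_n = 100, q_max = 0.01,
                            lfc_min = 0.25, similarity_threshold = 0.7) {
  stopifnot(inherits(healthy, "CellMatrix"))
  if (is.null(healthy$normalized)) stop("normalized layer required")
  if (length(types) != nrow(healthy$counts))
    stop("types must label every cell")
  tt <- table(types)
  usable <- names(tt)[tt >= 3]
  if (length(usable) < 2) stop("need at least 2 types with >= 3 cells")
  if (length(usable) < length(tt))
    warning("excluding type(s) with < 3 cells: ",
            paste(setdiff(names(tt), usable), collapse = ", "))
  markers <- list()
  for (t in usable) {
    de <- wilcoxon_de(healthy, which(types == t), which(types != t),
                      min_pct = 0.1, lfc_min = lfc_min)
    de <- de[de$q < q_max & de$lfc > 0, , drop = FALSE]
    de <- de[order(-de$lfc, de$gene), , drop = FALSE]
    markers[[t]] <- utils::head(de$gene, top_n)
  }
  union_genes <- sort(unique(unlist(markers)))
  if (!length(union_genes)) stop("no marker genes found")
  centroids <- sapply(usable, function(t)
    Matrix::colMeans(healthy$normalized[types == t, union_genes,
                                        drop = FALSE]))
  rownames(centroids) <- union_genes
  structure(list(markers = markers, centroids = centroids,
                 similarity_threshold = similarity_threshold),
            class = "CellTypeReference")
}

#' Project cells to their nearest reference centroid by cosine similarity
#'
#' Each cell, restricted to the reference marker-gene union (missing genes
#' imputed as 0), is assigned the type with the largest cosine similarity;
#' ties break by type-name order. Cells whose best similarity falls below
#' the reference threshold (or that are all-zero on the union) are flagged
#' unassigned.
#'
#' @param cells a normalized \code{CellMatrix}
#' @param ref a [build_reference()] object
#' @return data.frame per cell: \code{barcode}, \code{assigned_type},
#'   \code{similarity}, \code{unassigned}
#' @export
project_cells <- function(cells, ref) {
  stopifnot(inherits(cells, "CellMatrix"), inherits(ref, "CellTypeReference"))
  if (is.null(cells$normalized)) stop("normalized layer required")
  union_genes <- rownames(ref$centroids)
  present <- intersect(union_genes, gene_names(cells))
  if (!length(present)) stop("no reference genes present in cells")
  x <- matrix(0, nrow(cells$counts), length(union_genes),
              dimnames = list(cell_barcodes(cells), union_genes))
  x[, present] <- as.matrix(cells$normalized[, present, drop = FALSE])
  cn <- ref$centroids
  cnorm <- sqrt(colSums(cn^2)); cnorm[cnorm == 0] <- 1
  xnorm <- sqrt(rowSums(x^2))
  sim <- (x %*% cn) / outer(pmax(xnorm, .Machine$double.eps), cnorm)
  type_order <- order(colnames(sim))
  best <- apply(sim[, type_order, drop = FALSE], 1, which.max)
  assigned <- colnames(sim)[type_order][best]
  best_sim <- sim[cbind(seq_len(nrow(sim)), type_order[best])]
  unassigned <- xnorm == 0 | best_sim < ref$similarity_threshold
  data.frame(barcode = cell_barcodes(cells),
             assigned_type = ifelse(unassigned, "unassigned", assigned),
             similarity = ifelse(xnorm == 0, 0, best_sim),
             unassigned = unassigned,
             stringsAsFactors = FALSE)
}

#' Final per-cell labels: "-like" suffix for leukemic cells
#'
#' @param projection a [project_cells()] result
#' @param call a \code{MalignancyCall} covering the same cells (same order)
#' @return character vector of final labels
#' @export
label_malignant_types <- function(projection, call) {
  stopifnot(inherits(call, "MalignancyCall"))
  if (nrow(projection) != length(call$cell_call))
    stop("projection and malignancy call cover different cell sets")
  ifelse(call$cell_call == "leukemic",
         paste0(projection$assigned_type, "-like"),
         projection$assigned_type)
}
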