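#' Quality-control thresholds
#'
#' Defaults mirror common droplet scRNA-seq practice: drop cells with fewer
#' than 200 expressed genes or 500 UMIs, mitochondrial fraction above 15%,
#' or flagged as doublets; then drop genes seen in fewer than 10 cells.
#'
#' @param min_genes minimum expressed genes per cell
#' @param min_umi minimum UMI count per cell
#' @param max_mito maximum mitochondrial read fraction
#' @param min_cells_per_gene minimum number of expressing cells per gene
#' @param drop_doublets drop cells with \code{doublet_flag}
#' @return list of class \code{QCThresholds}
#' @export
qc_thresholds <- function(min_genes = 200, min_umi = 500, max_mito = 0.15,
                          min_cells_per_gene = 10, drop_doublets = TRUE) {
  stopifnot(min_genes >= 0, min_umi >= 0, max_mito >= 0,
            min_cells_per_gene >= 0)
  structure(list(min_genes = min_genes, min_umi = min_umi,
                 max_mito = max_mito,
                 min_cells_per_gene = min_cells_per_gene,
                 drop_doublets = drop_doublets),
            class = "QCThresholds")
}

#' Filter low-quality cells and rarely expressed genes
#'
#' Cells failing any threshold are removed first, then genes expressed in
#' fewer than \code{min_cells_per_gene} surviving cells. Because removing
#' genes lowers per-cell gene/UMI counts, the two steps are iterated to a
#' fixed point so the result is idempotent. Cell and gene order is preserved.
#'
#' @param m a \code{CellMatrix} with counts
#' @param thresholds a [qc_thresholds()] object
#' @return filtered \code{CellMatrix}
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "CellMatrix"), inherits(thresholds, "QCThresholds"))
  t <- thresholds
  repeat {
    meta <- m$cell_meta
    keep_cells <- meta$n_genes >= t$min_genes &
      meta$n_umi >= t$min_umi &
      meta$mito_fraction <= t$max_mito
    if (t$drop_doublets) keep_cells <- keep_cells & !meta$doublet_flag
    if (!any(keep_cells)) stop("all cells filtered by QC thresholds")
    sub <- subset_cells(m, cells = which(keep_cells))
    keep_genes <- Matrix::colSums(sub$counts > 0) >= t$min_cells_per_gene
    if (!any(keep_genes)) stop("all genes filtered by QC thresholds")
    sub <- subset_cells(sub, genes = which(keep_genes))
    if (all(keep_cells) && all(keep_genes)) return(sub)
    m <- sub
  }
}

#' Depth-normalize counts to 10,000 and log-transform
#'
#' \code{normalized[c, g] = log(1 + counts[c, g] / total_c * scale)}, so
#' for every cell \code{sum(expm1(normalized)) == scale}.
#'
#' @param m a \code{CellMatrix}
#' @param scale target depth (default 10000)
#' @return the \code{CellMatrix} with the \code{normalized} layer filled
#' @export
normalize_depth <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "CellMatrix"))
  totals <- Matrix::rowSums(m$counts)
  if (any(totals <= 0))
    stop("cells with zero total counts present; run qc_filter first")
  norm <- Matrix::Diagonal(x = scale / totals) %*% m$counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$normalized <- norm
  m
}

#' Select highly variable genes by variance-stabilized dispersion
#'
#' Fits a loess trend of log10(variance) on log10(mean) over the raw counts,
#' standardizes each gene by its expected standard deviation (values clipped
#' at sqrt(n_cells)), and ranks genes by the variance of the standardized
#' values. Ties are broken by gene-name order so the selection is
#' deterministic.
#'
#' @param m a normalized \code{CellMatrix}
#' @param n number of genes to return (default 3000)
#' @param loess_span span of the mean-variance trend fit
#' @return character vector of gene names, ranked
#' @export
select_variable_genes <- function(m, n = 3000, loess_span = 0.3) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required; run normalize_depth")
  x <- m$counts
  nc <- nrow(x)
  mu <- Matrix::colMeans(x)
  v <- Matrix::colMeans(x^2) - mu^2
  v <- v * nc / pmax(nc - 1, 1)
  gn <- colnames(x)
  std_var <- numeric(length(mu))
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 10) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = loess_span, degree = 2)
    exp_sd <- sqrt(10^stats::predict(fit, log10(mu[usable])))
    xs <- as.matrix(x[, usable, drop = FALSE])
    z <- sweep(sweep(xs, 2, mu[usable], "-"), 2, exp_sd, "/")
    z <- pmin(z, sqrt(nc))
    std_var[usable] <- apply(z, 2, stats::var)
  } else {
    std_var[usable] <- v[usable] / mu[usable]   # tiny-input fallback
  }
  if (n > length(gn)) {
    warning("n exceeds gene count; returning all genes")
    n <- length(gn)
  }
  ord <- order(-std_var, gn)
  gn[ord][seq_len(n)]
}

#' Per-gene z-score scaling, capped
#'
#' @param m a normalized \code{CellMatrix}
#' @param genes genes to scale (default: all)
#' @param cap clip scaled values at this magnitude (default 10)
#' @return dense cells x genes matrix of scaled values
#' @export
scale_genes <- function(m, genes = gene_names(m), cap = 10) {
  stopifnot(inherits(m, "CellMatrix"), !is.null(m$normalized))
  x <- as.matrix(m$normalized[, genes, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  pmin(pmax(z, -cap), cap)
}

#' Principal components of the scaled expression matrix
#'
#' Eigen-decomposition of the gene-gene covariance of the scaled data;
#' returns the cell embedding and the percentage of variance per component.
#'
#' @param m a normalized \code{CellMatrix}
#' @param genes genes to use (typically [select_variable_genes()] output)
#' @param n_pcs number of components to keep
#' @return list with \code{embedding} (cells x n_pcs) and
#'   \code{explained_pct} (length n_pcs, percentages of total variance)
#' @export
run_pca <- function(m, genes = gene_names(m), n_pcs = 30) {
  z <- scale_genes(m, genes)
  n_pcs <- min(n_pcs, ncol(z), nrow(z) - 1L)
  cv <- crossprod(z) / (nrow(z) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  tot <- sum(diag(cv))
  emb <- z %*% eig$vectors[, seq_len(n_pcs), drop = FALSE]
  colnames(emb) <- sprintf("PC%d", seq_len(n_pcs))
  list(embedding = emb,
       explained_pct = 100 * eig$values[seq_len(n_pcs)] / tot)
}

#' Choose the number of principal components
#'
#' Combines two cutoffs on the ordered per-component variance percentages:
#' \code{co1}, the first component at which the cumulative percentage exceeds
#' 90 while the component's own share is below 5; and \code{co2}, the last
#' component whose drop to the next component exceeds 0.1 percentage points.
#' The result is \code{min(co1, co2)}; if one rule never fires the other is
#' used, and at least one component is always returned.
#'
#' @param explained_pct nonnegative, non-increasing percentages
#' @param cum_cut cumulative-percentage cutoff (default 90)
#' @param own_cut own-share cutoff (default 5)
#' @param drop_cut successive-difference cutoff (default 0.1)
#' @return integer count of components
#' @export
select_pcs <- function(explained_pct, cum_cut = 90, own_cut = 5,
                       drop_cut = 0.1) {
  p <- explained_pct
  if (length(p) == 0) stop("empty explained-variance vector")
  if (any(p < 0) || is.unsorted(rev(p) , strictly = FALSE) && any(diff(p) > 1e-8))
    stop("percentages must be nonnegative and non-increasing")
  cum <- cumsum(p)
  co1_hits <- which(cum > cum_cut & p < own_cut)
  co1 <- if (length(co1_hits)) co1_hits[1] else NA_integer_
  drops <- which(diff(p) < -drop_cut)
  co2 <- if (length(drops)) max(drops) else NA_integer_
  res <- if (is.na(co1) && is.na(co2)) length(p)
  else min(co1, co2, na.rm = TRUE)
  max(1L, as.integer(res))
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph under cosine distance on the embedding,
#' reweights edges by the Jaccard similarity of neighbor sets (SNN), prunes
#' weak edges, and partitions with Leiden modularity optimization. The
#' result is deterministic for a fixed \code{seed}.
#'
#' @param embedding cells x k numeric matrix
#' @param k_neighbors neighbors per cell (default 20)
#' @param resolution modularity resolution (default 0.8)
#' @param prune SNN Jaccard pruning threshold (default 1/15)
#' @param seed RNG seed for the community search
#' @return integer vector of cluster labels \code{0..K-1}
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 0.8,
                          prune = 1 / 15, seed = 0L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k_neighbors >= n) stop("fewer cells than requested neighbors")
  nrm <- sqrt(rowSums(embedding^2))
  nrm[nrm == 0] <- 1
  unit <- embedding / nrm
  sim <- tcrossprod(unit)
  diag(sim) <- -Inf
  # neighbor sets include the cell itself (standard SNN convention)
  nb <- matrix(0L, n, k_neighbors + 1L)
  for (i in seq_len(n)) {
    nb[i, ] <- c(i, order(sim[i, ], decreasing = TRUE)[seq_len(k_neighbors)])
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors + 1L),
                              j = as.integer(t(nb)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  s <- shared@x[keep]
  jac <- s / (2 * (k_neighbors + 1L) - s)
  ok <- jac >= prune
  if (!any(ok)) return(rep(0L, n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = jac[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 5)
  memb <- igraph::membership(comm)
  memb <- memb[as.character(seq_len(n))]
  as.integer(memb) - 1L
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' The standard droplet scRNA-seq DE primitive: genes are pre-filtered on the
#' fraction of expressing cells and on the natural-log fold change of group
#' means (computed on \code{expm1} of the normalized layer with pseudocount
#' 1), then tested with the rank-sum statistic (exact null when group sizes
#' are small and values untied, tie-corrected normal approximation
#' otherwise) and BH-adjusted over the tested genes.
#'
#' @param m a normalized \code{CellMatrix}
#' @param group_a,group_b disjoint index vectors of cells (integer positions
#'   or barcode names)
#' @param min_pct minimum of max(pct.1, pct.2) for a gene to be tested
#' @param lfc_min minimum absolute log fold change for a gene to be tested
#' @return data.frame (one row per tested gene): \code{gene}, \code{lfc},
#'   \code{pct.1}, \code{pct.2}, \code{p}, \code{q}
#' @export
wilcoxon_de <- function(m, group_a, group_b, min_pct = 0.1, lfc_min = 0.25) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  if (is.character(group_a)) group_a <- match(group_a, cell_barcodes(m))
  if (is.character(group_b)) group_b <- match(group_b, cell_barcodes(m))
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 cells")
  xa <- m$normalized[group_a, , drop = FALSE]
  xb <- m$normalized[group_b, , drop = FALSE]
  mean_a <- Matrix::colMeans(expm1(as.matrix(xa)))
  mean_b <- Matrix::colMeans(expm1(as.matrix(xb)))
  lfc <- log((mean_a + 1) / (mean_b + 1))
  pct1 <- Matrix::colSums(xa > 0) / nrow(xa)
  pct2 <- Matrix::colSums(xb > 0) / nrow(xb)
  test <- pmax(pct1, pct2) >= min_pct & abs(lfc) >= lfc_min
  idx <- which(test)
  p <- rep(NA_real_, length(idx))
  na <- length(group_a); nb <- length(group_b)
  xa_d <- as.matrix(xa[, idx, drop = FALSE])
  xb_d <- as.matrix(xb[, idx, drop = FALSE])
  for (k in seq_along(idx)) {
    p[k] <- rank_sum_p(xa_d[, k], xb_d[, k])
  }
  out <- data.frame(gene = colnames(m$normalized)[idx],
                    lfc = lfc[idx], pct.1 = pct1[idx], pct.2 = pct2[idx],
                    p = p, stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, "BH")
  out[order(out$p, -abs(out$lfc), out$gene), , drop = FALSE]
}

# Two-sided Wilcoxon rank-sum p-value. Exact (pwilcox) when both groups are
# small and there are no ties; otherwise tie-corrected normal approximation.
rank_sum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U for group a
  if (!ties && na < 50 && nb < 50) {
    p <- if (w > na * nb / 2) {
      stats::pwilcox(w - 1, na, nb, lower.tail = FALSE) * 2
    } else {
      stats::pwilcox(w, na, nb) * 2
    }
    return(min(1, p))
  }
  n <- na + nb
  tie_tab <- table(r)
  sigma2 <- (na * nb / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - na * nb / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
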