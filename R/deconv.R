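#' Build the leukemic signature matrix
#'
#' Per-type one-vs-rest [wilcoxon_de()] selects up to \code{top_n}
#' up-regulated genes passing the stated thresholds (pct.1 > 0.3, p < 0.01,
#' FDR < 0.01, logFC > 0.2); a specificity filter then removes genes
#' "highly expressed" (mean >= \code{high_frac} of the maximum type mean) in
#' more than two types. The matrix holds each surviving gene's per-type mean
#' normalized expression and cross-cell SD.
#'
#' @param m a normalized \code{CellMatrix}
#' @param type_labels per-cell identity labels (>= 2 types, >= 20 cells each)
#' @param top_n candidate genes per type (default 300)
#' @param min_pct,p_max,q_max,lfc_min DE thresholds
#' @param high_frac "highly expressed" fraction of the max type mean
#'   (default 0.5)
#' @param max_high_types genes high in more than this many types are dropped
#'   (default 2)
#' @return list of class \code{SignatureMatrix}: \code{means} (genes x
#'   types), \code{sds}, \code{signature_genes}, \code{gene_type} (named:
#'   the type whose contrast selected each gene)
#' @export
build_signature_matrix <- function(m, type_labels, top_n = 300,
                                   min_pct = 0.3, p_max = 0.01,
                                   q_max = 0.01, lfc_min = 0.2,
                                   high_frac = 0.5, max_high_types = 2) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  tt <- table(type_labels)
  if (length(tt) < 2) stop("need at least 2 types")
  if (any(tt < 20))
    stop("type(s) with < 20 cells: ",
         paste(names(tt)[tt < 20], collapse = ", "))
  types <- names(tt)
  cand <- list()
  for (t in types) {
    de <- wilcoxon_de(m, which(type_labels == t), which(type_labels != t),
                      min_pct = min_pct, lfc_min = lfc_min)
    de <- de[de$lfc > lfc_min & de$pct.1 > min_pct &
               de$p < p_max & de$q < q_max, , drop = FALSE]
    de <- de[order(-de$lfc, de$gene), , drop = FALSE]
    cand[[t]] <- utils::head(de$gene, top_n)
  }
  all_cand <- unique(unlist(cand))
  if (!length(all_cand)) stop("no candidate signature genes found")
  # "highly expressed" is judged on the linear expression scale: the log1p
  # layer compresses fold differences and would mark almost every gene high
  type_means <- sapply(types, function(t)
    colMeans(expm1(as.matrix(m$normalized[type_labels == t, all_cand,
                                          drop = FALSE]))))
  type_means <- matrix(type_means, nrow = length(all_cand),
                       dimnames = list(all_cand, types))
  n_high <- rowSums(type_means >= high_frac *
                      apply(type_means, 1, max))
  keep <- all_cand[n_high <= max_high_types]
  cand <- lapply(cand, intersect, keep)
  empty <- names(cand)[vapply(cand, length, 0L) == 0]
  if (length(empty))
    stop("type(s) with zero signature genes after specificity filter: ",
         paste(empty, collapse = ", "))
  sig_genes <- sort(unique(unlist(cand)))
  means <- sapply(types, function(t)
    Matrix::colMeans(m$normalized[type_labels == t, sig_genes,
                                  drop = FALSE]))
  sds <- sapply(types, function(t)
    apply(as.matrix(m$normalized[type_labels == t, sig_genes,
                                 drop = FALSE]), 2, stats::sd))
  rownames(means) <- rownames(sds) <- sig_genes
  gene_type <- unlist(lapply(names(cand), function(t)
    stats::setNames(rep(t, length(cand[[t]])), cand[[t]])))
  structure(list(means = means, sds = sds, signature_genes = sig_genes,
                 gene_type = gene_type),
            class = "SignatureMatrix")
}

#' Pool cells at expected ratios into a pseudo-bulk profile
#'
#' Samples \code{round(n_cells * p_t)} cells of each type without
#' replacement and sums their normalized expression.
#'
#' @param m a normalized \code{CellMatrix}
#' @param type_labels per-cell identity labels
#' @param proportions named type -> fraction vector summing to 1
#' @param n_cells total cells to pool
#' @param seed RNG seed
#' @return list: \code{bulk} (named per-gene summed normalized expression),
#'   \code{realized} (named realized proportions)
#' @export
make_pseudobulk <- function(m, type_labels, proportions, n_cells,
                            seed = 0L) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  set.seed(seed)
  take <- round(n_cells * proportions)
  idx <- integer()
  for (t in names(take)) {
    if (take[[t]] == 0) next
    pool <- which(type_labels == t)
    if (length(pool) < take[[t]])
      stop("insufficient cells of type ", t)
    idx <- c(idx, sample(pool, take[[t]]))
  }
  bulk <- Matrix::colSums(m$normalized[idx, , drop = FALSE])
  realized <- take / sum(take)
  list(bulk = bulk, realized = realized)
}

# Lawson-Hanson non-negative least squares: min ||A x - b||, x >= 0.
# Small dense problems only (signature genes x types).
.nnls <- function(A, b, tol = 1e-10, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      zp <- qr.coef(qr(Ap), b)
      zp[is.na(zp)] <- 0
      if (all(zp > tol)) {
        x[] <- 0; x[passive] <- zp
        break
      }
      z <- numeric(n); z[passive] <- zp
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) { x[] <- 0; break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Deconvolve a bulk profile by constrained weighted least squares
#'
#' Solves min ||W^(1/2) (S p - b)||^2 subject to p >= 0 and sum(p) <= 1 on
#' the signature genes, with the bulk vector rescaled to the reference's
#' overall magnitude and per-gene weights equal to the inverse squared
#' reference variability (floored). The sum constraint is imposed through a
#' slack variable and a strongly weighted equality row inside a
#' Lawson-Hanson non-negative least-squares solve. When the residual
#' "other" mass is below \code{renorm_cutoff} the leukemic fractions are
#' renormalized to sum to 1.
#'
#' @param bulk named per-gene bulk expression vector
#' @param sig a [build_signature_matrix()] object
#' @param input_log2 bulk values are log2(x + 1) and should be un-logged to
#'   the linear scale first (default FALSE)
#' @param sd_floor weight floor on the per-gene SD (default: 5% of the mean
#'   SD)
#' @param renorm_cutoff "other" mass below which proportions are
#'   renormalized (default 0.05)
#' @return list of class \code{ProportionEstimate}: \code{proportions}
#'   (named, >= 0, sum <= 1 before renormalization), \code{other_mass},
#'   \code{residual_norm}
#' @export
deconvolve <- function(bulk, sig, input_log2 = FALSE, sd_floor = NULL,
                       renorm_cutoff = 0.05) {
  stopifnot(inherits(sig, "SignatureMatrix"))
  genes <- intersect(sig$signature_genes, names(bulk))
  if (length(genes) < ncol(sig$means))
    stop("fewer signature genes present than cell types")
  b <- bulk[genes]
  if (input_log2) b <- 2^b - 1
  S <- sig$means[genes, , drop = FALSE]
  qrS <- qr(S)
  if (qrS$rank < ncol(S))
    stop("signature matrix is rank deficient (duplicated type profiles); ",
         "merge the colliding types")
  # scale bulk to the reference magnitude so proportions are unitless
  sc <- sum(S) / ncol(S) / max(sum(b), .Machine$double.eps)
  b <- b * sc
  sdv <- sig$sds[genes, , drop = FALSE]
  gsd <- rowMeans(sdv)
  if (is.null(sd_floor)) sd_floor <- 0.05 * mean(gsd)
  w <- 1 / pmax(gsd, sd_floor)^2
  sw <- sqrt(w)
  Aw <- S * sw
  bw <- b * sw
  lambda <- 1e4 * max(abs(Aw))
  A <- rbind(cbind(Aw, 0), lambda)           # slack column; equality row
  rhs <- c(bw, lambda)
  x <- .nnls(A, rhs)
  p <- x[seq_len(ncol(S))]
  names(p) <- colnames(S)
  other <- x[length(x)]
  resid <- sqrt(sum((Aw %*% p - bw)^2))
  if (other < renorm_cutoff && sum(p) > 0) p <- p / sum(p)
  structure(list(proportions = p, other_mass = other,
                 residual_norm = resid),
            class = "ProportionEstimate")
}

#' Per-type recovery correlation between estimates and truth
#'
#' @param estimates samples x types matrix of estimated proportions
#' @param truth samples x types matrix of true proportions (same dimnames)
#' @return list: \code{per_type} (named Pearson R), \code{min}, \code{max}
#' @export
evaluate_recovery <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  truth <- as.matrix(truth)[rownames(estimates), colnames(estimates),
                            drop = FALSE]
  if (nrow(estimates) < 10)
    stop("need at least 10 mixture samples")
  r <- vapply(colnames(estimates), function(t) {
    if (stats::sd(truth[, t]) == 0) {
      warning("zero-variance truth for type ", t, "; skipped")
      return(NA_real_)
    }
    stats::cor(estimates[, t], truth[, t])
  }, 0)
  list(per_type = r, min = min(r, na.rm = TRUE), max = max(r, na.rm = TRUE))
}

#' Write a signature matrix as TSV
#' @param sig a \code{SignatureMatrix}
#' @param path output path
#' @export
write_signature_matrix <- function(sig, path) {
  df <- data.frame(gene = sig$signature_genes,
                   sig$means, check.names = FALSE)
  colnames(df)[-1] <- colnames(sig$means)
  sd_df <- as.data.frame(sig$sds)
  colnames(sd_df) <- paste0("sd.", colnames(sig$sds))
  utils::write.table(cbind(df, sd_df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
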