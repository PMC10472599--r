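#' Per-cell module score with bin-matched control genes
#'
#' All genes are binned by their dataset-wide mean normalized expression
#' into \code{n_bins} equal-frequency bins; for every member gene,
#' \code{n_ctrl} control genes are sampled (seeded) from its bin, and the
#' score is mean(member expression) - mean(control expression) per cell.
#'
#' @param m a normalized \code{CellMatrix}
#' @param genes member gene set (>= 1 present gene required)
#' @param n_bins expression bins (default 24)
#' @param n_ctrl control genes sampled per member gene (default 100)
#' @param seed RNG seed for control sampling
#' @return numeric per-cell score vector (named by barcode)
#' @export
module_score <- function(m, genes, n_bins = 24, n_ctrl = 100, seed = 0L) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  members <- intersect(genes, gene_names(m))
  if (!length(members)) stop("no member genes present in the matrix")
  avg <- Matrix::colMeans(m$normalized)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- if (n_bins <= 1) rep(1L, length(avg)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- gene_names(m)
  set.seed(seed)
  ctrl <- unique(unlist(lapply(members, function(g) {
    pool <- names(bins)[bins == bins[g]]
    sample(pool, min(n_ctrl, length(pool)))
  })))
  mem_mean <- Matrix::rowMeans(m$normalized[, members, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(m$normalized[, ctrl, drop = FALSE])
  out <- as.numeric(mem_mean - ctrl_mean)
  names(out) <- cell_barcodes(m)
  out
}

#' The 17-gene leukemia stem cell score coefficients
#'
#' The published weighted stemness signature for AML: a linear combination
#' of 17 genes whose above-median values index adverse-risk, LSC-rich
#' disease.
#'
#' @return named numeric vector of the 17 coefficients
#' @export
lsc17_coefficients <- function() {
  c(DNMT3B = 0.0874, ZBTB46 = -0.0347, NYNRIN = 0.00865,
    ARHGAP22 = -0.0138, LAPTM4B = 0.00582, MMRN1 = 0.0258,
    DPYSL3 = 0.0284, KIAA0125 = 0.0196, CDK6 = -0.0704,
    CPXM1 = -0.0258, SOCS2 = 0.0271, SMIM24 = -0.0226,
    EMP1 = 0.0146, NGFRAP1 = 0.0465, CD34 = 0.0338,
    AKR1C3 = -0.0402, GPR56 = 0.0501)
}

#' Compute the 17-gene LSC score
#'
#' \code{sum(coefficient * value)} over the 17 genes. Expression values are
#' expected on a scaled (per-gene z-score) axis; missing genes contribute 0
#' with a warning.
#'
#' @param expr named numeric vector (or genes x samples matrix) of scaled
#'   expression
#' @return numeric score (vector over samples for matrix input)
#' @export
lsc17_score <- function(expr) {
  co <- lsc17_coefficients()
  if (is.matrix(expr)) {
    missing <- setdiff(names(co), rownames(expr))
    if (length(missing))
      warning("missing LSC17 gene(s) treated as 0: ",
              paste(missing, collapse = ", "))
    present <- intersect(names(co), rownames(expr))
    as.numeric(co[present] %*% expr[present, , drop = FALSE])
  } else {
    missing <- setdiff(names(co), names(expr))
    if (length(missing))
      warning("missing LSC17 gene(s) treated as 0: ",
              paste(missing, collapse = ", "))
    present <- intersect(names(co), names(expr))
    sum(co[present] * expr[present])
  }
}

#' Median split of per-patient scores
#'
#' Scores strictly above the median are "high", the rest "low".
#'
#' @param scores numeric vector (>= 2 values)
#' @return character vector in \{high, low\}
#' @export
split_by_median <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  ifelse(scores > stats::median(scores), "high", "low")
}

# running-sum enrichment score for one set against a ranked stat vector
.gsea_es <- function(stat_sorted, in_set, weight_exp) {
  n <- length(stat_sorted)
  nh <- sum(in_set)
  w <- abs(stat_sorted)^weight_exp
  hit <- ifelse(in_set, w, 0)
  hs <- sum(hit)
  if (hs == 0) hit <- ifelse(in_set, 1 / nh, 0) else hit <- hit / hs
  miss <- ifelse(in_set, 0, 1 / (n - nh))
  rs <- cumsum(hit - miss)
  rs[which.max(abs(rs))]
}

#' Gene set enrichment analysis (classic running-sum, gene-label null)
#'
#' Hits are weighted by |stat|^weight_exp (normalized to sum 1), misses by
#' 1/(N - NH); the enrichment score is the running-sum extremum. The null is
#' built by permuting gene labels; NES divides ES by the mean |null ES| of
#' the same sign, the nominal p is one-sided on the same-sign null, and for
#' multiple sets ([gsea_batch()]) FDR is the standard pooled-NES ratio.
#'
#' @param ranked named numeric vector: gene -> ranking statistic (finite)
#' @param genes gene set (>= 1 member in the ranked list; singleton sets are
#'   allowed so degenerate top-gene checks evaluate exactly)
#' @param weight_exp hit-weight exponent (default 1; 0 = unweighted)
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return list: \code{es}, \code{nes}, \code{p}, \code{leading_edge},
#'   \code{null_es}
#' @export
gsea <- function(ranked, genes, weight_exp = 1, n_perm = 1000, seed = 0L) {
  if (any(!is.finite(ranked))) stop("ranking statistics must be finite")
  ord <- order(ranked, decreasing = TRUE)
  stat <- ranked[ord]
  in_set <- names(stat) %in% genes
  nh <- sum(in_set)
  if (nh < 1) stop("empty overlap between the gene set and the ranked list")
  n <- length(stat)
  if (nh == n) {                         # degenerate: every gene is a hit
    return(list(es = 1, nes = NA_real_, p = NA_real_,
                leading_edge = names(stat), null_es = numeric()))
  }
  es <- .gsea_es(stat, in_set, weight_exp)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    perm <- logical(n)
    perm[sample.int(n, nh)] <- TRUE
    .gsea_es(stat, perm, weight_exp)
  }, 0)
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- if (length(same)) mean(abs(same) >= abs(es)) else NA_real_
  # leading edge: set genes up to (and including) the running-sum extremum
  w <- abs(stat)^weight_exp
  hit <- ifelse(in_set, w, 0)
  if (sum(hit) > 0) hit <- hit / sum(hit) else hit <- ifelse(in_set, 1 / nh, 0)
  rs <- cumsum(hit - ifelse(in_set, 0, 1 / (n - nh)))
  peak <- which.max(abs(rs))
  le <- if (es >= 0) names(stat)[seq_len(peak)][in_set[seq_len(peak)]]
  else names(stat)[peak:n][in_set[peak:n]]
  list(es = es, nes = nes, p = p, leading_edge = le, null_es = null_es)
}

#' GSEA over a collection of gene sets with pooled-null FDR
#'
#' @param ranked named numeric ranking-statistic vector
#' @param sets named list of gene sets
#' @param weight_exp,n_perm,seed as in [gsea()]
#' @return data.frame per set: \code{set}, \code{es}, \code{nes}, \code{p},
#'   \code{fdr}
#' @export
gsea_batch <- function(ranked, sets, weight_exp = 1, n_perm = 1000,
                       seed = 0L) {
  res <- lapply(seq_along(sets), function(i)
    gsea(ranked, sets[[i]], weight_exp, n_perm, seed + i))
  obs_nes <- vapply(res, function(r) r$nes, 0)
  null_nes <- unlist(lapply(res, function(r) {
    pos <- r$null_es[r$null_es > 0]
    neg <- r$null_es[r$null_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }))
  fdr <- vapply(seq_along(res), function(i) {
    nes <- obs_nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes >= nes)
      den <- mean(obs_nes >= nes, na.rm = TRUE)
    } else {
      num <- mean(null_nes <= nes)
      den <- mean(obs_nes <= nes, na.rm = TRUE)
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, 0)
  data.frame(set = names(sets),
             es = vapply(res, function(r) r$es, 0),
             nes = obs_nes,
             p = vapply(res, function(r) r$p, 0),
             fdr = fdr, stringsAsFactors = FALSE)
}

#' Chemoresistance call from enrichment results
#'
#' True iff NES strictly exceeds \code{nes_min} and FDR is strictly below
#' \code{fdr_max}.
#'
#' @param enrichments data.frame with \code{nes} and \code{fdr} columns
#'   (e.g. from [gsea_batch()])
#' @param nes_min NES threshold (default 1.9)
#' @param fdr_max FDR threshold (default 0.001)
#' @return logical vector aligned with the rows of \code{enrichments}
#' @export
call_chemoresistant <- function(enrichments, nes_min = 1.9,
                                fdr_max = 0.001) {
  with(enrichments, !is.na(nes) & !is.na(fdr) & nes > nes_min & fdr < fdr_max)
}

#' Resistant-vs-sensitive differential genes with per-patient consistency
#'
#' Pools HSC-like cells of the resistant patients against those of the
#' sensitive patients with [wilcoxon_de()] at the stated thresholds, then
#' keeps genes whose per-patient fold-change sign matches the pooled sign in
#' at least \code{min_consistent} patients of the gene's assigned group
#' (up-regulated genes checked in resistant patients, down-regulated in
#' sensitive).
#'
#' @param m a normalized \code{CellMatrix} of HSC-like cells
#' @param patient per-cell patient ids
#' @param group named character vector patient -> \{resistant, sensitive\}
#' @param min_pct,lfc_min,p_max,q_max DE thresholds
#' @param min_consistent patients required to share the pooled sign
#' @return filtered DE data.frame with a \code{n_consistent} column
#' @export
resistant_vs_sensitive_degs <- function(m, patient, group,
                                        min_pct = 0.3, lfc_min = 0.3,
                                        p_max = 1e-10, q_max = 0.01,
                                        min_consistent = 2L) {
  stopifnot(inherits(m, "CellMatrix"))
  res_pat <- names(group)[group == "resistant"]
  sen_pat <- names(group)[group == "sensitive"]
  if (length(res_pat) < 2 || length(sen_pat) < 2)
    stop("need at least 2 patients per group")
  ra <- which(patient %in% res_pat)
  rb <- which(patient %in% sen_pat)
  de <- wilcoxon_de(m, ra, rb, min_pct = min_pct, lfc_min = lfc_min)
  de <- de[de$p < p_max & de$q < q_max, , drop = FALSE]
  if (!nrow(de)) return(cbind(de, n_consistent = integer()))
  # per-patient fold change of each surviving gene vs the other group pool
  lin <- expm1(as.matrix(m$normalized[, de$gene, drop = FALSE]))
  patient_lfc <- function(p) {
    own <- patient == p
    other <- if (p %in% res_pat) rb else ra
    log((colMeans(lin[own, , drop = FALSE]) + 1) /
          (colMeans(lin[other, , drop = FALSE]) + 1))
  }
  lfc_by_pat <- vapply(c(res_pat, sen_pat), patient_lfc,
                       numeric(nrow(de)))
  lfc_by_pat <- matrix(lfc_by_pat, nrow = nrow(de),
                       dimnames = list(de$gene, c(res_pat, sen_pat)))
  n_cons <- vapply(seq_len(nrow(de)), function(i) {
    pats <- if (de$lfc[i] > 0) res_pat else sen_pat
    sum(sign(lfc_by_pat[i, pats]) == sign(de$lfc[i]))
  }, 0L)
  de$n_consistent <- n_cons
  de[n_cons >= min_consistent, , drop = FALSE]
}

#' Fraction of a population expressing a gene
#'
#' @param m a normalized \code{CellMatrix}
#' @param population nonempty cell index (or barcode) vector
#' @param gene gene name (default "CD69")
#' @return fraction of the population with normalized expression > 0
#' @export
cd69_positive_fraction <- function(m, population, gene = "CD69") {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  if (!gene %in% gene_names(m)) stop("gene absent: ", gene)
  if (is.character(population)) population <- match(population,
                                                    cell_barcodes(m))
  if (!length(population)) stop("empty population")
  mean(as.numeric(m$normalized[population, gene]) > 0)
}
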