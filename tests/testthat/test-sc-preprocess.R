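test_that("qc_filter applies each threshold and is idempotent", {
  # toy 5-cell matrix: one cell over the mito cutoff, one gene seen in 1 cell
  genes <- c("MT-CO1", paste0("g", 1:9))
  counts <- matrix(5, 5, 10, dimnames = list(paste0("c", 1:5), genes))
  counts[, "MT-CO1"] <- c(1, 1, 1, 1, 20)   # c5 mito 20/65 > 0.15
  counts["c1", "g9"] <- 3; counts[-1, "g9"] <- 0
  t <- qc_thresholds(min_genes = 2, min_umi = 10, max_mito = 0.15,
                     min_cells_per_gene = 2, drop_doublets = TRUE)
  f <- qc_filter(CellMatrix(counts), t)
  expect_equal(cell_barcodes(f), paste0("c", 1:4))
  expect_false("g9" %in% gene_names(f))
  # a cell below the gene-count threshold is removed
  counts2 <- matrix(0, 3, 300,
                    dimnames = list(paste0("c", 1:3), paste0("g", 1:300)))
  counts2[1, 1:150] <- 10   # 150 expressed genes < 200
  counts2[2, 1:250] <- 10
  counts2[3, 1:250] <- 10
  f2 <- qc_filter(CellMatrix(counts2),
                  qc_thresholds(min_genes = 200, min_umi = 500,
                                min_cells_per_gene = 1))
  expect_false("c1" %in% cell_barcodes(f2))
  # all cells passing: identity; and idempotence
  ff <- qc_filter(f, t)
  expect_equal(as.matrix(ff$counts), as.matrix(f$counts))
  expect_error(qc_filter(CellMatrix(counts2[1, , drop = FALSE]),
                         qc_thresholds()),
               "all cells filtered")
})

test_that("qc_filter removes doublet-flagged cells", {
  hd <- generate_healthy_reference(fix_config())
  expect_true(any(hd$cells$cell_meta$doublet_flag))
  f <- qc_filter(hd$cells)
  expect_false(any(f$cell_meta$doublet_flag))
})

test_that("normalize_depth matches the closed form and conserves depth", {
  counts <- matrix(c(1, 1, 2), 1, dimnames = list("c1", c("a", "b", "c")))
  m <- normalize_depth(CellMatrix(counts))
  expect_equal(as.numeric(m$normalized[1, "c"]), log(1 + 2 / 4 * 1e4))
  # conservation invariant on real synthetic data
  h <- fix_healthy()
  sums <- Matrix::rowSums(expm1(h$normalized))
  expect_true(all(abs(sums - 1e4) / 1e4 < 1e-6))
  # depth invariance: doubling a cell's counts leaves its profile unchanged
  m2 <- normalize_depth(CellMatrix(counts * 2))
  expect_equal(as.numeric(m2$normalized), as.numeric(m$normalized))
  # all-zero gene stays zero
  expect_equal(as.numeric(m$normalized[, "a"] * 0), 0)
  zero <- CellMatrix(matrix(c(1, 0), 2, 1,
                            dimnames = list(c("c1", "c2"), "g")))
  expect_error(normalize_depth(zero), "zero total")
})

test_that("variable-gene selection ranks structure above noise", {
  set.seed(11)
  n <- 400
  # bimodal gene vs Poisson gene at the same mean, plus constant genes
  bimodal <- c(rpois(n / 2, 1), rpois(n / 2, 9))
  pois <- rpois(n, 5)
  counts <- cbind(BIM = bimodal, POIS = pois, CONST = rep(5, n),
                  matrix(rpois(n * 40, 5), n,
                         dimnames = list(NULL, sprintf("F%02d", 1:40))))
  rownames(counts) <- sprintf("c%03d", seq_len(n))
  m <- normalize_depth(CellMatrix(counts))
  ranked <- select_variable_genes(m, n = ncol(counts))
  expect_lt(match("BIM", ranked), match("POIS", ranked))
  expect_equal(match("CONST", ranked), length(ranked))
  expect_setequal(ranked, colnames(counts))
  expect_warning(select_variable_genes(m, n = 1000), "all genes")
})

test_that("select_pcs combines the cumulative and elbow rules", {
  expect_equal(select_pcs(c(30, 25, 20, 10, 6, 4, 2, 1, 1, 1)), 6)
  expect_equal(select_pcs(100), 1)
  # equal shares: neither rule fires, degenerate fallback returns length
  expect_equal(select_pcs(rep(10, 10)), 10)
  # appending near-zero trailing components never pushes the result below 1
  base <- c(50, 30, 15, 4, 1)
  r1 <- select_pcs(base)
  r2 <- select_pcs(c(base, rep(1e-6, 20)))
  expect_gte(r2, 1)
  expect_equal(r1, r2)
  expect_error(select_pcs(numeric()), "empty")
})

test_that("SNN clustering separates blobs and is order-equivariant", {
  set.seed(5)
  blob <- function(center, n) sweep(matrix(rnorm(n * 5, sd = 0.5), n, 5),
                                    2, center, "+")
  emb <- rbind(blob(c(10, 0, 0, 0, 0), 100), blob(c(-10, 0, 0, 0, 0), 100))
  truth <- rep(1:2, each = 100)
  cl <- cluster_cells(emb, k_neighbors = 15, seed = 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(ari(cl, truth), 1)
  # degenerate point mass: the SNN graph is a clique, which modularity
  # optimization never splits (a homogeneous Gaussian blob, by contrast, IS
  # legitimately partitioned by modularity methods; see the methods
  # vignette)
  ident <- matrix(1, 60, 5) + matrix(rnorm(300, sd = 1e-9), 60)
  one <- cluster_cells(ident, k_neighbors = 15, seed = 2)
  expect_equal(length(unique(one)), 1)
  # permuting cells permutes labels consistently
  perm <- sample(nrow(emb))
  cl_p <- cluster_cells(emb[perm, ], k_neighbors = 15, seed = 2)
  expect_equal(ari(cl_p, cl[perm]), 1)
  expect_error(cluster_cells(emb[1:10, ], k_neighbors = 20), "fewer cells")
})

test_that("wilcoxon_de matches exact enumeration on a 4v4 toy case", {
  vals <- c(5, 6, 7, 8, 1, 2, 3, 4)
  counts <- cbind(DE = vals, matrix(4, 8, 3,
                                    dimnames = list(NULL, c("f1", "f2", "f3"))))
  rownames(counts) <- paste0("c", 1:8)
  m <- normalize_depth(CellMatrix(counts))
  de <- wilcoxon_de(m, 1:4, 5:8, min_pct = 0, lfc_min = 0)
  # brute-force oracle: enumerate all 70 assignments of ranks to group A
  r <- rank(vals)
  w_obs <- sum(r[1:4])
  combos <- utils::combn(8, 4)
  w_null <- apply(combos, 2, function(i) sum(r[i]))
  p_exact <- mean(abs(w_null - mean(w_null)) >= abs(w_obs - mean(w_null)))
  expect_equal(de$p[de$gene == "DE"], p_exact, tolerance = 1e-12)
  # swapping group labels flips the sign, keeps p
  de2 <- wilcoxon_de(m, 5:8, 1:4, min_pct = 0, lfc_min = 0)
  expect_equal(de2$lfc[de2$gene == "DE"], -de$lfc[de$gene == "DE"])
  expect_equal(de2$p[de2$gene == "DE"], de$p[de$gene == "DE"])
})

test_that("wilcoxon_de pre-filters and validates groups", {
  counts <- matrix(rpois(8 * 10, 5), 8,
                   dimnames = list(paste0("c", 1:8), paste0("g", 1:10)))
  m <- normalize_depth(CellMatrix(counts))
  # identical groups (same distribution duplicated): no lfc passes a
  # positive cutoff
  cdup <- rbind(counts, counts)
  rownames(cdup) <- paste0("c", 1:16)
  md <- normalize_depth(CellMatrix(cdup))
  de <- wilcoxon_de(md, 1:8, 9:16, min_pct = 0, lfc_min = 0.1)
  expect_equal(nrow(de), 0)
  expect_error(wilcoxon_de(m, 1:2, 3:8), "at least 3")
  expect_error(wilcoxon_de(m, 1:4, 4:8), "disjoint")
  # q >= p after BH
  de3 <- wilcoxon_de(m, 1:4, 5:8, min_pct = 0, lfc_min = 0)
  expect_true(all(de3$q >= de3$p - 1e-12))
  expect_true(all(de3$pct.1 >= 0 & de3$pct.1 <= 1))
})

test_that("wilcoxon_de p-values are uniform under the null", {
  set.seed(21)
  n_genes <- 1000
  counts <- matrix(rpois(60 * n_genes, 5), 60,
                   dimnames = list(sprintf("c%02d", 1:60),
                                   sprintf("g%04d", seq_len(n_genes))))
  m <- normalize_depth(CellMatrix(counts))
  de <- wilcoxon_de(m, 1:30, 31:60, min_pct = 0, lfc_min = 0)
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
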