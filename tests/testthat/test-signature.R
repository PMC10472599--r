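test_that("module_score matches the one-bin brute-force oracle and is linear", {
  set.seed(8)
  n <- 50; g <- 40
  counts <- matrix(rpois(n * g, 5), n,
                   dimnames = list(sprintf("c%02d", 1:n),
                                   sprintf("g%02d", 1:g)))
  m <- normalize_depth(CellMatrix(counts))
  members <- c("g01", "g02", "g03")
  # one bin + control sample covering the whole pool: score reduces to
  # mean(member) - mean(all genes), computable independently
  sc <- module_score(m, members, n_bins = 1, n_ctrl = g)
  oracle <- Matrix::rowMeans(m$normalized[, members]) -
    Matrix::rowMeans(m$normalized)
  expect_equal(unname(sc), as.numeric(oracle))
  # adding a constant to member genes only shifts the score by it
  m2 <- m
  m2$normalized[, members] <- m2$normalized[, members] + 0.7
  sc2 <- module_score(m2, members, n_bins = 1, n_ctrl = g)
  ctrl_shift <- 0.7 * length(members) / g   # members sit inside the pool
  expect_equal(unname(sc2 - sc), rep(0.7 - ctrl_shift, n))
  # seeded control sampling is reproducible
  expect_equal(module_score(m, members, seed = 3),
               module_score(m, members, seed = 3))
  expect_error(module_score(m, c("nope")), "no member genes")
})

test_that("lsc17_score applies the printed coefficients", {
  co <- lsc17_coefficients()
  expect_length(co, 17)
  zero <- stats::setNames(rep(0, 17), names(co))
  expect_equal(lsc17_score(zero), 0)
  one_gene <- zero; one_gene["DNMT3B"] <- 1
  expect_equal(lsc17_score(one_gene), 0.0874)
  # sum of all printed coefficients, verified independently by hand
  ones <- stats::setNames(rep(1, 17), names(co))
  expect_equal(lsc17_score(ones), 0.14027, tolerance = 1e-10)
  # linearity
  set.seed(2)
  x <- stats::setNames(rnorm(17), names(co))
  expect_equal(lsc17_score(3 * x), 3 * lsc17_score(x))
  # matrix input and missing genes
  mat <- cbind(s1 = x, s2 = 2 * x)
  expect_equal(lsc17_score(mat), c(lsc17_score(x), 2 * lsc17_score(x)))
  expect_warning(lsc17_score(x[1:10]), "treated as 0")
})

test_that("split_by_median uses a strict-above rule", {
  g <- split_by_median(c(1, 2, 3, 4))
  expect_equal(g, c("low", "low", "high", "high"))
  expect_equal(split_by_median(rep(5, 4)), rep("low", 4))
  # monotone transforms preserve the partition
  x <- c(0.3, 1.2, 5, 0.7, 2.2)
  expect_equal(split_by_median(x), split_by_median(log(x)))
  expect_error(split_by_median(1), "at least 2")
})

test_that("gsea matches the hand-computed running sum", {
  ranked <- stats::setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  res <- gsea(ranked, "g1", weight_exp = 0, n_perm = 10, seed = 1)
  # running sum with one top hit: 1, .75, .5, .25, 0 -> ES = 1
  expect_equal(res$es, 1.0)
  expect_error(gsea(ranked, "absent_gene"), "empty overlap")
  # all genes in the set: degenerate ES = 1
  expect_equal(gsea(ranked, paste0("g", 1:5))$es, 1)
  # reversing the ranking negates the ES of a top-loaded set
  fwd <- gsea(ranked, c("g1", "g2"), n_perm = 10, seed = 1)
  revd <- gsea(-ranked, c("g1", "g2"), n_perm = 10, seed = 1)
  expect_equal(revd$es, -fwd$es)
  expect_error(gsea(c(a = Inf, b = 1), "a"), "finite")
})

test_that("gsea ES is bounded and null p is uniform", {
  set.seed(31)
  n <- 200
  p_vals <- es_vals <- numeric(300)
  for (i in seq_len(300)) {
    ranked <- stats::setNames(rnorm(n), sprintf("x%03d", 1:n))
    set_genes <- sample(names(ranked), 15)
    r <- gsea(ranked, set_genes, n_perm = 200, seed = i)
    p_vals[i] <- r$p
    es_vals[i] <- r$es
  }
  expect_true(all(abs(es_vals) <= 1))
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("call_chemoresistant applies strict NES and FDR cutoffs", {
  enr <- data.frame(nes = c(2.3, 2.3, 1.9, 2.5, NA),
                    fdr = c(1e-5, 0.01, 1e-5, 0.0009, 1e-5))
  expect_equal(call_chemoresistant(enr),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("resistant-vs-sensitive DEGs require per-patient consistency", {
  set.seed(12)
  n_per <- 40
  pats <- rep(c("R1", "R2", "S1", "S2"), each = n_per)
  group <- c(R1 = "resistant", R2 = "resistant",
             S1 = "sensitive", S2 = "sensitive")
  g <- 30
  mu <- matrix(4, length(pats), g,
               dimnames = list(NULL, sprintf("g%02d", 1:g)))
  mu[pats %in% c("R1", "R2"), "g01"] <- 16       # consistent effect
  mu[pats == "R1", "g02"] <- 20                  # discordant effect
  mu[pats == "R2", "g02"] <- 1
  counts <- matrix(rpois(length(mu), mu), nrow(mu), dimnames = dimnames(mu))
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  m <- normalize_depth(CellMatrix(counts))
  degs <- resistant_vs_sensitive_degs(m, pats, group, p_max = 1e-6)
  expect_true("g01" %in% degs$gene)
  expect_false("g02" %in% degs$gene)
  # identical groups give an empty list
  none <- resistant_vs_sensitive_degs(
    m, rep(c("R1", "R2", "S1", "S2"), n_per), group, p_max = 1e-6)
  expect_equal(nrow(none), 0)
  expect_error(resistant_vs_sensitive_degs(m, pats,
                                           c(R1 = "resistant",
                                             S1 = "sensitive",
                                             S2 = "sensitive")),
               "2 patients")
})

test_that("CD69-positive fraction recovers the generative parameter", {
  counts <- matrix(1, 10, 2, dimnames = list(paste0("c", 1:10),
                                             c("CD69", "f")))
  counts[10, "CD69"] <- 0
  m <- normalize_depth(CellMatrix(counts))
  expect_equal(cd69_positive_fraction(m, 1:10), 0.9)
  counts[, "CD69"] <- 0
  m0 <- normalize_depth(CellMatrix(counts))
  expect_equal(cd69_positive_fraction(m0, 1:10), 0)
  expect_error(cd69_positive_fraction(m, integer()), "empty population")
  # generative check at n >= 500 malignant HSC-like cells
  cfg <- sim_config(seed = 13, n_cells_per_sample = 2500,
                    cd69_hsc_fraction = 0.9)
  pp <- generate_patient_pair(cfg)
  m <- normalize_depth(pp$pre)
  meta <- m$cell_meta
  hsc_mal <- which(meta$true_malignant & meta$true_type == "HSC" &
                     !meta$doublet_flag)
  expect_gte(length(hsc_mal), 300)
  expect_lt(abs(cd69_positive_fraction(m, hsc_mal) - 0.9), 0.05)
})
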