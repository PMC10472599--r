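# Shared fixtures, built once per test run and memoised. All synthetic data
# comes from the package's own generator at its stated-world defaults
# (reduced cell counts keep the full suite inside the CI budget).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fix_config <- function() {
  memo("cfg", sim_config(seed = 1, n_cells_per_type = 80,
                         n_cells_per_sample = 1200))
}

fix_healthy <- function() {
  memo("healthy", {
    hd <- generate_healthy_reference(fix_config())
    normalize_depth(qc_filter(hd$cells))
  })
}

fix_patient <- function() {
  memo("patient", generate_patient_pair(fix_config()))
}

# full anchored co-clustering run: healthy + pre + post, QC, HVG, PCA, SNN
fix_cocluster <- function() {
  memo("cocluster", {
    cfg <- fix_config()
    hd <- generate_healthy_reference(cfg)
    pp <- fix_patient()
    anchor <- compose_anchor_set(hd$cells, pp$pre, pp$post)
    m <- normalize_depth(qc_filter(anchor$cells))
    hvg <- select_variable_genes(m, 1000)
    pca <- run_pca(m, hvg, n_pcs = 30)
    npc <- max(select_pcs(pca$explained_pct), 5)
    cl <- cluster_cells(pca$embedding[, seq_len(npc), drop = FALSE],
                        seed = 1)
    list(m = m, clusters = cl, call = call_leukemic_clusters(
      cl, m$cell_meta$origin))
  })
}

fix_leukref <- function() {
  memo("leukref",
       generate_leukemic_reference(sim_config(seed = 0),
                                   n_cells_per_identity = 120))
}

fix_signature <- function() {
  memo("signature", {
    lr <- fix_leukref()
    build_signature_matrix(lr$cells, lr$identities)
  })
}

# adjusted Rand index for partition comparisons
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# tiny dense CellMatrix from an explicit matrix
toy_matrix <- function(counts, meta = NULL, normalize = TRUE) {
  m <- CellMatrix(counts, meta)
  if (normalize) m <- normalize_depth(m) else m
  m
}
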