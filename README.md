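# leukotrace

Tracing chemoresistant leukemic cells in paired pre-/post-chemotherapy
single-cell transcriptomes.

## The problem

Pediatric AML patients in remission still harbor rare residual leukemic
cells (often ~1–10% of marrow), and these cells seed relapse. Because AML
blasts lack universal surface markers, whole bone-marrow scRNA-seq of such
samples yields an unlabeled mixture of normal and malignant cells in which
the malignant fraction of a *post*-therapy sample is too small to form its
own obvious clusters. `leukotrace` implements an anchored co-clustering
strategy for this setting, plus the downstream analyses that characterize
which leukemic subpopulations survive therapy — in particular a CD69⁺
HSC-like subpopulation whose abundance predicts measurable residual
disease (MRD), relapse, and shorter survival.

## What the package computes

- **Malignancy calling by anchored co-clustering.** Healthy-donor cells,
  the high-burden pre-therapy sample, and the paired post-therapy sample
  are pooled (gene intersection), depth-normalized
  (`x′ = ln(1 + 10⁴·x/Σx)`), reduced by PCA on variance-stabilized
  high-variance genes, and partitioned on a shared-nearest-neighbor (SNN)
  graph with Leiden modularity clustering. A cluster is called leukemic iff
  strictly more than 80% of its cells come from the pre-therapy sample;
  every cell in such a cluster — including post-therapy cells — inherits
  the call (residual disease). Clusters resembling mature lymphoid cells
  (B/CTL/NK) are revised to normal.
- **Cell typing by cosine projection.** A reference of per-type centroids
  over the union of top-100 one-vs-rest marker genes assigns each cell its
  nearest healthy counterpart by cosine similarity; leukemic cells are
  labeled with a `"-like"` suffix (`HSC-like`, `GMP-like`, …).
- **Independent genotype validation.** Per-cell SNV genotypes from
  UMI-deduplicated allele counts; fusion-bearing cells from two rules
  (junction-proximal soft clips realigning to the partner flank; UMIs
  split across the two partners); chromosome-Y loss via the RPS4Y1
  indicator; LAIP marker co-expression; and the concordance of each
  evidence set with the transcriptomic call.
- **Chemoresistance scoring.** Bin-matched module scores, the 17-gene
  LSC score `Σ cᵢ·xᵢ` with the published coefficients
  (DNMT3B·0.0874 + ZBTB46·(−0.0347) + … + GPR56·0.0501), permutation GSEA
  with NES/FDR and the `NES > 1.9 & FDR < 0.001` chemoresistance call,
  resistant-vs-sensitive DEGs with per-patient consistency filtering, and
  CD69-positive fractions.
- **Deconvolution of bulk cohorts.** A signature matrix over the 11
  leukemic identities (top-300 one-vs-rest genes, specificity-filtered to
  genes high in ≤ 2 types), pseudo-bulk simulation by pooling cells at
  expected ratios and summing normalized expression, and constrained
  weighted least squares `min ‖W^{1/2}(Sp − b)‖²` s.t. `p ≥ 0, Σp ≤ 1`
  solved by Lawson–Hanson NNLS with an equality slack.
- **Cohort statistics.** Blast/FAB cohort filtering, CD69⁺ HSC-like
  stratification (> 25% high, < 10% low), exact two-sided Fisher tests,
  MRD positivity (≥ 0.1%), Kaplan–Meier/log-rank, and the univariate
  (p < 0.10 entry) → multivariate Cox workflow.
- **A synthetic-data module** generates every input with ground truth — a
  13-type hematopoietic hierarchy, patient pairs at configurable tumor
  burden (defaults 0.65 pre / 0.036 post), a CD69⁺ HSC-like program,
  variant/fusion read evidence with decoy soft clips, and bulk cohorts
  whose MRD odds and event hazard rise with the true CD69⁺ HSC-like
  fraction — so the whole pipeline is testable without restricted data.

## Worked example

```r
library(leukotrace)
cfg <- sim_config(seed = 42, n_cells_per_type = 80, n_cells_per_sample = 1500)
hd  <- generate_healthy_reference(cfg)
pp  <- generate_patient_pair(cfg)

anchor <- compose_anchor_set(hd$cells, pp$pre, pp$post)
m   <- normalize_depth(qc_filter(anchor$cells))
hvg <- select_variable_genes(m, 1000)
pca <- run_pca(m, hvg, n_pcs = 30)
npc <- max(select_pcs(pca$explained_pct), 5)
cl  <- cluster_cells(pca$embedding[, 1:npc], seed = 42)
call <- call_leukemic_clusters(cl, m$cell_meta$origin)
summarize_residual(call, m$cell_meta$origin)
#>   origin n_leukemic n_total    fraction
#>  healthy          2    1039 0.001924928
#>      pre        999    1500 0.666000000
#>     post         58    1500 0.038666667
```

The recovered leukemic fractions (66.6% pre, 3.87% post) match the
generator's realized truth (66.5% / 3.79%): the caller finds the residual
post-therapy cells without ever seeing the labels. Validation against read
evidence and the CD69 rule:

```r
reads <- generate_read_evidence(cfg, pp$pre)
snv   <- assign_snv_genotype(reads, cell_barcodes(pp$pre), "FLT3")
mut   <- intersect(snv$barcode[snv$genotype == "mutant"], m$cell_meta$barcode)
concordance(mut, call, m$cell_meta$barcode)
#> [1] 1                     # all 499 mutant cells fall in leukemic calls

hsc <- which(m$cell_meta$true_malignant & m$cell_meta$true_type == "HSC")
cd69_positive_fraction(m, hsc)
#> [1] 0.904                 # configured cd69_hsc_fraction = 0.9
```

## Layout

- `R/` — implementation (simulation, preprocessing, malignancy calling,
  projection, genotyping, signatures/GSEA, deconvolution, cohort stats)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/leukotrace-methods.Rmd` — the methods notes: model,
  parameters, numerical choices, limitations
- `scripts/acceptance.R` — the acceptance report
- `inst/cli/leukotrace` — minimal command-line entry point
  (`leukotrace simulate --seed 0 --out dir/`)
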