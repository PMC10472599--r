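---
title: "leukotrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leukotrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the model behind each stage of the pipeline, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The malignancy-calling model

Residual leukemic cells in a remission marrow are too rare to form obvious
clusters on their own. The package therefore anchors them: healthy-donor
cells, the high-burden pre-therapy sample, and the paired post-therapy
sample are pooled over their gene intersection and clustered together.
Pre-therapy leukemic cells are abundant enough to form their own clusters
away from the healthy manifold, and residual post-therapy cells — being
transcriptomically the same clone — co-cluster with them.

The call itself is a composition rule: a cluster is leukemic iff strictly
more than 80% of its cells originate from the pre-therapy sample. The
strictness matters only at the boundary and is exposed (`threshold`).
Post-therapy cells inside a leukemic cluster are the residual-disease
readout. Two guards temper the rule:

* clusters smaller than `min_cluster_size` (default 10) are never called
  leukemic — the composition fraction of a tiny cluster is noise, and the
  source procedure is silent on them;
* leukemic clusters whose majority projected cell type is mature lymphoid
  (B/CTL/NK/T) are revised to normal. This operationalizes the additional
  requirement that leukemic clusters "relate closely to myeloid cells":
  in pediatric AML a pre-therapy-dominated lymphoid cluster is far more
  plausibly a sampling artifact (e.g., donor-specific lymphocytes) than a
  myeloid malignancy.

Clusters dominated by *post*-therapy cells are never called leukemic; a
regenerating normal compartment after chemotherapy looks exactly like
that, and the one-sided rule encodes it.

## 2. Preprocessing

QC drops cells with < 200 expressed genes, < 500 UMIs, > 15%
mitochondrial reads (genes prefixed `MT-`), or a doublet flag, then genes
expressed in < 10 cells. Removing genes lowers per-cell gene/UMI counts,
so the two steps iterate to a fixed point; this makes `qc_filter`
idempotent by construction. The gene filter runs *after* cell filtering
(the order is unstated in the source procedure; filtering genes on
post-QC cells is the interpretation that does not let discarded cells
veto genes).

Normalization is depth-10,000 log1p; the invariant
`sum(expm1(x')) == 1e4` per cell is asserted in the tests. Scaling for
PCA is a per-gene z-score capped at ±10; cell-cycle regression is
deliberately omitted (the synthetic world has no cell-cycle structure,
and the hook would be untestable here).

The number of PCs combines two cutoffs on the per-component variance
percentages: `co1`, the first component where the cumulative share
exceeds 90% while the component's own share is below 5%; `co2`, the last
component whose drop to its successor exceeds 0.1 points. The result is
`min(co1, co2)`, falling back to whichever is defined, and to the full
length when neither fires (all-equal shares). The original sentence
describing this heuristic is grammatically ambiguous; `min(co1, co2)` is
its standard reading and both sub-criteria are exposed as parameters.

### Clustering and the single-blob caveat

Clustering builds a cosine k-NN graph (k = 20), reweights edges by the
Jaccard similarity of (self-inclusive) neighbor sets, prunes below 1/15,
and runs Leiden modularity optimization at resolution 0.8 with a fixed
seed. The community-detection backend is pluggable in principle (Louvain
and Leiden agree on all synthetic checks); Leiden is the default.

One property one might expect does **not** hold and is not claimed: a
single homogeneous Gaussian blob is *not* guaranteed to come back as one
cluster. Its k-NN graph is a random geometric graph, and modularity
optimization at resolution 0.8 legitimately partitions it (typically 4–5
communities). The degenerate case that does hold — a point mass, whose
SNN graph is a clique that no modularity split can improve — is what the
test asserts. Over-partitioning is harmless to the malignancy caller:
splitting a leukemic cluster into several sub-clusters leaves each
sub-cluster's pre-therapy composition, and hence the call, intact.
Under-partitioning would be harmful, which is why no cluster-merging
heuristic is applied.

### Differential expression

The Wilcoxon rank-sum primitive pre-filters genes on expressing-cell
fraction and on the natural-log fold change of group means computed on
`expm1` of the normalized layer with pseudocount 1 (the Seurat-v3
convention), then tests with an exact null when both groups are < 50
cells and values are untied, and a tie-corrected normal approximation
otherwise. BH adjustment runs over tested genes only, so `q >= p`
row-wise.

## 3. Cell-type projection

The projection reference replaces per-cell nearest-neighbor search with
per-type centroids: mean normalized expression over the union of top-100
one-vs-rest markers (ranked by average fold change among genes with
q < 0.01). A cell's type is the argmax of cosine similarity on that gene
union (missing genes imputed 0, ties broken by type-name order), with an
unassigned flag below 0.7 — the default threshold of the projection tool
family this emulates. The centroid simplification is deliberate: it is
deterministic, testable in closed form (the 0.6/0.4 two-centroid example
gives similarity `0.6/sqrt(0.52)`), and on the synthetic world achieves
the ≥ 0.9 held-out accuracy the contract requires. Reference types with
fewer than 3 cells are excluded with a warning rather than an error so a
sparsely sampled mature type cannot abort reference construction.

The 20-type manual merging step used on real data (correlation-heatmap
merging of over-clustered groups) is left to configuration: the package
accepts any type labeling.

## 4. Genotype validation

Three independent evidence channels validate the transcriptomic call:

* **SNV genotypes**: per cell, alleles are deduplicated to distinct UMIs;
  a UMI with conflicting alleles is discarded entirely. Mutant = ≥ 1 alt
  UMI; wildtype = 0 alt and ≥ 1 ref; unknown otherwise. No UMI-error
  collapsing is attempted (unstated upstream; exact-match dedup is the
  conservative choice).
* **Fusions**: Rule 1 accepts a read whose clip attachment is within
  `max_junction_distance` (default 5) of the junction, with a soft clip of
  ≥ `min_clip_len` (10) aligning ungapped to the partner's junction flank
  at ≥ 90% identity over a sliding window. Rule 2 accepts a (barcode, UMI)
  pair split across the two partners. The original procedure realigned
  clips with blastn without stated cutoffs; the sliding-window identity is
  a deterministic stand-in, and the decoy-clip suite (random 20-mers, 10
  seeds) verifies a zero false-positive rate at these defaults. Absence
  of fusion evidence yields "unknown", never "wildtype" — dropout makes
  the evidence one-sided.
* **Chromosome-Y loss** uses a single pervasively expressed chrY
  indicator gene (default `RPS4Y1`): the fraction of a population
  expressing it, with a loss-consistent call below 5% in a male sample.
* **LAIP co-expression** requires every marker simultaneously > 0; the
  result equals the intersection of per-marker positive sets.

`concordance` then reports the fraction of evidence-positive cells that
the transcriptomic caller labels leukemic; on the default synthetic world
this exceeds 0.9, mirroring the > 93% reported on real patients.

## 5. Signature scoring

`module_score` follows the bin-matched control-gene scheme: genes binned
by dataset-wide mean expression (24 equal-frequency bins), `n_ctrl`
controls sampled per member from its bin with a fixed seed, score = mean
member minus mean control expression per cell. It is the package's single
per-cell scoring primitive; a GSVA variant is intentionally not
duplicated alongside it.

The 17-gene LSC score uses the printed coefficients verbatim; the test
suite freezes their hand-verified sum (0.14027) and the score's
linearity. Scores are computed on per-gene z-scores across patients
before the median split (the "scaled data" convention; the source is not
fully explicit, and z-scoring is the reading that makes the median split
scale-free). The split is strict: score > median is high.

GSEA is the classic running sum (hits weighted by |stat|^w normalized to
sum 1, misses by 1/(N−NH); ES = extremum). The null permutes **gene
labels**, not phenotypes — at desk scale (tens of cells per population,
thousands of genes) phenotype permutation is both unstable and
unnecessary for the NES > 1.9 / FDR < 0.001 call, and the divergence from
the reference tool's default is deliberate and documented here. NES
divides ES by the mean |null ES| of the same sign; FDR pools null NES
across sets in the standard ratio. The ranking statistic for population
scans is the natural-log fold change of the population versus all other
leukemic populations within the same patient. Both chemoresistance-call
cutoffs are strict inequalities.

## 6. Deconvolution

The signature matrix takes the top-300 one-vs-rest up-regulated genes per
identity (pct.1 > 0.3, p < 0.01, FDR < 0.01, logFC > 0.2) and removes
genes "highly expressed" in more than two identities. Two choices here
are ours and exposed as parameters: *highly expressed* means a type's
linear-scale mean is ≥ 50% of the maximum type mean (the log1p scale
compresses fold differences so badly that on it the filter degenerates),
and the ≤ 2-type allowance is what lets genuinely shared programs (e.g.,
the two HSC-like subtypes' stem markers) survive while promiscuous genes
are dropped.

Pseudo-bulk profiles pool `round(n·p_t)` cells per type without
replacement and sum the normalized expression — deliberately the same
scale on which the signature means are stored, so mixing is linear in the
realized proportions. Deconvolution solves weighted constrained least
squares with weights 1/SD² (floored at 5% of the mean SD), the bulk
vector rescaled to the reference's overall magnitude, non-negativity and
`sum ≤ 1` enforced through a Lawson–Hanson NNLS with a slack variable and
a strongly weighted equality row (no QP dependency). The full
mRNA-content renormalization of the reference tool is simplified away —
synthetic types share content by construction — but a per-type content
multiplier would slot into the same solve. Bulk cohort matrices arrive as
log2(x+1); an `input_log2` flag un-logs before solving.

The exact proportion grid behind the published 2,529-sample simulation is
unstated; the acceptance run uses 55 mixtures in which a rotating focal
identity sweeps zero-to-dominant with a Dirichlet remainder, which spans
the "from zero to all" range at desk scale.

## 7. Cohort statistics

The Fisher test is exact two-sided by probability-mass ordering with a
`1 + 1e-7` relative tolerance (the convention of standard software, and
verified against it exhaustively in tests); the odds ratio is the sample
ratio. KM/log-rank are implemented directly (deaths precede censorings at
tied times; 1-df statistic) and cross-checked against the survival
package. The Cox workflow delegates the partial-likelihood fit to
`survival::coxph` (Efron ties, Wald CIs) — re-deriving a Newton solver
would add risk, not information — while the screening logic (univariate
p < 0.10 entry, correlation pruning at |r| > 0.8 keeping the smaller
univariate p, per-covariate convergence flags) is the package's own. The
0.8 pruning cutoff parameterizes an unquantified "mutually strong
correlations" exclusion and is exposed.

The CD69⁺ stratification uses > 25% (high) and < 10% (low); the middle
stratum is excluded from two-group tests to keep ambiguous fractions out,
and MRD positivity is ≥ 0.1% (a non-strict inequality, unlike the
stratification cutoffs).

## 8. The synthetic world

The generator is a stated world, not a tuning dial. Counts are negative
binomial (size 2) with a log-normal library factor (sdlog 0.25) — the
standard model for UMI data, whose distributional family the source does
not state. Its fixed points:

* 13 healthy types with disjoint 30-gene marker blocks at 4-fold
  elevation; named genes (`CD34`, `CD69`, `RPS4Y1`, `CD56`, `CD123`,
  `MT-*`) exist so the literal rules run unmodified.
* Malignant cells = base-type program + a shared 50-gene leukemia program
  at 4-fold — strong enough that co-clustering separation is achievable,
  weak enough that the caller is actually exercised; both knobs exist to
  stress-test it.
* Tumor burden 0.65 pre / 0.036 post (the cohort averages 64.76% and
  3.58%); malignant counts are binomial draws, so recovery tests use
  binomial oracles.
* CD69 positivity among malignant HSC-like cells is an explicit Bernoulli
  at `cd69_hsc_fraction` (default 0.9, the ~90% observed in resistant
  patients) with a forced positive count, so configured fractions are
  exact; CD69⁺ cells additionally carry a 20-gene adhesion/quiescence
  program (3-fold; real resistant HSC-like cells show such a program),
  which is also what makes the two HSC-like identities separable in
  deconvolution beyond the single CD69 gene.
* Read evidence: alt-allele capture 0.5, fusion-evidence capture 0.3 per
  mutant cell, decoy soft clips of random sequence at rate 0.05, and
  background non-junction reads on both partners.
* Bulk cohorts draw true proportions from a Dirichlet with concentration
  1 except 2 on the CD69⁺ HSC-like component — giving a cohort mean near
  17% and roughly a quarter of patients above the 25% cutoff, the
  magnitudes printed for the public cohorts. MRD-positivity log-odds and
  event hazards increase with the true CD69⁺ fraction through
  `hazard_link` (default 3, chosen once so the high-vs-low hazard ratio
  lands near 2.3, the printed magnitude; 0 severs the association and the
  independence test uses exactly that).
* Doublets are summed random cell pairs with a truth flag; QC consumes
  the flag, no detection algorithm is implemented.

What the generator does **not** emulate — and therefore what a green test
does not establish: transcriptome-wide co-expression structure, batch
effects (the integration hook is pass-through; anchor-based integration
internals are out of scope), sequence-error models beyond decoy clips,
ambient RNA, and realistic FAB-subtype/composition coupling. Desk scale
(≤ 3,000 cells/sample, 2,000 genes) stands in for the published hundreds
of thousands of cells; thresholds shown to hold here are necessary, not
sufficient, evidence for behavior at full scale.

## 9. Numerical and degenerate-input choices

* Variable-gene ranking breaks ties by gene name; projection ties break
  by type name; both make reruns bit-identical.
* `select_pcs` returns at least 1 and falls back to the vector length
  when neither cutoff fires (all-equal shares).
* `qc_filter` errors explicitly when every cell (or gene) would be
  removed; `normalize_depth` refuses zero-total cells.
* The NNLS solve tolerates 1e-10; noiseless identifiable mixtures are
  recovered to ≤ 1e-6 absolute error (asserted).
* All generator randomness derives from `sim_config(seed)`; each
  generator call re-seeds from the config seed plus a fixed offset, so
  outputs are reproducible independently of call order, and the baseline
  gene means are drawn once in `sim_config` itself so every sample shares
  the same world.
* Fisher p-values are clipped at 1; empty evidence sets, empty marker
  sets, empty populations, and mismatched cell universes raise immediate
  errors rather than propagating NA.

## 10. Known limitations

* The centroid projection cannot represent within-type continua; cells
  between two types get the nearer centroid, not a mixture.
* Gene-label GSEA nulls ignore inter-gene correlation; FDRs are
  well-calibrated on the synthetic world but optimistic on strongly
  correlated real modules.
* The deconvolution solver assumes the bulk platform is, after one global
  rescaling, on the reference scale; platform-specific per-gene biases
  are not modeled.
* The Cox workflow fits a single multivariate model; no stepwise
  refinement or interaction terms.
* The CLI is a thin convenience wrapper; the R API is the contract.
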