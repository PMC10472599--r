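#' Simulation configuration for the synthetic hematopoietic world
#'
#' Defines the generative model every downstream stage is tested against: a
#' multi-type hematopoietic hierarchy with disjoint marker-gene blocks, a
#' shared leukemia program separating malignant cells from their normal
#' counterparts, a CD69-positive HSC-like subpopulation carrying its own
#' adhesion/quiescence program, negative-binomial counts with log-normal
#' library sizes, variant/fusion read evidence, and bulk cohorts whose
#' event hazard and MRD-positivity odds increase with the true CD69+
#' HSC-like fraction.
#'
#' Defaults encode the stated world: pre-therapy tumor burden 0.65 and
#' post-therapy 0.036 (the cohort averages 64.76% and 3.58%), a CD69+
#' fraction of 0.9 among malignant HSC-like cells (~90% observed in
#' resistant patients), marker and leukemia-program fold changes of 4, and
#' desk scale (<= 3000 cells/sample, <= 2000 genes).
#'
#' @param seed integer seed; fully determines all generator output
#' @param n_genes total gene count (>= number of structured genes)
#' @param n_markers marker genes per cell type (disjoint blocks)
#' @param marker_fold fold elevation of a type's markers within that type
#' @param n_cells_per_type healthy-reference cells per type
#' @param n_cells_per_sample cells per patient sample
#' @param tumor_burden_pre,tumor_burden_post malignant fraction per timepoint
#' @param cd69_hsc_fraction fraction of malignant HSC-like cells CD69-positive
#' @param leuk_program_size,leuk_program_fold shared leukemia program block
#' @param cd69_program_size,cd69_program_fold CD69+ HSC-like program block
#' @param nb_size negative-binomial size (inverse dispersion)
#' @param libsize_sdlog sd of the log-normal per-cell library factor
#' @param doublet_rate fraction of appended doublet cells
#' @param sex donor/patient sex ("male" or "female"); drives RPS4Y1
#' @param chrY_loss malignant cells carry a chromosome-Y deletion
#' @param rps4y1_capture probability a male cell shows RPS4Y1 expression
#' @param cd69_baseline probability a normal cell shows CD69 expression
#' @param cohort_size bulk-cohort patient count
#' @param dirichlet_conc Dirichlet concentration for bulk true proportions
#' @param cd69_dirichlet_conc concentration of the CD69+ HSC-like component
#'   (default 2, giving a cohort mean near 17% and roughly a quarter of
#'   patients above the 25% "high" cutoff, as printed for the public
#'   cohorts)
#' @param hazard_link coefficient tying CD69+ HSC-like fraction to event
#'   hazard and MRD-positivity log-odds (0 = no association; the default 3
#'   yields a high-vs-low hazard ratio near 2.3, the printed magnitude)
#' @param bulk_noise_sd lognormal noise sd on linear-scale bulk profiles
#' @param variant_spec,fusion_spec see [default_variant_spec()],
#'   [default_fusion_spec()]
#' @return list of class \code{SimConfig}
#' @export
sim_config <- function(seed = 0L,
                       n_genes = 2000L,
                       n_markers = 30L,
                       marker_fold = 4,
                       n_cells_per_type = 150L,
                       n_cells_per_sample = 2000L,
                       tumor_burden_pre = 0.65,
                       tumor_burden_post = 0.036,
                       cd69_hsc_fraction = 0.9,
                       leuk_program_size = 50L,
                       leuk_program_fold = 4,
                       cd69_program_size = 20L,
                       cd69_program_fold = 3,
                       nb_size = 2,
                       libsize_sdlog = 0.25,
                       doublet_rate = 0.02,
                       sex = "male",
                       chrY_loss = FALSE,
                       rps4y1_capture = 0.8,
                       cd69_baseline = 0.05,
                       cohort_size = 120L,
                       dirichlet_conc = 1,
                       cd69_dirichlet_conc = 2,
                       hazard_link = 3,
                       bulk_noise_sd = 0.1,
                       variant_spec = default_variant_spec(),
                       fusion_spec = default_fusion_spec()) {
  fracs <- c(tumor_burden_pre, tumor_burden_post, cd69_hsc_fraction,
             doublet_rate, rps4y1_capture, cd69_baseline)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (!sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  if (nchar(fusion_spec$flank5) < fusion_spec$min_clip_len ||
      nchar(fusion_spec$flank3) < fusion_spec$min_clip_len)
    stop("fusion flanks shorter than min_clip_len")
  types <- c("HSC", "LMPP", "GMP", "CLP", "MEP", "EBM",
             "MONO", "NEUT", "CDC", "PDC", "B", "CTL", "NK")
  catalog <- .build_gene_catalog(types, n_genes, n_markers,
                                 leuk_program_size, cd69_program_size)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_markers = n_markers, marker_fold = marker_fold,
              n_cells_per_type = n_cells_per_type,
              n_cells_per_sample = n_cells_per_sample,
              tumor_burden_pre = tumor_burden_pre,
              tumor_burden_post = tumor_burden_post,
              cd69_hsc_fraction = cd69_hsc_fraction,
              leuk_program_fold = leuk_program_fold,
              cd69_program_fold = cd69_program_fold,
              nb_size = nb_size, libsize_sdlog = libsize_sdlog,
              doublet_rate = doublet_rate, sex = sex, chrY_loss = chrY_loss,
              rps4y1_capture = rps4y1_capture, cd69_baseline = cd69_baseline,
              cohort_size = as.integer(cohort_size),
              dirichlet_conc = dirichlet_conc,
              cd69_dirichlet_conc = cd69_dirichlet_conc,
              hazard_link = hazard_link,
              bulk_noise_sd = bulk_noise_sd,
              variant_spec = variant_spec, fusion_spec = fusion_spec,
              types = types, catalog = catalog)
  # baseline gene means are part of the stated world and shared by every
  # generator call, so they are drawn once here from the config seed
  cfg$base_means <- .draw_base_means(cfg)
  structure(cfg, class = "SimConfig")
}

#' Default single-nucleotide variant specification
#' @param alt_capture per-cell probability that a mutant cell yields alt reads
#' @param ref_capture per-cell probability of ref-allele coverage
#' @return list describing the variant locus
#' @export
default_variant_spec <- function(alt_capture = 0.5, ref_capture = 0.6) {
  list(gene = "FLT3", pos = 1773L, ref = "A", alt = "T",
       alt_capture = alt_capture, ref_capture = ref_capture)
}

#' Default fusion specification (RUNX1--RUNX1T1-style junction)
#' @param capture per-cell probability that a mutant cell yields junction
#'   evidence
#' @param decoy_rate per-cell probability of a random-sequence decoy soft clip
#' @return list of class \code{FusionSpec}
#' @export
default_fusion_spec <- function(capture = 0.3, decoy_rate = 0.05) {
  structure(list(
    gene5 = "RUNX1", gene3 = "RUNX1T1",
    junction5 = 1000L, junction3 = 500L,
    # junction-flanking sequences: flank5 precedes the breakpoint on the 5'
    # partner, flank3 follows it on the 3' partner (fixed, part of the world)
    flank5 = "ACGGTCTTAGCGGATCCATGACTGGACATTGA",
    flank3 = "TTGACCGGATACCAGTTCGAGCTTAGGACCTA",
    min_clip_len = 10L, max_junction_distance = 5L, min_identity = 0.9,
    clip_len = 20L, capture = capture, decoy_rate = decoy_rate,
    background_rate = 0.3), class = "FusionSpec")
}

# Assign structured gene names: disjoint per-type marker blocks, the shared
# leukemia program, the CD69+ HSC-like program, indicator genes and
# mitochondrial genes, padded with filler genes.
.build_gene_catalog <- function(types, n_genes, n_markers,
                                leuk_size, cd69_size) {
  markers <- lapply(types, function(t)
    sprintf("%s.M%02d", t, seq_len(n_markers)))
  names(markers) <- types
  markers$HSC[1] <- "CD34"
  leuk <- sprintf("LEUK.P%02d", seq_len(leuk_size))
  leuk[1:2] <- c("CD56", "CD123")   # LAIP-style aberrant markers
  cd69_named <- c("CXCR4", "DUSP1", "ANXA1", "LGALS1", "SPARC", "JUNB")
  cd69_prog <- c(cd69_named[seq_len(min(cd69_size, length(cd69_named)))],
                 if (cd69_size > length(cd69_named))
                   sprintf("CD69P.%02d", seq_len(cd69_size - length(cd69_named))))
  mito <- c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND2", "MT-CYB")
  special <- c("CD69", "RPS4Y1")
  structured <- c(unlist(markers, use.names = FALSE), leuk, cd69_prog,
                  mito, special)
  if (anyDuplicated(structured))
    stop("configuration error: marker blocks overlap")
  if (length(structured) > n_genes)
    stop("n_genes too small for the structured gene catalog")
  filler <- sprintf("G%04d", seq_len(n_genes - length(structured)))
  list(genes = c(structured, filler), markers = markers,
       leukemia_program = leuk, cd69_program = cd69_prog, mito = mito)
}

.draw_base_means <- function(cfg) {
  set.seed(cfg$seed + 1000L)
  g <- cfg$catalog$genes
  mu <- stats::rgamma(length(g), shape = 0.4, scale = 1.2)
  names(mu) <- g
  mu[unlist(cfg$catalog$markers)] <- stats::runif(
    length(unlist(cfg$catalog$markers)), 0.5, 1.5)
  mu[cfg$catalog$leukemia_program] <-
    stats::runif(length(cfg$catalog$leukemia_program), 0.5, 1.5)
  mu[cfg$catalog$cd69_program] <-
    stats::runif(length(cfg$catalog$cd69_program), 0.5, 1.5)
  mu[cfg$catalog$mito] <- stats::runif(length(cfg$catalog$mito), 2, 4)
  mu["CD69"] <- 0       # handled by the explicit positivity scheme
  mu["RPS4Y1"] <- 0     # handled by the explicit capture scheme
  mu
}

#' The 11 leukemic cell identities
#' @return character vector of identity names
#' @export
leukemic_identities <- function() {
  c("CD69+ HSC-like", "CD69- HSC-like", "LMPP-like", "GMP-like",
    "MEP-like", "E/B/M-like", "CLP-like", "monocyte-like",
    "neutrophil-like", "cDC-like", "pDC-like")
}

# display name of a catalog type id
.type_display <- function(type) {
  map <- c(EBM = "E/B/M", MONO = "monocyte", NEUT = "neutrophil",
           CDC = "cDC", PDC = "pDC")
  ifelse(type %in% names(map), map[type], type)
}

# Core cell sampler. `spec` is a data.frame with columns: type (catalog id),
# malignant, cd69_pos, chrY_loss (all logical).
.sim_cells <- function(cfg, spec, prefix) {
  n <- nrow(spec)
  g <- cfg$catalog$genes
  lib <- stats::rlnorm(n, 0, cfg$libsize_sdlog)
  mu <- outer(lib, cfg$base_means[g])
  colnames(mu) <- g
  for (t in unique(spec$type)) {
    rows <- spec$type == t
    mu[rows, cfg$catalog$markers[[t]]] <-
      mu[rows, cfg$catalog$markers[[t]]] * cfg$marker_fold
  }
  if (any(spec$malignant)) {
    mu[spec$malignant, cfg$catalog$leukemia_program] <-
      mu[spec$malignant, cfg$catalog$leukemia_program] * cfg$leuk_program_fold
  }
  if (any(spec$cd69_pos)) {
    mu[spec$cd69_pos, cfg$catalog$cd69_program] <-
      mu[spec$cd69_pos, cfg$catalog$cd69_program] * cfg$cd69_program_fold
  }
  counts <- matrix(stats::rnbinom(n * length(g), mu = as.numeric(mu),
                                  size = cfg$nb_size),
                   nrow = n, dimnames = list(NULL, g))
  # CD69: explicit positivity so configured fractions are exact Bernoullis
  cd69_on <- spec$cd69_pos |
    (!spec$malignant & stats::runif(n) < cfg$cd69_baseline)
  counts[, "CD69"] <- ifelse(cd69_on, 1L + stats::rpois(n, 2), 0L)
  # RPS4Y1: male cells express at the capture rate unless the clone lost chrY
  if (cfg$sex == "male") {
    y_on <- stats::runif(n) < cfg$rps4y1_capture & !spec$chrY_loss
    counts[, "RPS4Y1"] <- ifelse(y_on, 1L + stats::rpois(n, 2), 0L)
  }
  rownames(counts) <- sprintf("%s-%05d", prefix, seq_len(n))
  counts
}

.append_doublets <- function(cfg, counts, meta) {
  n_dbl <- round(cfg$doublet_rate * nrow(counts))
  if (n_dbl < 1) return(list(counts = counts, meta = meta))
  i <- sample.int(nrow(counts), n_dbl, replace = TRUE)
  j <- sample.int(nrow(counts), n_dbl, replace = TRUE)
  dbl <- counts[i, , drop = FALSE] + counts[j, , drop = FALSE]
  rownames(dbl) <- sprintf("%s-DBL%04d", meta$sample_id[1], seq_len(n_dbl))
  dmeta <- meta[i, , drop = FALSE]
  dmeta$barcode <- rownames(dbl)
  dmeta$doublet_flag <- TRUE
  rownames(dmeta) <- rownames(dbl)
  list(counts = rbind(counts, dbl), meta = rbind(meta, dmeta))
}

.make_meta <- function(barcodes, sample_id, timepoint, spec) {
  data.frame(barcode = barcodes, sample_id = sample_id,
             timepoint = timepoint,
             true_type = spec$type,
             true_identity = spec$identity,
             true_malignant = spec$malignant,
             true_mutant = spec$malignant,
             doublet_flag = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate the healthy hematopoietic reference sample
#'
#' One cell block of \code{n_cells_per_type} cells per catalog type, plus
#' doublets, with ground-truth labels in the metadata.
#'
#' @param config a [sim_config()]
#' @return list with \code{cells} (a \code{CellMatrix}) and \code{truth}
#'   (per-cell data.frame)
#' @export
generate_healthy_reference <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  spec <- data.frame(
    type = rep(config$types, each = config$n_cells_per_type),
    malignant = FALSE, cd69_pos = FALSE, chrY_loss = FALSE,
    stringsAsFactors = FALSE)
  spec$identity <- .type_display(spec$type)
  counts <- .sim_cells(config, spec, "HD1")
  meta <- .make_meta(rownames(counts), "HD1", "healthy", spec)
  ad <- .append_doublets(config, counts, meta)
  cells <- CellMatrix(ad$counts, ad$meta)
  list(cells = cells, truth = ad$meta)
}

# Draw a mixed (normal + malignant) patient sample at a given burden.
.sim_patient_sample <- function(cfg, n, burden, sample_id, timepoint) {
  n_mal <- stats::rbinom(1, n, burden)
  leuk_base <- c("HSC", "LMPP", "GMP", "CLP", "MEP", "EBM",
                 "MONO", "NEUT", "CDC", "PDC")
  wts <- c(HSC = 0.25, LMPP = 0.15, GMP = 0.15, CLP = 0.05, MEP = 0.10,
           EBM = 0.05, MONO = 0.10, NEUT = 0.05, CDC = 0.05, PDC = 0.05)
  mal_type <- sample(leuk_base, n_mal, replace = TRUE, prob = wts[leuk_base])
  norm_type <- sample(cfg$types, n - n_mal, replace = TRUE)
  spec <- data.frame(
    type = c(mal_type, norm_type),
    malignant = rep(c(TRUE, FALSE), c(n_mal, n - n_mal)),
    stringsAsFactors = FALSE)
  spec$cd69_pos <- spec$malignant & spec$type == "HSC" &
    stats::runif(n) < cfg$cd69_hsc_fraction
  spec$chrY_loss <- spec$malignant & cfg$chrY_loss
  spec$identity <- ifelse(
    spec$malignant,
    ifelse(spec$type == "HSC",
           ifelse(spec$cd69_pos, "CD69+ HSC-like", "CD69- HSC-like"),
           paste0(.type_display(spec$type), "-like")),
    .type_display(spec$type))
  ord <- sample.int(nrow(spec))      # shuffle so order carries no signal
  spec <- spec[ord, , drop = FALSE]
  counts <- .sim_cells(cfg, spec, sample_id)
  meta <- .make_meta(rownames(counts), sample_id, timepoint, spec)
  ad <- .append_doublets(cfg, counts, meta)
  CellMatrix(ad$counts, ad$meta)
}

#' Generate a paired pre-/post-chemotherapy patient sample
#'
#' Malignant cells combine their base-type program with the shared leukemia
#' program; malignant HSC-like cells are CD69-positive with probability
#' \code{cd69_hsc_fraction}. The post-therapy sample retains malignant cells
#' at \code{tumor_burden_post}.
#'
#' @param config a [sim_config()]
#' @param patient_id sample-name prefix
#' @return list with \code{pre}, \code{post} (\code{CellMatrix}) and
#'   \code{truth} (per-sample true leukemic fractions)
#' @export
generate_patient_pair <- function(config, patient_id = "P1") {
  stopifnot(inherits(config, "SimConfig"))
  if (config$tumor_burden_pre <= config$tumor_burden_post)
    stop("tumor_burden_pre must exceed tumor_burden_post")
  set.seed(config$seed + 2L)
  pre <- .sim_patient_sample(config, config$n_cells_per_sample,
                             config$tumor_burden_pre,
                             paste0(patient_id, "pre"), "pre")
  post <- .sim_patient_sample(config, config$n_cells_per_sample,
                              config$tumor_burden_post,
                              paste0(patient_id, "post"), "post")
  truth <- data.frame(
    sample_id = c(paste0(patient_id, "pre"), paste0(patient_id, "post")),
    timepoint = c("pre", "post"),
    leukemic_fraction = c(mean(pre$cell_meta$true_malignant),
                          mean(post$cell_meta$true_malignant)))
  list(pre = pre, post = post, truth = truth)
}

#' Generate a pure leukemic reference across the 11 identities
#'
#' Used for signature-matrix construction and pseudo-bulk simulation:
#' \code{n_cells_per_identity} malignant cells for each of the 11 leukemic
#' identities (the HSC-like identity split into CD69+ and CD69-).
#'
#' @param config a [sim_config()]
#' @param n_cells_per_identity cells per identity (default 150)
#' @return list with \code{cells} (a normalized \code{CellMatrix}) and
#'   \code{identities} (per-cell identity labels)
#' @export
generate_leukemic_reference <- function(config, n_cells_per_identity = 150L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 3L)
  ids <- leukemic_identities()
  base <- c("HSC", "HSC", "LMPP", "GMP", "MEP", "EBM", "CLP",
            "MONO", "NEUT", "CDC", "PDC")
  spec <- data.frame(
    type = rep(base, each = n_cells_per_identity),
    identity = rep(ids, each = n_cells_per_identity),
    malignant = TRUE, chrY_loss = config$chrY_loss,
    stringsAsFactors = FALSE)
  spec$cd69_pos <- spec$identity == "CD69+ HSC-like"
  counts <- .sim_cells(config, spec, "LREF")
  meta <- .make_meta(rownames(counts), "LREF", "pre", spec)
  cells <- normalize_depth(CellMatrix(counts, meta))
  list(cells = cells, identities = meta$true_identity)
}

.random_umi <- function(n, len = 8L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate barcode/UMI-tagged read evidence for variant and fusion calling
#'
#' Mutant-flagged cells receive alt-allele reads and fusion-junction evidence
#' (soft-clipped reads whose clip matches the partner's junction flank, and
#' UMI pairs split across partners) at the configured capture rates;
#' wild-type cells receive only reference and non-junction reads. Decoy soft
#' clips of random sequence are emitted at \code{decoy_rate}.
#'
#' @param config a [sim_config()]
#' @param cells a \code{CellMatrix} whose metadata carries \code{true_mutant}
#' @return data.frame of read records: \code{read_id}, \code{barcode},
#'   \code{umi}, \code{mapped_gene}, \code{mapped_pos} (0-based coordinate of
#'   the clip attachment / variant base), \code{clip_side}, \code{clip_seq},
#'   \code{allele_at_variant}, and a construction flag \code{true_junction}
#' @export
generate_read_evidence <- function(config, cells) {
  stopifnot(inherits(config, "SimConfig"), inherits(cells, "CellMatrix"))
  set.seed(config$seed + 4L)
  vs <- config$variant_spec
  fs <- config$fusion_spec
  if (nchar(fs$flank5) < fs$min_clip_len || nchar(fs$flank3) < fs$min_clip_len)
    stop("fusion flank shorter than configured clip length")
  meta <- cells$cell_meta
  recs <- list()
  add <- function(barcode, gene, pos, clip_side = "none", clip_seq = "",
                  allele = "none", umi = NULL, true_junction = FALSE) {
    data.frame(barcode = barcode, umi = if (is.null(umi)) .random_umi(1) else umi,
               mapped_gene = gene, mapped_pos = as.integer(pos),
               clip_side = clip_side, clip_seq = clip_seq,
               allele_at_variant = allele, true_junction = true_junction,
               stringsAsFactors = FALSE)
  }
  for (ci in seq_len(nrow(meta))) {
    bc <- meta$barcode[ci]
    mutant <- isTRUE(meta$true_mutant[ci]) && !isTRUE(meta$doublet_flag[ci])
    # SNV evidence
    if (mutant && stats::runif(1) < vs$alt_capture) {
      for (k in seq_len(1L + stats::rpois(1, 0.5)))
        recs[[length(recs) + 1L]] <- add(bc, vs$gene, vs$pos, allele = "alt")
    }
    if (stats::runif(1) < vs$ref_capture && !mutant) {
      for (k in seq_len(1L + stats::rpois(1, 0.5)))
        recs[[length(recs) + 1L]] <- add(bc, vs$gene, vs$pos, allele = "ref")
    }
    # fusion evidence in mutant cells
    if (mutant && stats::runif(1) < fs$capture) {
      mode <- sample(c("clip5", "clip3", "split_umi"), 1)
      if (mode == "clip5") {
        clip <- substr(fs$flank3, 1, fs$clip_len)
        recs[[length(recs) + 1L]] <- add(
          bc, fs$gene5, fs$junction5 + sample(-1:1, 1),
          clip_side = "right", clip_seq = clip, true_junction = TRUE)
      } else if (mode == "clip3") {
        f5 <- fs$flank5
        clip <- substr(f5, nchar(f5) - fs$clip_len + 1L, nchar(f5))
        recs[[length(recs) + 1L]] <- add(
          bc, fs$gene3, fs$junction3 + sample(-1:1, 1),
          clip_side = "left", clip_seq = clip, true_junction = TRUE)
      } else {
        umi <- .random_umi(1)
        recs[[length(recs) + 1L]] <- add(bc, fs$gene5,
                                         fs$junction5 - 200L, umi = umi)
        recs[[length(recs) + 1L]] <- add(bc, fs$gene3,
                                         fs$junction3 + 200L, umi = umi)
      }
    }
    # background non-junction reads on the partners, distinct UMIs
    if (stats::runif(1) < fs$background_rate)
      recs[[length(recs) + 1L]] <- add(bc, fs$gene5, fs$junction5 - 300L)
    if (stats::runif(1) < fs$background_rate)
      recs[[length(recs) + 1L]] <- add(bc, fs$gene3, fs$junction3 + 300L)
    # decoy soft clips of random sequence, near the junction
    if (stats::runif(1) < fs$decoy_rate) {
      recs[[length(recs) + 1L]] <- add(
        bc, fs$gene5, fs$junction5 + sample(-2:2, 1),
        clip_side = "right", clip_seq = .random_seq(fs$clip_len))
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(barcode = character(), umi = character(),
               mapped_gene = character(), mapped_pos = integer(),
               clip_side = character(), clip_seq = character(),
               allele_at_variant = character(), true_junction = logical(),
               stringsAsFactors = FALSE)
  out <- cbind(read_id = sprintf("r%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a bulk expression cohort with clinical outcomes
#'
#' Each patient's bulk profile is a proportion-weighted mixture of the
#' identity mean linear-scale profiles (from \code{signature_source}), with
#' lognormal noise, reported as log2(x + 1). MRD positivity, relapse and
#' OS/EFS times are simulated with log-odds / log-hazard increasing in the
#' true CD69+ HSC-like fraction via \code{hazard_link}; blast percentage and
#' FAB labels are attached for cohort-filter testing.
#'
#' @param config a [sim_config()]
#' @param signature_source output of [generate_leukemic_reference()] (or any
#'   list with a normalized \code{cells} CellMatrix and \code{identities})
#' @return list with \code{bulk} (genes x patients matrix, log2 scale),
#'   \code{patients} (clinical data.frame incl. true proportions in
#'   \code{attr(,"true_proportions")}), \code{truth} (patients x identities
#'   true proportion matrix)
#' @export
generate_bulk_cohort <- function(config, signature_source) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 5L)
  cells <- signature_source$cells
  ids <- signature_source$identities
  if (is.null(cells$normalized)) cells <- normalize_depth(cells)
  lin <- expm1(as.matrix(cells$normalized))
  prof <- sapply(leukemic_identities(), function(t)
    colMeans(lin[ids == t, , drop = FALSE]))
  n <- config$cohort_size
  if (n < 2) stop("cohort_size must be at least 2")
  alpha <- rep(config$dirichlet_conc, length(leukemic_identities()))
  names(alpha) <- leukemic_identities()
  alpha["CD69+ HSC-like"] <- config$cd69_dirichlet_conc
  props <- .rdirichlet(n, alpha)
  colnames(props) <- leukemic_identities()
  rownames(props) <- sprintf("PT%03d", seq_len(n))
  mix <- prof %*% t(props)
  noise <- matrix(stats::rlnorm(length(mix), 0, config$bulk_noise_sd),
                  nrow = nrow(mix))
  bulk <- log2(mix * noise + 1)
  colnames(bulk) <- rownames(props)
  cd69 <- props[, "CD69+ HSC-like"]
  link <- config$hazard_link
  mrd_pos <- stats::runif(n) < stats::plogis(stats::qlogis(0.3) +
                                               link * (cd69 - 0.15))
  mrd_pct <- ifelse(mrd_pos, stats::runif(n, 0.1, 5), stats::runif(n, 0, 0.09))
  relapse <- stats::runif(n) < stats::plogis(stats::qlogis(0.25) +
                                               link * (cd69 - 0.15))
  os_lat <- stats::rexp(n, rate = 0.25 * exp(link * (cd69 - 0.15)))
  efs_lat <- stats::rexp(n, rate = 0.40 * exp(link * (cd69 - 0.15)))
  cens <- stats::runif(n, 1, 6)
  patients <- data.frame(
    patient_id = rownames(props),
    blast_pct = stats::runif(n, 40, 95),
    FAB = sample(c("M0", "M1", "M2", "M3", "M4", "M5"), n, replace = TRUE,
                 prob = c(0.08, 0.22, 0.25, 0.08, 0.22, 0.15)),
    MRD_pct = round(mrd_pct, 3),
    relapse = relapse,
    os_time = pmin(os_lat, cens), os_event = os_lat <= cens,
    efs_time = pmin(efs_lat, cens), efs_event = efs_lat <= cens,
    age = round(stats::runif(n, 1, 17), 1),
    wbc = round(stats::rlnorm(n, log(20), 0.8), 1),
    sct = stats::runif(n) < 0.25,
    cd69_hsc_fraction = cd69,
    stringsAsFactors = FALSE)
  attr(patients, "true_proportions") <- props
  list(bulk = bulk, patients = patients, truth = props)
}
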