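mk_read <- function(barcode, umi, gene = "FLT3", pos = 1773,
                    clip_side = "none", clip_seq = "", allele = "none") {
  data.frame(read_id = "r", barcode = barcode, umi = umi,
             mapped_gene = gene, mapped_pos = pos, clip_side = clip_side,
             clip_seq = clip_seq, allele_at_variant = allele,
             stringsAsFactors = FALSE)
}

test_that("assign_snv_genotype deduplicates UMIs and calls alleles", {
  reads <- rbind(
    mk_read("c1", "U1", allele = "alt"),
    mk_read("c1", "U2", allele = "ref"),
    mk_read("c1", "U3", allele = "ref"),
    mk_read("c1", "U4", allele = "ref"),
    mk_read("c2", "U1", allele = "ref"),
    mk_read("c3", "U1", allele = "ref"),   # conflicting alleles, same UMI
    mk_read("c3", "U1", allele = "alt"))
  gt <- assign_snv_genotype(reads, c("c1", "c2", "c3", "c4"))
  expect_equal(gt$genotype, c("mutant", "wildtype", "unknown", "unknown"))
  expect_equal(gt$alt_umis[1], 1L)
  expect_equal(gt$ref_umis[1], 3L)
  # conflicting UMI fully discarded
  expect_equal(gt$ref_umis[3] + gt$alt_umis[3], 0L)
})

test_that("SNV genotypes equal a brute-force per-cell recount", {
  cfg <- fix_config()
  pp <- fix_patient()
  reads <- generate_read_evidence(cfg, pp$pre)
  bcs <- cell_barcodes(pp$pre)
  gt <- assign_snv_genotype(reads, bcs, "FLT3")
  # independent oracle: nested loops over raw records
  oracle <- sapply(bcs, function(bc) {
    r <- reads[reads$barcode == bc & reads$allele_at_variant != "none", ]
    umis <- unique(r$umi)
    al <- vapply(umis, function(u) {
      a <- unique(r$allele_at_variant[r$umi == u])
      if (length(a) > 1) NA_character_ else a
    }, "")
    al <- al[!is.na(al)]
    if (sum(al == "alt") >= 1) "mutant"
    else if (sum(al == "ref") >= 1) "wildtype" else "unknown"
  })
  expect_equal(gt$genotype, unname(oracle))
  # mutant calls only in truly mutant (non-doublet) cells
  meta <- pp$pre$cell_meta
  expect_true(all(meta$true_mutant[gt$genotype == "mutant"]))
})

test_that("fusion rule 1 fires on junction-proximal matching soft clips", {
  fs <- default_fusion_spec()
  flank3_clip <- substr(fs$flank3, 1, 20)
  reads <- rbind(
    mk_read("c1", "U1", gene = fs$gene5, pos = fs$junction5,
            clip_side = "right", clip_seq = flank3_clip),
    # too far from the junction
    mk_read("c2", "U1", gene = fs$gene5, pos = fs$junction5 + 50,
            clip_side = "right", clip_seq = flank3_clip),
    # clip does not match the partner flank
    mk_read("c3", "U1", gene = fs$gene5, pos = fs$junction5,
            clip_side = "right",
            clip_seq = paste(rep("A", 20), collapse = "")))
  gt <- detect_fusion_cells(reads, fs, c("c1", "c2", "c3"))
  expect_equal(gt$genotype, c("mutant", "unknown", "unknown"))
  expect_equal(gt$junction_reads[1], 1L)
})

test_that("fusion rule 2 fires on split UMIs; neither rule alone on distinct UMIs", {
  fs <- default_fusion_spec()
  reads <- rbind(
    mk_read("c1", "AACC", gene = fs$gene5, pos = 100),
    mk_read("c1", "AACC", gene = fs$gene3, pos = 900),
    mk_read("c2", "AAAA", gene = fs$gene5, pos = 100),
    mk_read("c2", "TTTT", gene = fs$gene3, pos = 900))
  gt <- detect_fusion_cells(reads, fs, c("c1", "c2"))
  expect_equal(gt$genotype, c("mutant", "unknown"))
  expect_equal(gt$split_umi_pairs[1], 1L)
  # necessary condition: rule-2 calls lie inside cells with reads on both
  # partners
  with_both <- intersect(reads$barcode[reads$mapped_gene == fs$gene5],
                         reads$barcode[reads$mapped_gene == fs$gene3])
  expect_true(all(gt$barcode[gt$split_umi_pairs > 0] %in% with_both))
})

test_that("no false-positive fusion calls on decoy-only data, 10 seeds", {
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_cells_per_type = 10,
                      n_cells_per_sample = 300,
                      fusion_spec = default_fusion_spec(capture = 0,
                                                        decoy_rate = 0.2))
    vs <- cfg$variant_spec; vs$alt_capture <- 0
    cfg$variant_spec <- vs
    pp <- generate_patient_pair(cfg)
    reads <- generate_read_evidence(cfg, pp$pre)
    expect_gt(sum(nzchar(reads$clip_seq)), 0)
    gt <- detect_fusion_cells(reads, cfg$fusion_spec,
                              cell_barcodes(pp$pre))
    expect_equal(sum(gt$genotype == "mutant"), 0)
    # capture 0 also means no alt evidence anywhere
    snv <- assign_snv_genotype(reads, cell_barcodes(pp$pre))
    expect_equal(sum(snv$alt_umis), 0L)
  }
})

test_that("constructed junction clips realign exactly to the partner flank", {
  cfg <- fix_config()
  pp <- fix_patient()
  reads <- generate_read_evidence(cfg, pp$pre)
  fs <- cfg$fusion_spec
  tj <- reads[reads$true_junction, ]
  expect_gt(nrow(tj), 0)
  for (i in seq_len(nrow(tj))) {
    flank <- if (tj$mapped_gene[i] == fs$gene5) fs$flank3 else fs$flank5
    expect_true(grepl(tj$clip_seq[i], flank, fixed = TRUE))
  }
})

test_that("malformed clips are skipped with a warning", {
  fs <- default_fusion_spec()
  reads <- mk_read("c1", "U1", gene = fs$gene5, pos = fs$junction5,
                   clip_side = "right", clip_seq = "ACGTXX??ACGTACGTACGT")
  expect_warning(gt <- detect_fusion_cells(reads, fs, "c1"), "malformed")
  expect_equal(gt$genotype, "unknown")
})

test_that("chrY-loss detection tracks the generative capture rate", {
  cfg <- sim_config(seed = 6, n_cells_per_type = 60, chrY_loss = TRUE,
                    n_cells_per_sample = 1000, rps4y1_capture = 0.8)
  pp <- generate_patient_pair(cfg)
  m <- normalize_depth(pp$pre)
  meta <- m$cell_meta
  normal <- which(!meta$true_malignant & !meta$doublet_flag)
  res_n <- detect_chrY_loss(m, normal)
  expect_lt(abs(res_n$fraction_expressing - 0.8), 0.05)
  expect_false(res_n$loss_consistent)
  malignant <- which(meta$true_malignant & !meta$doublet_flag)
  res_m <- detect_chrY_loss(m, malignant)
  expect_equal(res_m$fraction_expressing, 0)
  expect_true(res_m$loss_consistent)
  # female sample: no expression regardless of malignancy
  cfgf <- sim_config(seed = 6, n_cells_per_type = 20, sex = "female",
                     n_cells_per_sample = 200)
  hf <- generate_healthy_reference(cfgf)
  mf <- normalize_depth(hf$cells)
  expect_equal(detect_chrY_loss(mf, seq_len(nrow(mf$counts)))$fraction_expressing, 0)
  expect_error(detect_chrY_loss(m, normal, indicator_gene = "NOPE"),
               "absent")
})

test_that("LAIP co-expression equals the marker-positive intersection", {
  counts <- rbind(c1 = c(3, 2, 5), c2 = c(3, 0, 5), c3 = c(0, 0, 5))
  colnames(counts) <- c("CD34", "CD56", "filler")
  m <- normalize_depth(CellMatrix(counts))
  hits <- detect_laip_cells(m, c("CD34", "CD56"))
  expect_equal(hits, "c1")
  # set-intersection oracle
  pos1 <- cell_barcodes(m)[as.numeric(m$normalized[, "CD34"]) > 0]
  pos2 <- cell_barcodes(m)[as.numeric(m$normalized[, "CD56"]) > 0]
  expect_equal(hits, intersect(pos1, pos2))
  expect_error(detect_laip_cells(m, character()), "empty")
  expect_error(detect_laip_cells(m, c("CD34", "GONE")), "absent")
})

test_that("concordance is the leukemic fraction of evidence cells", {
  call <- structure(list(cell_call = c("leukemic", "leukemic", "normal",
                                       "normal")),
                    class = "MalignancyCall")
  bcs <- c("a", "b", "c", "d")
  expect_equal(concordance(c("a", "b"), call, bcs), 1.0)
  expect_equal(concordance(c("a", "c"), call, bcs), 0.5)
  expect_error(concordance(character(), call, bcs), "empty evidence")
})

test_that("SAM records parse soft clips, tags and attachment coordinates", {
  sam <- c(
    "@HD\tVN:1.6",
    paste("r1", "0", "RUNX1", "981", "60", "20M20S", "*", "0", "0",
          paste0(paste(rep("A", 20), collapse = ""), "TTGACCGGATACCAGTTCGA"),
          "*", "CB:Z:c1", "UB:Z:U1", sep = "\t"),
    paste("r2", "0", "FLT3", "1774", "60", "30M", "*", "0", "0",
          paste(rep("C", 30), collapse = ""),
          "*", "CB:Z:c2", "UB:Z:U2", "AL:Z:alt", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  recs <- read_sam_records(path)
  expect_equal(recs$clip_side, c("right", "none"))
  expect_equal(recs$mapped_pos[1], 980 + 20)   # 0-based attachment
  expect_equal(recs$clip_seq[1], "TTGACCGGATACCAGTTCGA")
  expect_equal(recs$barcode, c("c1", "c2"))
  expect_equal(recs$allele_at_variant, c("none", "alt"))
  # the parsed soft clip drives rule 1 through the standard caller
  gt <- detect_fusion_cells(recs, default_fusion_spec(), c("c1", "c2"))
  expect_equal(gt$genotype[gt$barcode == "c1"], "mutant")
})
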