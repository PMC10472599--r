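#' Assign single-cell SNV genotypes from allele-tagged reads
#'
#' Reads covering the variant carry \code{allele_at_variant} in
#' \{ref, alt\}. Supporting evidence is deduplicated to distinct UMIs per
#' cell; a UMI whose reads disagree on the allele is discarded. A cell is
#' mutant with >= 1 alt UMI, wildtype with 0 alt and >= 1 ref UMI, unknown
#' otherwise.
#'
#' @param reads read-record data.frame (see [generate_read_evidence()])
#' @param cell_barcodes barcodes defining the cell universe; reads with other
#'   barcodes are ignored
#' @param variant_gene restrict to reads mapped to this gene (default: any
#'   read with a non-"none" allele)
#' @return data.frame per cell: \code{barcode}, \code{ref_umis},
#'   \code{alt_umis}, \code{genotype} in \{mutant, wildtype, unknown\}
#' @export
assign_snv_genotype <- function(reads, cell_barcodes, variant_gene = NULL) {
  r <- reads[reads$allele_at_variant %in% c("ref", "alt"), , drop = FALSE]
  if (!is.null(variant_gene))
    r <- r[r$mapped_gene == variant_gene, , drop = FALSE]
  r <- r[r$barcode %in% cell_barcodes, , drop = FALSE]
  counts <- data.frame(barcode = cell_barcodes, ref_umis = 0L, alt_umis = 0L,
                       stringsAsFactors = FALSE)
  if (nrow(r)) {
    key <- paste(r$barcode, r$umi, sep = "\r")
    allele_by_umi <- tapply(r$allele_at_variant, key, function(a)
      if (length(unique(a)) > 1) NA_character_ else a[1])
    keep <- !is.na(allele_by_umi)
    bc <- vapply(strsplit(names(allele_by_umi)[keep], "\r", fixed = TRUE),
                 `[`, "", 1)
    al <- allele_by_umi[keep]
    tab <- table(factor(bc, levels = cell_barcodes),
                 factor(al, levels = c("ref", "alt")))
    counts$ref_umis <- as.integer(tab[, "ref"])
    counts$alt_umis <- as.integer(tab[, "alt"])
  }
  counts$genotype <- ifelse(counts$alt_umis >= 1, "mutant",
                            ifelse(counts$ref_umis >= 1, "wildtype",
                                   "unknown"))
  counts
}

# Best ungapped sliding-window identity of a clip against a flank: the clip
# is slid along the flank and the identity of each overlap of length >=
# min_len is computed; returns the maximum.
.clip_identity <- function(clip, flank, min_len) {
  clip <- toupper(clip); flank <- toupper(flank)
  lc <- nchar(clip); lf <- nchar(flank)
  if (lc < min_len || lf < min_len) return(0)
  cs <- strsplit(clip, "")[[1]]
  fsq <- strsplit(flank, "")[[1]]
  best <- 0
  for (off in (-(lc - min_len)):(lf - min_len)) {
    i1 <- max(1L, 1L - off); i2 <- min(lc, lf - off)
    len <- i2 - i1 + 1L
    if (len < min_len) next
    ident <- sum(cs[i1:i2] == fsq[(i1:i2) + off]) / len
    best <- max(best, ident)
  }
  best
}

#' Detect fusion-bearing cells from soft clips and split UMIs
#'
#' A cell is called mutant if either rule fires. Rule 1: a read mapped to
#' one partner whose clip attachment lies within \code{max_junction_distance}
#' of the junction, with a clip of at least \code{min_clip_len} that aligns
#' (ungapped sliding window) to the other partner's junction flank at
#' identity >= \code{min_identity}. Rule 2: two reads sharing (barcode, UMI)
#' mapped one to each partner. Absence of evidence is reported as unknown,
#' never wildtype.
#'
#' @param reads read-record data.frame restricted by barcode to the cell
#'   universe internally
#' @param spec a \code{FusionSpec} (see [default_fusion_spec()])
#' @param cell_barcodes barcodes defining the cell universe
#' @return data.frame per cell: \code{barcode}, \code{junction_reads},
#'   \code{split_umi_pairs}, \code{genotype} in \{mutant, unknown\}
#' @export
detect_fusion_cells <- function(reads, spec, cell_barcodes) {
  r <- reads[reads$mapped_gene %in% c(spec$gene5, spec$gene3) &
               reads$barcode %in% cell_barcodes, , drop = FALSE]
  bad <- nzchar(r$clip_seq) & grepl("[^ACGTNacgtn]", r$clip_seq)
  if (any(bad)) {
    warning(sum(bad), " read(s) with malformed clip sequence skipped")
    r <- r[!bad, , drop = FALSE]
  }
  junction_reads <- setNames(integer(length(cell_barcodes)), cell_barcodes)
  split_pairs <- junction_reads
  clipped <- which(r$clip_side != "none" &
                     nchar(r$clip_seq) >= spec$min_clip_len)
  for (i in clipped) {
    jn <- if (r$mapped_gene[i] == spec$gene5) spec$junction5 else
      spec$junction3
    if (abs(r$mapped_pos[i] - jn) > spec$max_junction_distance) next
    flank <- if (r$mapped_gene[i] == spec$gene5) spec$flank3 else spec$flank5
    if (.clip_identity(r$clip_seq[i], flank, spec$min_clip_len) >=
        spec$min_identity) {
      junction_reads[r$barcode[i]] <- junction_reads[r$barcode[i]] + 1L
    }
  }
  key <- paste(r$barcode, r$umi, sep = "\r")
  genes_by_umi <- tapply(r$mapped_gene, key, function(g) length(unique(g)))
  both <- names(genes_by_umi)[genes_by_umi == 2]
  if (length(both)) {
    bc <- vapply(strsplit(both, "\r", fixed = TRUE), `[`, "", 1)
    tab <- table(factor(bc, levels = cell_barcodes))
    split_pairs <- split_pairs + as.integer(tab)
  }
  data.frame(barcode = cell_barcodes,
             junction_reads = as.integer(junction_reads),
             split_umi_pairs = as.integer(split_pairs),
             genotype = ifelse(junction_reads + split_pairs > 0,
                               "mutant", "unknown"),
             stringsAsFactors = FALSE)
}

#' Chromosome-Y loss indicator from a single pervasive chrY gene
#'
#' @param m a normalized \code{CellMatrix}
#' @param population cell indices (or barcodes) to summarize
#' @param indicator_gene chrY indicator (default "RPS4Y1")
#' @param loss_cutoff population expressing-fraction below which the
#'   population is loss-consistent (default 0.05)
#' @return list: \code{expressed} (per-population-cell logical),
#'   \code{fraction_expressing}, \code{loss_consistent}
#' @export
detect_chrY_loss <- function(m, population, indicator_gene = "RPS4Y1",
                             loss_cutoff = 0.05) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  if (!indicator_gene %in% gene_names(m))
    stop("indicator gene absent: ", indicator_gene)
  if (is.character(population)) population <- match(population,
                                                    cell_barcodes(m))
  v <- as.numeric(m$normalized[population, indicator_gene])
  expressed <- v > 0
  frac <- mean(expressed)
  list(expressed = expressed, fraction_expressing = frac,
       loss_consistent = frac < loss_cutoff)
}

#' Cells co-expressing every marker of a leukemia-associated immunophenotype
#'
#' @param m a normalized \code{CellMatrix}
#' @param markers gene set; every marker must be present
#' @return character vector of barcodes where every marker is > 0
#' @export
detect_laip_cells <- function(m, markers) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.null(m$normalized)) stop("normalized layer required")
  if (!length(markers)) stop("empty marker set")
  missing <- setdiff(markers, gene_names(m))
  if (length(missing))
    stop("marker gene(s) absent: ", paste(missing, collapse = ", "))
  x <- m$normalized[, markers, drop = FALSE]
  cell_barcodes(m)[Matrix::rowSums(x > 0) == length(markers)]
}

#' Concordance of evidence cells with the transcriptomic leukemic call
#'
#' @param evidence_barcodes nonempty set of evidence-positive cell barcodes
#' @param call a \code{MalignancyCall}
#' @param barcodes barcodes aligned with the call's cells
#' @return fraction of evidence cells called leukemic
#' @export
concordance <- function(evidence_barcodes, call, barcodes) {
  stopifnot(inherits(call, "MalignancyCall"),
            length(barcodes) == length(call$cell_call))
  evidence_barcodes <- intersect(evidence_barcodes, barcodes)
  if (!length(evidence_barcodes))
    stop("empty evidence set; concordance undefined")
  leuk <- barcodes[call$cell_call == "leukemic"]
  length(intersect(evidence_barcodes, leuk)) / length(evidence_barcodes)
}

#' Read the simplified barcoded-read TSV dialect
#'
#' Columns: read_id, barcode, umi, mapped_gene, mapped_pos, clip_side,
#' clip_seq, allele_at_variant.
#'
#' @param path TSV path
#' @return read-record data.frame
#' @export
read_reads_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character") -> r
  r$mapped_pos <- as.integer(r$mapped_pos)
  r
}

#' Write read records to the simplified TSV dialect
#' @param reads read-record data.frame
#' @param path output path
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a SAM text file into read records
#'
#' Minimal parser for validation inputs: takes barcode and UMI from CB:Z: /
#' UB:Z: tags, derives clip side/sequence from a single terminal
#' soft clip in the CIGAR (clip attachment coordinate: the 0-based reference
#' position adjacent to the clip), and reads an optional AL:Z:ref|alt allele
#' tag.
#'
#' @param path SAM file (text, with or without header lines)
#' @return read-record data.frame
#' @export
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    tags <- f[-(1:11)]
    tagval <- function(pfx) {
      hit <- tags[startsWith(tags, pfx)]
      if (length(hit)) sub(pfx, "", hit[1]) else ""
    }
    cigar <- f[6]; pos0 <- as.integer(f[4]) - 1L; seq <- f[10]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typ <- sub("[0-9]+", "", ops)
    ref_len <- sum(lens[typ %in% c("M", "D", "N", "=", "X")])
    clip_side <- "none"; clip_seq <- ""; attach <- pos0
    if (length(typ) && typ[1] == "S") {
      clip_side <- "left"
      clip_seq <- substr(seq, 1, lens[1])
      attach <- pos0
    } else if (length(typ) && typ[length(typ)] == "S") {
      clip_side <- "right"
      clip_seq <- substr(seq, nchar(seq) - lens[length(typ)] + 1L, nchar(seq))
      attach <- pos0 + ref_len
    }
    data.frame(read_id = f[1], barcode = tagval("CB:Z:"),
               umi = tagval("UB:Z:"), mapped_gene = f[3],
               mapped_pos = attach, clip_side = clip_side,
               clip_seq = clip_seq,
               allele_at_variant = ifelse(nzchar(tagval("AL:Z:")),
                                          tagval("AL:Z:"), "none"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
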