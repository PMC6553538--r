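#' Read a FASTA file into named uppercase sequences
#'
#' Sequences are case-folded to uppercase and validated against the alphabet
#' \{A,C,G,T,N\}. Every downstream module works on this representation, so all
#' alphabet checking happens once at the I/O boundary.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (order preserved).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (any(nm == "")) stop("FASTA record with empty name")
  if (anyDuplicated(nm)) stop("duplicate sequence names in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("invalid character in sequence(s): ",
                     paste(nm[bad], collapse = ", "))
  if (any(nchar(seqs) < 1)) stop("empty sequence in FASTA")
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

paf_cols <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "blocklen", "mapq")

#' Read a PAF pairwise-alignment file
#'
#' PAF is the 12+ column tab-separated format emitted by minimap2 and by the
#' package's own micro-aligner. Coordinates are 0-based half-open; on the
#' negative strand, query coordinates refer to the original query strand
#' (minimap2 dialect). Coordinates are validated against the record invariants.
#'
#' @param path path to a PAF file.
#' @return data frame of alignment records with columns
#'   `qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
#'   nmatch, blocklen, mapq`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) stop("PAF line with fewer than 12 columns (line ",
                         which(nf < 12)[1], ")")
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  aln <- data.frame(
    qname = mat[, 1], qlen = as.integer(mat[, 2]),
    qstart = as.integer(mat[, 3]), qend = as.integer(mat[, 4]),
    strand = mat[, 5],
    tname = mat[, 6], tlen = as.integer(mat[, 7]),
    tstart = as.integer(mat[, 8]), tend = as.integer(mat[, 9]),
    nmatch = as.integer(mat[, 10]), blocklen = as.integer(mat[, 11]),
    mapq = as.integer(mat[, 12]),
    stringsAsFactors = FALSE
  )
  validate_paf(aln)
  aln
}

empty_paf <- function() {
  data.frame(qname = character(), qlen = integer(), qstart = integer(),
             qend = integer(), strand = character(), tname = character(),
             tlen = integer(), tstart = integer(), tend = integer(),
             nmatch = integer(), blocklen = integer(), mapq = integer(),
             stringsAsFactors = FALSE)
}

validate_paf <- function(aln) {
  check_that(all(aln$strand %in% c("+", "-")), "unknown strand in alignment")
  check_that(all(aln$qstart >= 0 & aln$qstart < aln$qend & aln$qend <= aln$qlen),
             "invalid query coordinates (need 0 <= qstart < qend <= qlen)")
  check_that(all(aln$tstart >= 0 & aln$tstart < aln$tend & aln$tend <= aln$tlen),
             "invalid target coordinates (need 0 <= tstart < tend <= tlen)")
  check_that(all(aln$nmatch <= aln$blocklen), "nmatch exceeds block length")
  invisible(aln)
}

#' Write alignment records as PAF
#'
#' @param aln alignment data frame (see [read_paf()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  validate_paf(aln)
  lines <- do.call(paste, c(aln[paf_cols], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-sample VCF, keeping only GT
#'
#' Parses a VCF 4.x file via vcfR, normalizes per-sample genotype calls to
#' `hom-ref`, `het`, `hom-alt` or `missing`, and splits multi-allelic sites
#' into one biallelic record per ALT allele (a genotype carrying neither the
#' reference nor the focal ALT allele is reported relative to the focal allele:
#' two copies of it -> hom-alt, one -> het, zero -> hom-ref).
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @return a `multi_vcf` list: `sites` (data.frame chrom, pos (1-based), ref,
#'   alt), `gt` (character matrix, sites x samples), `samples`.
#' @export
read_vcf_multisample <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!"gt" %in% slotNames(v) || ncol(v@gt) < 2)
    stop("VCF has no sample genotype columns")
  fmt <- v@gt[, 1]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) stop("missing GT field in FORMAT")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw)))
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt_raw)
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  out_sites <- list(); out_gt <- list()
  for (i in seq_along(pos)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      if (alts[ai] == ref[i]) stop("ALT equals REF at ", chrom[i], ":", pos[i])
      out_sites[[length(out_sites) + 1L]] <-
        data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                   alt = alts[ai], stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1L]] <- normalize_gt(gt_raw[i, ], ai)
    }
  }
  sites <- do.call(rbind, out_sites)
  gt <- do.call(rbind, out_gt)
  colnames(gt) <- samples
  rownames(gt) <- NULL
  structure(list(sites = sites, gt = gt, samples = samples),
            class = "multi_vcf")
}

# Normalize diploid GT strings against ALT allele index `allele`.
normalize_gt <- function(g, allele) {
  g <- ifelse(is.na(g), ".", g)
  parts <- strsplit(g, "[/|]")
  vapply(parts, function(p) {
    if (any(p == ".") || length(p) == 0) return("missing")
    a <- suppressWarnings(as.integer(p))
    if (any(is.na(a))) return("missing")
    nalt <- sum(a == allele)
    if (nalt == length(a)) "hom-alt" else if (nalt > 0) "het" else "hom-ref"
  }, character(1))
}

#' Write a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT. Genotypes are encoded
#' `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param vcf a `multi_vcf` object (see [read_vcf_multisample()]).
#' @param path output path.
#' @param source_tag value for the `##source=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf_multisample <- function(vcf, path, source_tag = "asmcurate") {
  code <- c("hom-ref" = "0/0", "het" = "0/1", "hom-alt" = "1/1",
            "missing" = "./.")
  gtm <- matrix(code[vcf$gt], nrow = nrow(vcf$gt))
  body <- paste(vcf$sites$chrom, vcf$sites$pos, ".", vcf$sites$ref,
                vcf$sites$alt, ".", "PASS", ".", "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_tag),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vcf$samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read BED intervals
#'
#' BED3/BED6 via rtracklayer; returned as a data frame with the package's
#' internal 0-based half-open convention and an optional `label` column (BED
#' name field).
#'
#' @param path path to a BED file.
#' @return data.frame with columns chrom, start, end, label.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = lab, stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with chrom, start, end and optional label
#'   (internal 0-based half-open coordinates, written unchanged: BED is
#'   0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  check_that(all(intervals$start < intervals$end), "interval with start >= end")
  if (!is.null(intervals$label) && !all(is.na(intervals$label))) {
    lines <- paste(intervals$chrom, intervals$start, intervals$end,
                   ifelse(is.na(intervals$label), ".", intervals$label),
                   sep = "\t")
  } else {
    lines <- paste(intervals$chrom, intervals$start, intervals$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript exon models from GFF3
#'
#' Extracts exon features and groups them by transcript (`Parent` or
#' `transcript_id` attribute) for the isoform-novelty classifier.
#'
#' @param path path to a GFF3 file.
#' @return exon data.frame: transcript, chrom, strand, start, end (0-based
#'   half-open), sorted by transcript then start.
#' @export
read_gff_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else NA_character_
  if (all(is.na(parent)) && !is.null(gr$transcript_id))
    parent <- as.character(gr$transcript_id)
  df <- data.frame(transcript = parent,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$transcript, df$start), , drop = FALSE]
}

# intervals data.frame -> GRanges (internal half-open to IRanges 1-based closed)
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_intervals <- function(gr, label = NULL) {
  if (is.null(label)) label <- rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = label,
             stringsAsFactors = FALSE)
}
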