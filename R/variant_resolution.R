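#' Select recurring variants from a multi-sample panel
#'
#' A site is recurring when the fraction of samples carrying a
#' homozygous-ALT call is at least `min_frac`; missing genotypes are excluded
#' from the denominator. With `homozygous_only`, sites with any heterozygous
#' call among non-missing samples are excluded entirely (the analysis is then
#' restricted to fixed, homozygous variation).
#'
#' @param vcf a `multi_vcf` (see [read_vcf_multisample()]).
#' @param min_frac recurrence threshold (default 0.75, inclusive).
#' @param homozygous_only drop sites with het calls (default TRUE).
#' @return data.frame of selected sites (chrom, pos, ref, alt) with
#'   `recurrence` and `n_informative` columns.
#' @export
select_recurring <- function(vcf, min_frac = 0.75, homozygous_only = TRUE) {
  if (length(vcf$samples) == 0) stop("panel has zero samples")
  gt <- vcf$gt
  informative <- rowSums(gt != "missing")
  homalt <- rowSums(gt == "hom-alt")
  het <- rowSums(gt == "het")
  frac <- ifelse(informative > 0, homalt / informative, 0)
  keep <- informative > 0 & frac >= min_frac
  if (homozygous_only) keep <- keep & het == 0
  out <- vcf$sites[keep, , drop = FALSE]
  out$recurrence <- frac[keep]
  out$n_informative <- informative[keep]
  rownames(out) <- NULL
  out
}

#' Classify recurring variants as resolved by a new assembly
#'
#' Lifts each variant position through the chain/net and compares the panel
#' ALT allele with the base(s) the new assembly carries there. A SNV is
#' `resolved` when the assembly base equals the ALT allele
#' (reverse-complemented for minus-strand mappings) — i.e. the old reference,
#' not the strains, carried the error — and `unresolved` when the assembly
#' sides with the old reference. Unliftable sites are `unmappable` with the
#' liftover reason recorded. Indels are compared as spanned haplotype strings
#' over lifted flanking anchors (experimental; the recurring-variant analysis
#' is SNV-focused).
#'
#' @param variants data.frame with chrom, pos (1-based), ref, alt.
#' @param chainset `ChainSet` mapping reference coordinates to the assembly.
#' @param assembly named character vector of assembly sequences.
#' @return the input with `status` (resolved/unresolved/unmappable),
#'   `asm_chrom`, `asm_pos` (0-based), `asm_allele`, `strand`, `reason`.
#' @export
classify_resolved <- function(variants, chainset, assembly) {
  v <- variants
  n <- nrow(v)
  v$status <- "unmappable"
  v$asm_chrom <- NA_character_; v$asm_pos <- NA_integer_
  v$asm_allele <- NA_character_; v$strand <- NA_character_
  v$reason <- NA_character_
  if (n == 0) return(v)
  is_snv <- nchar(v$ref) == 1 & nchar(v$alt) == 1
  if (any(is_snv)) {
    m <- map_positions(chainset, v$chrom[is_snv], v$pos[is_snv] - 1L)
    idx <- which(is_snv)
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!m$mapped[j]) { v$reason[i] <- m$reason[j]; next }
      qn <- m$qname[j]; qp <- m$qpos[j]
      if (!qn %in% names(assembly) || qp < 0 ||
          qp >= nchar(assembly[[qn]])) {
        v$reason[i] <- "out_of_bounds"; next
      }
      base <- substr(assembly[[qn]], qp + 1L, qp + 1L)
      alt_adj <- if (m$strand[j] == "-") revcomp(v$alt[i]) else v$alt[i]
      v$asm_chrom[i] <- qn; v$asm_pos[i] <- qp
      v$asm_allele[i] <- if (m$strand[j] == "-") revcomp(base) else base
      v$strand[i] <- m$strand[j]
      v$status[i] <- if (base == alt_adj) "resolved" else "unresolved"
    }
  }
  for (i in which(!is_snv)) {
    # indel: lift the anchor base and the base after the REF span
    a0 <- v$pos[i] - 1L
    a1 <- v$pos[i] - 1L + nchar(v$ref[i])
    m <- map_positions(chainset, c(v$chrom[i], v$chrom[i]), c(a0, a1))
    if (!all(m$mapped)) { v$reason[i] <- m$reason[!m$mapped][1]; next }
    if (m$chain_id[1] != m$chain_id[2] || m$strand[1] != m$strand[2]) {
      v$reason[i] <- "split"; next
    }
    qn <- m$qname[1]
    if (m$strand[1] == "+") {
      hap <- substr(assembly[[qn]], m$qpos[1] + 1L, m$qpos[2])
    } else {
      hap <- revcomp(substr(assembly[[qn]], m$qpos[2] + 1L, m$qpos[1]))
    }
    v$asm_chrom[i] <- qn; v$asm_pos[i] <- min(m$qpos)
    v$asm_allele[i] <- hap; v$strand[i] <- m$strand[1]
    v$status[i] <- if (identical(hap, v$alt[i])) "resolved" else "unresolved"
  }
  v
}

#' Summarize a resolution call set
#'
#' Counts resolved / unresolved / unmappable calls and reports the resolved
#' percentage (half-up, 1 decimal) over a selectable denominator: `"all"`
#' (every considered variant, `total_considered` if given) or `"net"` (only
#' remappable calls).
#'
#' @param calls output of [classify_resolved()].
#' @param total_considered denominator for `"all"` (defaults to `nrow(calls)`).
#' @param denominator `"all"` or `"net"`.
#' @return list: counts, denominator used, `resolved_pct`, and when
#'   `total_considered` is given, `net_pct` (remappable share of the total).
#' @export
summarize_resolution <- function(calls, total_considered = NULL,
                                 denominator = c("all", "net")) {
  denominator <- match.arg(denominator)
  n_res <- sum(calls$status == "resolved")
  n_unres <- sum(calls$status == "unresolved")
  n_unmap <- sum(calls$status == "unmappable")
  total <- if (is.null(total_considered)) nrow(calls) else total_considered
  denom <- switch(denominator, all = total, net = n_res + n_unres)
  if (denom == 0) stop("zero denominator")
  out <- list(resolved = n_res, unresolved = n_unres, unmappable = n_unmap,
              denominator = denom,
              resolved_pct = percent_of(n_res, denom))
  if (!is.null(total_considered) && total_considered > 0)
    out$net_pct <- percent_of(n_res + n_unres, total_considered)
  out
}

#' Classify CDS indels of transcript placements as frameshifting or not
#'
#' A placement counts as frameshifting (FS) when any of its alignment gaps
#' inside annotated CDS has length not divisible by 3; otherwise it is
#' non-frameshifting (NFS) if it has at least one CDS gap. Gaps outside CDS
#' are ignored.
#'
#' @param gaps data.frame with `placement`, `len`, and either a logical
#'   `in_cds` column or `chrom`, `start`, `end` coordinates.
#' @param cds optional CDS interval data.frame (chrom, start, end); when
#'   given, `in_cds` is computed as any overlap with a CDS interval.
#' @return list: `per_placement` (placement, class in FS/NFS/none), `fs`,
#'   `nfs` counts.
#' @export
classify_cds_indels <- function(gaps, cds = NULL) {
  g <- gaps
  if (!is.null(cds)) {
    g$in_cds <- IRanges::overlapsAny(intervals_to_gr(g),
                                           intervals_to_gr(cds))
  }
  check_that(!is.null(g$in_cds), "need in_cds column or cds intervals")
  per <- do.call(rbind, lapply(split(g, g$placement), function(d) {
    lens <- d$len[d$in_cds]
    cls <- if (!length(lens)) "none"
           else if (any(lens %% 3 != 0)) "FS" else "NFS"
    data.frame(placement = d$placement[1], class = cls,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_placement = per,
       fs = sum(per$class == "FS"), nfs = sum(per$class == "NFS"))
}
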