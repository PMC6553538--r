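#' Find assembly gaps (maximal N-runs) in a reference
#'
#' @param reference named character vector of sequences.
#' @param min_gap_len minimum N-run length to report (default 10).
#' @param exclude optional interval data.frame (chrom, start, end); gaps
#'   overlapping an excluded interval (e.g. centromere/telomere masks) are
#'   omitted.
#' @return gap data.frame: gap_id, chrom, start, end (0-based half-open),
#'   length.
#' @export
find_gaps <- function(reference, min_gap_len = 10L, exclude = NULL) {
  rows <- list()
  for (chrom in names(reference)) {
    m <- gregexpr("N+", reference[[chrom]])[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    keep <- len >= min_gap_len
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = as.integer(m[keep]) - 1L,
      end = as.integer(m[keep]) - 1L + len[keep],
      length = len[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gap_id = integer(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  gaps <- do.call(rbind, rows)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    hit <- IRanges::overlapsAny(intervals_to_gr(gaps),
                                      intervals_to_gr(exclude))
    gaps <- gaps[!hit, , drop = FALSE]
  }
  gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
  gaps$gap_id <- seq_len(nrow(gaps))
  rownames(gaps) <- NULL
  gaps[, c("gap_id", "chrom", "start", "end", "length")]
}

#' Pad gaps with flanking sequence
#'
#' Extends each gap by `flank` bp on both sides, clipped to chromosome
#' bounds, and names the padded region by its 1-based inclusive span.
#'
#' @param gaps gap data.frame from [find_gaps()].
#' @param flank flank size in bp (default 50000; desk-scale runs use 5000).
#' @param chrom_lens named chromosome lengths for clipping.
#' @return the gap data.frame with added `pstart`, `pend`, `region` columns.
#' @export
pad_gaps <- function(gaps, flank = 50000L, chrom_lens) {
  check_that(flank > 0, "flank must be positive")
  gaps$pstart <- pmax(0L, gaps$start - as.integer(flank))
  gaps$pend <- pmin(as.integer(chrom_lens[gaps$chrom]),
                    gaps$end + as.integer(flank))
  gaps$region <- sprintf("%s:%d-%d", gaps$chrom, gaps$pstart + 1L, gaps$pend)
  gaps
}

#' Extract padded-region sequences
#'
#' @param reference named character vector.
#' @param padded gap table from [pad_gaps()].
#' @return named character vector of region sequences (names = `region`).
#' @export
extract_regions <- function(reference, padded) {
  out <- mapply(function(ch, s, e) substr(reference[[ch]], s + 1L, e),
                padded$chrom, padded$pstart, padded$pend, USE.NAMES = FALSE)
  names(out) <- padded$region
  out
}

#' Filter gap-fill candidate scaffolds
#'
#' Applies the three candidate filters to alignments of assembly scaffolds
#' against padded gap regions: (a) the (region, scaffold) pair must be a
#' reciprocal best hit by total matched bases, (b) the pair's total matched
#' bases must reach `min_total_aln` (inclusive), and (c) the scaffold's
#' whole-assembly placement must be unique (see [scaffold_uniqueness()]).
#' Best-hit ties break toward the pair with fewer alignment records (more
#' contiguous support), then lexicographically.
#'
#' @param region_alignments PAF of scaffolds (query) vs padded regions
#'   (target).
#' @param padded gap table from [pad_gaps()].
#' @param min_total_aln minimum summed matched bases (default 80000;
#'   desk-scale runs use 8000).
#' @param uniqueness data.frame from [scaffold_uniqueness()], or NULL to
#'   skip criterion (c).
#' @return one row per gap: gap columns plus `scaffold`, `total_aln`,
#'   `n_aln`, `status` (candidate / no_candidate / not_reciprocal /
#'   below_min_aln / not_unique).
#' @export
filter_candidates <- function(region_alignments, padded,
                              min_total_aln = 80000L, uniqueness = NULL) {
  aln <- region_alignments
  res <- padded
  res$scaffold <- NA_character_
  res$total_aln <- 0L
  res$n_aln <- 0L
  res$status <- "no_candidate"
  if (nrow(aln)) {
    # score each (region, scaffold) pair by its best co-linear chain, not by
    # the raw sum over records: repetitive cross-matches would otherwise
    # inflate a large scaffold against every region
    cs <- build_chains(aln)
    ch <- cs$chains
    pair <- do.call(rbind, lapply(split(ch, paste(ch$tname, ch$qname,
                                                  sep = "\r")),
      function(d) {
        best <- which.max(d$score)
        data.frame(tname = d$tname[1], qname = d$qname[1],
                   total = d$score[best], n = d$nblocks[best],
                   stringsAsFactors = FALSE)
      }))
    best_of <- function(d, by) {
      do.call(rbind, lapply(split(d, d[[by]]), function(g) {
        g[order(-g$total, g$n, g$tname, g$qname), ][1, , drop = FALSE]
      }))
    }
    best_for_region <- best_of(pair, "tname")     # region -> best scaffold
    best_for_scaffold <- best_of(pair, "qname")   # scaffold -> best region
    for (i in seq_len(nrow(res))) {
      rg <- res$region[i]
      br <- best_for_region[best_for_region$tname == rg, , drop = FALSE]
      if (nrow(br) == 0) next
      scaf <- br$qname[1]
      res$scaffold[i] <- scaf
      res$total_aln[i] <- br$total[1]
      res$n_aln[i] <- br$n[1]
      bs <- best_for_scaffold[best_for_scaffold$qname == scaf, , drop = FALSE]
      if (nrow(bs) == 0 || bs$tname[1] != rg) {
        res$status[i] <- "not_reciprocal"
      } else if (br$total[1] < min_total_aln) {
        res$status[i] <- "below_min_aln"
      } else if (!is.null(uniqueness) &&
                 (!scaf %in% uniqueness$qname ||
                  !uniqueness$unique[match(scaf, uniqueness$qname)])) {
        res$status[i] <- "not_unique"
      } else {
        res$status[i] <- "candidate"
      }
    }
  }
  res
}

# Signed indel delta observed across the gap from paired flank records:
# (query advance) - (target advance) between the inner alignment ends.
flank_delta <- function(left, right, strand) {
  if (strand == "+") {
    (right$qstart - left$qend) - (right$tstart - left$tend)
  } else {
    (right$qstart - left$qend) - (left$tstart - right$tend)
  }
}

# Pick the flank record adjacent to the gap: among records overlapping the
# flank zone by at least min_ov, the one whose inner end sits closest to the
# gap (side = "left": largest qend; side = "right": smallest qstart). A
# nearby indel can split a flank into several records, and only the
# innermost one defines the fill boundary.
pick_flank <- function(recs, lo, hi, side = c("left", "right"),
                       min_ov = 30L) {
  side <- match.arg(side)
  ov <- pmin(recs$qend, hi) - pmax(recs$qstart, lo)
  cand <- which(ov >= min_ov)
  if (!length(cand)) {
    cand <- which(ov > 0)
    if (!length(cand)) return(NULL)
  }
  key <- if (side == "left") order(-recs$qend[cand], -recs$nmatch[cand])
         else order(recs$qstart[cand], -recs$nmatch[cand])
  recs[cand[key[1]], , drop = FALSE]
}

#' Confirm a gap-fill candidate and extract the fill sequence
#'
#' Uses the reciprocal alignments (padded region as query, scaffold as
#' target). The left and right gap flanks must align to the same scaffold on
#' the same strand, co-linearly; the fill is the scaffold sequence between
#' the inner ends of the two flank alignments (reverse-complemented for
#' minus-strand scaffolds), and the candidate is confirmed when the signed
#' length difference observed in the forward direction equals the negation
#' of the reciprocal one within `tol`. A single alignment record spanning the
#' whole gap (fill length equal to gap length) is handled directly.
#'
#' @param candidate one row of [filter_candidates()] output (status
#'   "candidate").
#' @param reciprocal_alignments PAF of padded regions (query) vs scaffolds
#'   (target).
#' @param forward_alignments PAF of scaffolds (query) vs regions (target),
#'   used for the reciprocity check; NULL skips that check.
#' @param assembly named character vector of scaffold sequences.
#' @param tol tolerance (bp) for the reciprocal discrepancy check
#'   (default 10).
#' @return the candidate row extended with `fill_len`, `discrepancy`,
#'   `confirmed`, `reason`, `fill` (sequence, reference orientation).
#' @export
confirm_and_extract <- function(candidate, reciprocal_alignments,
                                forward_alignments = NULL, assembly,
                                tol = 10L) {
  out <- candidate
  out$fill <- NA_character_; out$fill_len <- NA_integer_
  out$discrepancy <- NA_integer_; out$confirmed <- FALSE
  out$reason <- NA_character_
  gs <- candidate$start - candidate$pstart          # gap offset in region
  glen <- candidate$length
  rlen <- candidate$pend - candidate$pstart
  recs <- reciprocal_alignments[
    reciprocal_alignments$qname == candidate$region &
    reciprocal_alignments$tname == candidate$scaffold, , drop = FALSE]
  if (nrow(recs) == 0) { out$reason <- "no_flank_alignment"; return(out) }
  # both flanks must align on one strand; strands are tried in order of
  # matched-base support (an inversion inside a flank contributes records on
  # the other strand without making the flanks discordant)
  sup <- sort(tapply(recs$nmatch, recs$strand, sum), decreasing = TRUE)
  left <- right <- NULL
  strand <- names(sup)[1]
  for (st in names(sup)) {
    rs <- recs[recs$strand == st, , drop = FALSE]
    # a single gap-free record covering both flanks (possible when the fill
    # length equals the gap length) takes precedence over separate flanks
    ovl <- pmin(rs$qend, gs) - pmax(rs$qstart, 0L)
    ovr <- pmin(rs$qend, rlen) - pmax(rs$qstart, gs + glen)
    span_ok <- ovl >= 50L & ovr >= 50L
    if (any(span_ok)) {
      best <- which(span_ok)[which.max(rs$nmatch[span_ok])]
      l <- r <- rs[best, , drop = FALSE]
    } else {
      l <- pick_flank(rs, 0L, gs, side = "left")
      r <- pick_flank(rs, gs + glen, rlen, side = "right")
    }
    if (!is.null(l) && !is.null(r)) {
      left <- l; right <- r; strand <- st
      break
    }
  }
  if (is.null(left) || is.null(right)) {
    out$reason <- if (length(sup) > 1) "discordant_strand"
                  else "no_flank_alignment"
    return(out)
  }
  recs <- recs[recs$strand == strand, , drop = FALSE]
  spanning <- identical(rownames(left), rownames(right))
  scaf_seq <- assembly[[candidate$scaffold]]
  if (spanning) {
    # one gap-free record covers both flanks: fill length == gap length
    if (strand == "+") {
      fs <- left$tstart + (gs - left$qstart)
      fe <- fs + glen
      fill <- substr(scaf_seq, fs + 1L, fe)
    } else {
      fe <- left$tend - (gs - left$qstart)
      fs <- fe - glen
      fill <- revcomp(substr(scaf_seq, fs + 1L, fe))
    }
    delta_b <- 0L
  } else {
    if (strand == "+") {
      if (right$tstart < left$tend) { out$reason <- "discordant_order"; return(out) }
      fill <- substr(scaf_seq, left$tend + 1L, right$tstart)
    } else {
      if (left$tstart < right$tend) { out$reason <- "discordant_order"; return(out) }
      fill <- revcomp(substr(scaf_seq, right$tend + 1L, left$tstart))
    }
    delta_b <- flank_delta(left, right, strand) * -1L  # fill - gap, signed
  }
  out$fill <- fill
  out$fill_len <- nchar(fill)
  out$discrepancy <- out$fill_len - glen
  # reciprocity: the forward direction must show the opposite signed pattern
  if (!is.null(forward_alignments)) {
    fw <- forward_alignments[
      forward_alignments$qname == candidate$scaffold &
      forward_alignments$tname == candidate$region &
      forward_alignments$strand == strand, , drop = FALSE]
    # on the region (target) axis the flanks sit at [0,gs) and [gs+glen,rlen)
    ovl <- pmin(fw$tend, gs) - pmax(fw$tstart, 0L)
    ovr <- pmin(fw$tend, rlen) - pmax(fw$tstart, gs + glen)
    span_ok <- length(ovl) > 0 & ovl >= 50L & ovr >= 50L
    if (any(span_ok)) {
      best <- which(span_ok)[which.max(fw$nmatch[span_ok])]
      lf <- rf <- fw[best, , drop = FALSE]
    } else {
      lf <- if (length(ovl) && max(ovl) > 0) {
        cand <- which(ovl >= pmin(30L, max(ovl)))
        fw[cand[order(-fw$tend[cand], -fw$nmatch[cand])[1]], , drop = FALSE]
      } else NULL
      rf <- if (length(ovr) && max(ovr) > 0) {
        cand <- which(ovr >= pmin(30L, max(ovr)))
        fw[cand[order(fw$tstart[cand], -fw$nmatch[cand])[1]], , drop = FALSE]
      } else NULL
    }
    if (is.null(lf) || is.null(rf)) {
      out$reason <- "no_reciprocal_alignment"; return(out)
    }
    delta_a <- if (identical(rownames(lf), rownames(rf))) 0L else {
      if (strand == "+") {
        (rf$qstart - lf$qend) - (rf$tstart - lf$tend)
      } else {
        (lf$qstart - rf$qend) - (rf$tstart - lf$tend)
      }
    }
    if (abs(delta_a + (-delta_b)) > tol) {
      out$reason <- "reciprocity_failed"
      return(out)
    }
  }
  out$confirmed <- TRUE
  out
}

#' Run the full gap-filling procedure on a reference/assembly pair
#'
#' find gaps, pad, align scaffolds to padded regions and reciprocally, apply
#' the candidate filters, confirm and extract fills.
#'
#' @param reference,assembly named character vectors of sequences.
#' @param flank,min_total_aln procedure parameters (see [pad_gaps()] and
#'   [filter_candidates()]).
#' @param chainset optional whole-assembly `ChainSet` for the uniqueness
#'   criterion (built on the fly when NULL and `build_uniqueness` is TRUE).
#' @param min_gap_len,exclude passed to [find_gaps()].
#' @param aligner_args list of arguments forwarded to [align_genomes()].
#' @return list with `gaps`, `candidates`, `fills` (confirmed-and-extracted
#'   table).
#' @export
gapfill_run <- function(reference, assembly, flank = 50000L,
                        min_total_aln = 80000L, chainset = NULL,
                        min_gap_len = 10L, exclude = NULL,
                        aligner_args = list()) {
  gaps <- find_gaps(reference, min_gap_len = min_gap_len, exclude = exclude)
  if (nrow(gaps) == 0)
    return(list(gaps = gaps, candidates = gaps, fills = gaps))
  padded <- pad_gaps(gaps, flank = flank,
                     chrom_lens = vapply(reference, nchar, 1L))
  regions <- extract_regions(reference, padded)
  fwd <- do.call(align_genomes, c(list(queries = assembly,
                                       targets = regions), aligner_args))
  uniq <- if (!is.null(chainset)) scaffold_uniqueness(chainset) else NULL
  cand <- filter_candidates(fwd, padded, min_total_aln = min_total_aln,
                            uniqueness = uniq)
  rec <- do.call(align_genomes, c(list(queries = regions,
                                       targets = assembly), aligner_args))
  fills <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    if (cand$status[i] != "candidate") {
      row <- cand[i, , drop = FALSE]
      row$fill <- NA_character_; row$fill_len <- NA_integer_
      row$discrepancy <- NA_integer_; row$confirmed <- FALSE
      row$reason <- row$status
      return(row)
    }
    confirm_and_extract(cand[i, , drop = FALSE], rec, fwd, assembly)
  }))
  rownames(fills) <- NULL
  list(gaps = gaps, candidates = cand, fills = fills)
}
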