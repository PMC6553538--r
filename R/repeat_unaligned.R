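#' Per-base intersection of several interval sets
#'
#' Builds the consensus region common to all of the given interval sets
#' (e.g. the sequence left unaligned by each of several alignment methods),
#' emitted as maximal merged intervals. Order-independent and idempotent.
#'
#' @param sets list of at least two interval data.frames (chrom, start, end).
#' @param seqlens optional named sequence lengths; when given, sets that
#'   reference unknown sequences raise an error.
#' @return interval data.frame (chrom, start, end).
#' @export
consensus_unaligned <- function(sets, seqlens = NULL) {
  check_that(length(sets) >= 2, "need at least two interval sets")
  if (!is.null(seqlens)) {
    for (s in sets) {
      bad <- setdiff(unique(s$chrom), names(seqlens))
      if (length(bad)) stop("set references unknown sequences: ",
                            paste(bad, collapse = ", "))
    }
  }
  grs <- lapply(sets, function(s)
    GenomicRanges::reduce(intervals_to_gr(s)))
  res <- Reduce(function(x, y) GenomicRanges::intersect(x, y,
                                                        ignore.strand = TRUE),
                grs)
  res <- GenomicRanges::reduce(res)
  res <- GenomicRanges::sort(res)
  gr_to_intervals(res)[, c("chrom", "start", "end")]
}

# Resolve overlapping repeat annotation: after sorting by (start, class),
# the first-listed class claims shared bases.
resolve_repeat_overlaps <- function(repeats) {
  out <- list()
  for (chrom in unique(repeats$chrom)) {
    d <- repeats[repeats$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start, d$label), , drop = FALSE]
    claimed <- IRanges::IRanges()
    for (i in seq_len(nrow(d))) {
      r <- IRanges::IRanges(d$start[i] + 1L, d$end[i])
      free <- IRanges::setdiff(r, claimed)
      if (length(free)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = IRanges::start(free) - 1L,
          end = IRanges::end(free), label = d$label[i],
          stringsAsFactors = FALSE)
        claimed <- IRanges::reduce(c(claimed, free))
      }
    }
  }
  do.call(rbind, out)
}

#' Repeat-class composition of a region set
#'
#' Overlap of each labeled repeat class with the region, in bp and as a
#' percentage of the region total (half-up rounding; 2 decimals by default,
#' matching repeat composition tables). Overlapping repeat annotations are
#' resolved first-listed-class-wins after sorting by (start, class).
#'
#' @param region interval data.frame (chrom, start, end); must have
#'   positive total length.
#' @param repeats labeled interval data.frame (chrom, start, end, label).
#' @param decimals decimal places for percentages (default 2).
#' @return list: `table` (class, bp, pct), `total_bp` (region), `repeat_bp`
#'   (all classes), `repeat_pct`.
#' @export
repeat_composition <- function(region, repeats, decimals = 2) {
  total <- sum(region$end - region$start)
  check_that(total > 0, "zero-length region")
  rgr <- GenomicRanges::reduce(intervals_to_gr(region))
  reps <- resolve_repeat_overlaps(repeats)
  classes <- sort(unique(reps$label))
  rows <- lapply(classes, function(cl) {
    cgr <- intervals_to_gr(reps[reps$label == cl, , drop = FALSE])
    ov <- GenomicRanges::intersect(rgr, cgr, ignore.strand = TRUE)
    bp <- sum(GenomicRanges::width(ov))
    data.frame(class = cl, bp = bp, pct = percent_of(bp, total, decimals),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rep_bp <- sum(tab$bp)
  list(table = tab, total_bp = total, repeat_bp = rep_bp,
       repeat_pct = percent_of(rep_bp, total, 1))
}

#' Chi-square enrichment of a repeat class between two genomes
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' class vs non-class base counts in genome A and genome B; p-value from the
#' upper tail of chi-square with 1 df. When any expected cell is below 5 the
#' result carries a reliability flag rather than an error.
#'
#' @param class_bp_a,total_a class and total bp in genome A.
#' @param class_bp_b,total_b class and total bp in genome B.
#' @return list: `chi2`, `p`, `table`, `unreliable` (TRUE if any expected
#'   cell < 5).
#' @export
class_enrichment <- function(class_bp_a, total_a, class_bp_b, total_b) {
  check_that(all(c(class_bp_a, class_bp_b) >= 0) &&
               all(c(total_a, total_b) > 0), "counts must be nonnegative, totals positive")
  check_that(class_bp_a <= total_a && class_bp_b <= total_b,
             "class bp exceeds total")
  m <- rbind(A = c(class_bp_a, total_a - class_bp_a),
             B = c(class_bp_b, total_b - class_bp_b))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value), table = m,
       unreliable = any(expected < 5))
}

#' Perturbed copies of an interval set
#'
#' Deterministically jitters interval endpoints to emulate independent
#' alignment methods producing slightly different unaligned sets; used by
#' the pipeline to exercise the consensus operation.
#'
#' @param intervals interval data.frame (chrom, start, end).
#' @param n number of perturbed copies.
#' @param jitter max absolute endpoint shift (bp).
#' @param seqlens named sequence lengths for clipping.
#' @param seed RNG seed.
#' @return list of `n` interval data.frames.
#' @export
perturb_interval_sets <- function(intervals, n = 3L, jitter = 50L, seqlens,
                                  seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- intervals
    d$start <- pmax(0L, d$start + sample(seq(-jitter, jitter), nrow(d),
                                         replace = TRUE))
    d$end <- pmin(as.integer(seqlens[d$chrom]),
                  d$end + sample(seq(-jitter, jitter), nrow(d),
                                 replace = TRUE))
    d[d$end > d$start, , drop = FALSE]
  })
}
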