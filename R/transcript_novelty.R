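#' Validate and normalize transcript exon models
#'
#' @param exons data.frame: transcript, chrom, strand, start, end (0-based
#'   half-open), one row per exon.
#' @return the exon table sorted by (transcript, start), after checking that
#'   each transcript's exons are disjoint and on one chrom/strand.
#' @export
transcript_models <- function(exons) {
  check_that(all(exons$start < exons$end), "exon with start >= end")
  for (tx in unique(exons$transcript)) {
    d <- exons[exons$transcript == tx, , drop = FALSE]
    check_that(length(unique(d$chrom)) == 1 && length(unique(d$strand)) == 1,
               "transcript %s spans multiple chrom/strand", tx)
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1)
      check_that(all(d$start[-1] >= d$end[-nrow(d)]),
                 "transcript %s has overlapping exons", tx)
  }
  exons[order(exons$transcript, exons$start), , drop = FALSE]
}

#' Splice-junction set of transcript models
#'
#' Introns in intron coordinates: donor = exon end, acceptor = next exon
#' start (0-based half-open); deduplicated across transcripts. Single-exon
#' models contribute no junctions.
#'
#' @param models exon data.frame (see [transcript_models()]).
#' @return data.frame: chrom, donor, acceptor, strand (unique rows).
#' @export
junction_set <- function(models) {
  rows <- lapply(split(models, models$transcript), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    data.frame(chrom = d$chrom[1],
               donor = d$end[-nrow(d)], acceptor = d$start[-1],
               strand = d$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Classify a predicted transcript against reference annotation
#'
#' Categories, in precedence order:
#' \describe{
#'   \item{novel_locus}{no exon of the prediction overlaps any reference
#'     exon;}
#'   \item{novel_exon}{at least one exon overlaps no reference exon by more
#'     than `slack` bp (a fully novel exon, e.g. inside a reference intron);}
#'   \item{splice_shift}{some junction is absent from the reference junction
#'     set; typically it shares one coordinate (donor or acceptor) with a
#'     reference junction. Any unannotated junction without a novel exon
#'     falls in this category;}
#'   \item{annotated}{every junction is in the reference set.}
#' }
#'
#' @param prediction exon data.frame of one transcript.
#' @param reference_models reference exon data.frame.
#' @param reference_junctions optional precomputed [junction_set()] of the
#'   reference (computed when NULL).
#' @param slack maximum bp of exon overlap still treated as "no overlap" for
#'   the novel-exon test (default 0: strictest reading).
#' @return one of "annotated", "splice_shift", "novel_exon", "novel_locus".
#' @export
classify_novelty <- function(prediction, reference_models,
                             reference_junctions = NULL, slack = 0L) {
  if (is.null(reference_junctions))
    reference_junctions <- junction_set(reference_models)
  pg <- intervals_to_gr(data.frame(chrom = prediction$chrom,
                                   start = prediction$start,
                                   end = prediction$end))
  rg <- intervals_to_gr(data.frame(chrom = reference_models$chrom,
                                   start = reference_models$start,
                                   end = reference_models$end))
  ov <- GenomicRanges::findOverlaps(pg, rg)
  ov_bp <- rep(0L, length(pg))
  if (length(ov)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      pg[S4Vectors::queryHits(ov)], rg[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), max)
    ov_bp[as.integer(names(agg))] <- as.integer(agg)
  }
  if (all(ov_bp <= slack)) return("novel_locus")
  if (any(ov_bp <= slack)) return("novel_exon")
  pj <- junction_set(prediction)
  if (nrow(pj) == 0) return("annotated")
  key <- function(j) paste(j$chrom, j$donor, j$acceptor, j$strand)
  known <- key(pj) %in% key(reference_junctions)
  if (all(known)) return("annotated")
  "splice_shift"
}

#' Classify a set of predicted transcripts
#'
#' @param predictions exon data.frame of several transcripts.
#' @param reference_models reference exon data.frame.
#' @param slack see [classify_novelty()].
#' @return data.frame: transcript, status.
#' @export
classify_novelty_all <- function(predictions, reference_models, slack = 0L) {
  rj <- junction_set(reference_models)
  out <- do.call(rbind, lapply(split(predictions, predictions$transcript),
    function(d) data.frame(
      transcript = d$transcript[1],
      status = classify_novelty(d, reference_models, rj, slack),
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
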