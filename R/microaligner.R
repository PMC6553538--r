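#' Pairwise alignment of two sequences by minimizer seed-and-chain
#'
#' A deliberately small exact-k-mer aligner for low-divergence same-species
#' assembly pairs: minimizer anchors (k-mers containing N never anchor,
#' highly repetitive seeds above `max_occ` target hits are skipped), sparse
#' co-linear chaining with gap penalty `|dq - dt|`, X-drop extension of the
#' chain termini, and gap-free match counting between anchors. Each maximal
#' gap-free run of a chain (constant diagonal) is emitted as one PAF record,
#' so records double as gap-free blocks for chain/net construction. Both
#' strands are searched; negative-strand records carry query coordinates on
#' the original strand (PAF convention).
#'
#' @param query,target named single-element character vectors (or plain
#'   strings with `qname`/`tname` given) over \{A,C,G,T,N\}.
#' @param k anchor k-mer size (default 15).
#' @param w minimizer window: one anchor seed is sampled per `w` consecutive
#'   k-mer starts (default 10).
#' @param max_gap maximum per-step query/target gap bridged within a chain
#'   (default 2000).
#' @param min_chain_score chains scoring below this are dropped (default 100).
#' @param max_occ seeds occurring more than this many times in the target are
#'   treated as repetitive and skipped (default 64).
#' @param qname,tname sequence names used in the PAF output; default to the
#'   names of `query`/`target`.
#' @return PAF-style alignment data frame (see [read_paf()]), sorted by target
#'   coordinate.
#' @export
align <- function(query, target, k = 15L, w = 10L, max_gap = 2000L,
                  min_chain_score = 100, max_occ = 64L,
                  qname = names(query), tname = names(target)) {
  qseq <- unname(query[[1]]); tseq <- unname(target[[1]])
  if (is.null(qname)) qname <- "query"
  if (is.null(tname)) tname <- "target"
  qlen <- nchar(qseq); tlen <- nchar(tseq)
  if (k > min(qlen, tlen)) stop("k exceeds the shorter sequence length")
  tcodes <- encode_dna(tseq)
  fwd <- align_one_strand(qseq, tseq, encode_dna(qseq), tcodes, k, w,
                          max_gap, min_chain_score, max_occ)
  qrc <- revcomp(qseq)
  rev_ <- align_one_strand(qrc, tseq, encode_dna(qrc), tcodes, k, w,
                           max_gap, min_chain_score, max_occ)
  recs <- list()
  if (nrow(fwd)) {
    fwd$strand <- "+"
    recs[[length(recs) + 1L]] <- fwd
  }
  if (nrow(rev_)) {
    # back-transform query coordinates to the original strand
    qs <- qlen - rev_$qend
    rev_$qend <- qlen - rev_$qstart
    rev_$qstart <- qs
    rev_$strand <- "-"
    recs[[length(recs) + 1L]] <- rev_
  }
  if (!length(recs)) return(empty_paf())
  out <- do.call(rbind, recs)
  out$qname <- qname; out$qlen <- qlen
  out$tname <- tname; out$tlen <- tlen
  out$mapq <- 60L
  out <- out[order(out$tstart, out$tend, out$qstart), paf_cols, drop = FALSE]
  rownames(out) <- NULL
  validate_paf(out)
}

# One-strand seed/chain/extend. Returns partial PAF columns (coordinates in
# the oriented query), one record per gap-free run.
align_one_strand <- function(qseq, tseq, qcodes, tcodes, k, w, max_gap,
                             min_chain_score, max_occ) {
  anc <- .mz_anchors(qcodes, tcodes, as.integer(k), as.integer(w),
                     as.integer(max_occ))
  out <- data.frame(qstart = integer(), qend = integer(),
                    tstart = integer(), tend = integer(),
                    nmatch = integer(), blocklen = integer(),
                    chain = integer(), stringsAsFactors = FALSE)
  if (nrow(anc) == 0) return(out)
  chains <- .chain_anchors(anc[, 1], anc[, 2], as.integer(k),
                           as.integer(max_gap), min_chain_score, 100L)
  if (!length(chains)) return(out)
  acc_qs <- acc_qe <- acc_ts <- acc_te <- acc_nm <- acc_ch <- integer(0)
  for (ci in seq_along(chains)) {
    idx <- chains[[ci]]
    qp <- anc[idx, 1]; tp <- anc[idx, 2]
    runs <- run_segments(qp, tp, k)
    first <- 1L; last <- length(runs$qs)
    # X-drop terminal extension of the outermost runs, bounded to 500 bp:
    # anchors sit within about a minimizer window of the true alignment
    # ends, so longer terminal extensions only duplicate space that belongs
    # to a neighboring chain (e.g. across an unanchored repeat block)
    term_cap <- 500L
    ext <- xdrop_extend(qcodes, tcodes, runs$qs[first], runs$ts[first],
                        direction = -1L, cap = term_cap)
    runs$qs[first] <- runs$qs[first] - ext
    runs$ts[first] <- runs$ts[first] - ext
    ext <- xdrop_extend(qcodes, tcodes, runs$qe[last], runs$te[last],
                        direction = +1L, cap = term_cap)
    runs$qe[last] <- runs$qe[last] + ext
    runs$te[last] <- runs$te[last] + ext
    # interior extension toward each inter-run gap, capped so adjacent
    # runs never cross on either axis (exact boundaries at zero noise,
    # where the first mismatching base stops the extension)
    if (last > 1L) {
      for (ri in seq_len(last - 1L)) {
        cap <- min(runs$qs[ri + 1L] - runs$qe[ri],
                   runs$ts[ri + 1L] - runs$te[ri])
        if (cap > 0) {
          ext <- xdrop_extend(qcodes, tcodes, runs$qe[ri], runs$te[ri],
                              direction = +1L, cap = cap)
          runs$qe[ri] <- runs$qe[ri] + ext
          runs$te[ri] <- runs$te[ri] + ext
        }
        cap <- min(runs$qs[ri + 1L] - runs$qe[ri],
                   runs$ts[ri + 1L] - runs$te[ri])
        if (cap > 0) {
          ext <- xdrop_extend(qcodes, tcodes, runs$qs[ri + 1L],
                              runs$ts[ri + 1L], direction = -1L, cap = cap)
          runs$qs[ri + 1L] <- runs$qs[ri + 1L] - ext
          runs$ts[ri + 1L] <- runs$ts[ri + 1L] - ext
        }
      }
    }
    nm <- vapply(seq_len(last), function(ri)
      count_matches(qcodes, tcodes, runs$qs[ri], runs$qe[ri],
                    runs$ts[ri], runs$te[ri]), 0L)
    acc_qs <- c(acc_qs, runs$qs); acc_qe <- c(acc_qe, runs$qe)
    acc_ts <- c(acc_ts, runs$ts); acc_te <- c(acc_te, runs$te)
    acc_nm <- c(acc_nm, nm); acc_ch <- c(acc_ch, rep.int(ci, last))
  }
  data.frame(qstart = acc_qs, qend = acc_qe, tstart = acc_ts,
             tend = acc_te, nmatch = acc_nm,
             blocklen = pmax(acc_qe - acc_qs, acc_te - acc_ts),
             chain = acc_ch, stringsAsFactors = FALSE)
}

# Split a chain's anchors into maximal constant-diagonal runs (anchors are
# in chain order: increasing qpos and tpos).
run_segments <- function(qp, tp, k) {
  d <- tp - qp
  brk <- which(c(TRUE, d[-1] != d[-length(d)]))
  ends <- c(brk[-1] - 1L, length(qp))
  list(qs = qp[brk], qe = qp[ends] + k, ts = tp[brk], te = tp[ends] + k)
}

# Count exactly matching bases over a same-length coordinate window
# (N never matches anything, itself included).
count_matches <- function(qcodes, tcodes, qs, qe, ts, te) {
  n <- min(qe - qs, te - ts)
  if (n <= 0) return(0L)
  qc <- qcodes[(qs + 1L):(qs + n)]
  tc <- tcodes[(ts + 1L):(ts + n)]
  sum(qc == tc & qc < 4L)
}

# Greedy X-drop extension outward from (q0, t0): +1 match, -2 mismatch,
# stop when the score falls `xdrop` below its running maximum; the extension
# length is the argmax of the running score (ties -> shortest).
xdrop_extend <- function(qcodes, tcodes, q0, t0, direction, xdrop = 20L,
                         cap = Inf) {
  Lmax <- if (direction > 0) {
    min(length(qcodes) - q0, length(tcodes) - t0, cap)
  } else {
    min(q0, t0, cap)
  }
  if (Lmax <= 0) return(0L)
  # chunked scan: almost every extension stops within a few hundred bases,
  # so never materialize the full remaining sequence
  chunk <- 512L
  done <- 0L
  base <- 0L          # score at the end of previous chunks
  best <- 0L; best_at <- 0L; seen_max <- 0L
  while (done < Lmax) {
    n <- min(chunk, Lmax - done)
    if (direction > 0) {
      qc <- qcodes[(q0 + done + 1L):(q0 + done + n)]
      tc <- tcodes[(t0 + done + 1L):(t0 + done + n)]
    } else {
      qc <- qcodes[(q0 - done):(q0 - done - n + 1L)]
      tc <- tcodes[(t0 - done):(t0 - done - n + 1L)]
    }
    sc <- base + cumsum(ifelse(qc == tc & qc < 4L, 1L, -2L))
    run_max <- cummax(pmax(sc, seen_max))
    stop_at <- which(run_max - sc > xdrop)
    lim <- if (length(stop_at)) stop_at[1] else n
    mx <- max(sc[seq_len(lim)])
    if (mx > best) { best <- mx; best_at <- done + which.max(sc[seq_len(lim)]) }
    seen_max <- max(seen_max, mx)
    if (length(stop_at)) break
    base <- sc[n]
    done <- done + n
  }
  if (best <= 0) return(0L)
  best_at
}

#' Align every query sequence against every target sequence
#'
#' Convenience wrapper producing one combined PAF table, used for
#' whole-assembly alignment ahead of chain/net construction.
#'
#' @param queries,targets named character vectors of sequences.
#' @inheritParams align
#' @return combined PAF data frame.
#' @export
align_genomes <- function(queries, targets, k = 15L, w = 10L,
                          max_gap = 2000L, min_chain_score = 100,
                          max_occ = 64L) {
  res <- list()
  for (tn in names(targets)) {
    for (qn in names(queries)) {
      if (k > min(nchar(queries[[qn]]), nchar(targets[[tn]]))) next
      res[[length(res) + 1L]] <-
        align(queries[qn], targets[tn], k = k, w = w, max_gap = max_gap,
              min_chain_score = min_chain_score, max_occ = max_occ)
    }
  }
  if (!length(res)) return(empty_paf())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
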