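#' Build a netted chain set from pairwise alignments
#'
#' Re-implements same-species chain-and-net construction: gap-free alignment
#' records between one query assembly and one target assembly are merged into
#' co-linear chains scored by total matched bases, and target space is then
#' "netted" — assigned greedily to chains in descending score, truncating
#' lower-scoring chains to the space no better chain owns. The result is the
#' liftover substrate: after netting every target base is owned by at most one
#' chain.
#'
#' Input records whose query and target spans differ (records that internally
#' contain an indel) are trimmed to the shorter span so that every stored
#' block is strictly gap-free; the micro-aligner already emits one record per
#' gap-free run, so its output passes through unchanged.
#'
#' @param alignments PAF-style data frame (see [read_paf()]).
#' @param max_join_gap two co-linear records merge into one chain only if
#'   both coordinate gaps between them are below this (default 100 kb).
#' @param join_slop small negative inter-record gap (overlap, bp) tolerated
#'   when joining; the overlapping prefix of the later record is trimmed.
#' @param max_join_drift maximum |query gap - target gap| between joined
#'   records (bounds the implied indel; keeps distant repeat cross-matches
#'   from capturing a chain).
#' @return a `ChainSet`: list with `chains` (chain_id, names, strand, spans,
#'   score), `blocks` (gap-free blocks per chain), `net` (blocks truncated to
#'   owned target space), `tlens`, `qlens`.
#' @export
build_chains <- function(alignments, max_join_gap = 100000L,
                         join_slop = 1000L, max_join_drift = 5000L) {
  if (nrow(alignments) == 0) {
    return(structure(list(chains = data.frame(), blocks = data.frame(),
                          net = data.frame(), tlens = integer(),
                          qlens = integer()),
                     class = "ChainSet"))
  }
  validate_paf(alignments)
  aln <- alignments
  # enforce gap-free blocks
  qspan <- aln$qend - aln$qstart; tspan <- aln$tend - aln$tstart
  n <- pmin(qspan, tspan)
  fix <- which(qspan != tspan)
  for (i in fix) {
    if (aln$strand[i] == "+") {
      aln$qend[i] <- aln$qstart[i] + n[i]
      aln$tend[i] <- aln$tstart[i] + n[i]
    } else {
      # target left edge pairs with query right edge on the minus strand
      aln$tend[i] <- aln$tstart[i] + n[i]
      aln$qstart[i] <- aln$qend[i] - n[i]
    }
  }
  aln$nmatch <- pmin(aln$nmatch, n)
  key <- paste(aln$qname, aln$tname, aln$strand, sep = "\r")
  groups <- split(seq_len(nrow(aln)), key)
  chain_id <- integer(nrow(aln))
  next_id <- 0L
  for (g in groups) {
    idx <- g[order(aln$tstart[g], aln$qstart[g])]
    # several chains may be open at once (spurious repeat cross-matches
    # interleave with the true chain on the target axis); each record joins
    # the co-linear open chain with the smallest diagonal drift
    open_te <- integer(0); open_qe <- integer(0); open_qs <- integer(0)
    open_id <- integer(0); open_score <- numeric(0)
    for (i in idx) {
      fwd <- aln$strand[i] == "+"
      tgap <- aln$tstart[i] - open_te
      qgap <- if (fwd) aln$qstart[i] - open_qe else open_qs - aln$qend[i]
      # modest negative gaps (X-drop overshoot at indel boundaries) are
      # tolerated and trimmed away below
      span_i <- aln$tend[i] - aln$tstart[i]
      okc <- which(tgap >= -min(join_slop, span_i %/% 2L) &
                     tgap <= max_join_gap &
                     qgap >= -min(join_slop, span_i %/% 2L) &
                     qgap <= max_join_gap &
                     abs(qgap - tgap) <= max_join_drift)
      if (length(okc)) {
        # attach to the strongest eligible open chain (repeat-slippage
        # fragments are weak), then the nearest, then least diagonal drift
        pick <- okc[order(-open_score[okc],
                          pmax(tgap[okc], 0) + pmax(qgap[okc], 0),
                          abs(qgap[okc] - tgap[okc]))][1]
        cur <- open_id[pick]
        d <- max(0L, -tgap[pick], -qgap[pick])
        if (d > 0) {
          if (aln$tend[i] - aln$tstart[i] <= d) { chain_id[i] <- 0L; next }
          aln$tstart[i] <- aln$tstart[i] + d
          if (fwd) aln$qstart[i] <- aln$qstart[i] + d
          else aln$qend[i] <- aln$qend[i] - d
          aln$nmatch[i] <- min(aln$nmatch[i], aln$tend[i] - aln$tstart[i])
        }
      } else {
        next_id <- next_id + 1L
        cur <- next_id
        open_id <- c(open_id, cur)
        open_te <- c(open_te, -1L); open_qe <- c(open_qe, -1L)
        open_qs <- c(open_qs, .Machine$integer.max)
        open_score <- c(open_score, 0)
        pick <- length(open_id)
      }
      chain_id[i] <- cur
      open_te[pick] <- aln$tend[i]
      open_qe[pick] <- aln$qend[i]
      open_qs[pick] <- aln$qstart[i]
      open_score[pick] <- open_score[pick] + aln$nmatch[i]
    }
  }
  aln$chain_id <- chain_id
  aln <- aln[aln$chain_id > 0L, , drop = FALSE]
  blocks <- aln[, c("chain_id", "qname", "tname", "strand",
                    "qstart", "qend", "tstart", "tend", "nmatch")]
  chains <- do.call(rbind, lapply(split(blocks, blocks$chain_id), function(d) {
    data.frame(chain_id = d$chain_id[1], qname = d$qname[1],
               tname = d$tname[1], strand = d$strand[1],
               qstart = min(d$qstart), qend = max(d$qend),
               tstart = min(d$tstart), tend = max(d$tend),
               score = sum(d$nmatch), nblocks = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(chains) <- NULL
  tlens <- tapply(aln$tlen, aln$tname, max)
  qlens <- tapply(aln$qlen, aln$qname, max)
  cs <- structure(list(chains = chains,
                       blocks = blocks[, c("chain_id", "qname", "tname",
                                           "strand", "qstart", "qend",
                                           "tstart", "tend")],
                       tlens = tlens, qlens = qlens),
                  class = "ChainSet")
  cs$net <- net_chains(cs)
  cs
}

# Greedy net: descending (score, target span, qname, chain_id); each chain
# keeps only target space not owned by a better chain, blocks truncated.
net_chains <- function(cs) {
  ch <- cs$chains
  ord <- order(-ch$score, -(ch$tend - ch$tstart), ch$qname, ch$chain_id)
  by_chain <- split(seq_len(nrow(cs$blocks)), cs$blocks$chain_id)
  owned <- list()  # per tname IRanges
  out <- list()
  for (i in ord) {
    cid <- ch$chain_id[i]; tn <- ch$tname[i]
    b <- cs$blocks[by_chain[[as.character(cid)]], , drop = FALSE]
    have <- owned[[tn]]
    if (is.null(have)) have <- IRanges::IRanges()
    br <- IRanges::IRanges(b$tstart + 1L, b$tend)
    free <- IRanges::setdiff(br, have)
    if (length(free) == 0) next
    hits <- IRanges::findOverlaps(free, br)
    if (length(hits) == 0) next
    fi <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    piece_s <- pmax(IRanges::start(free)[fi] - 1L, b$tstart[bi])
    piece_e <- pmin(IRanges::end(free)[fi], b$tend[bi])
    keep <- piece_e > piece_s
    fi <- fi[keep]; bi <- bi[keep]
    piece_s <- piece_s[keep]; piece_e <- piece_e[keep]
    qs <- qe <- integer(length(bi))
    fwd <- b$strand[bi] == "+"
    qs[fwd] <- b$qstart[bi][fwd] + (piece_s[fwd] - b$tstart[bi][fwd])
    qe[fwd] <- b$qstart[bi][fwd] + (piece_e[fwd] - b$tstart[bi][fwd])
    qe[!fwd] <- b$qend[bi][!fwd] - (piece_s[!fwd] - b$tstart[bi][!fwd])
    qs[!fwd] <- b$qend[bi][!fwd] - (piece_e[!fwd] - b$tstart[bi][!fwd])
    out[[length(out) + 1L]] <- data.frame(
      chain_id = cid, qname = b$qname[bi], tname = tn,
      strand = b$strand[bi], qstart = qs, qend = qe,
      tstart = piece_s, tend = piece_e, stringsAsFactors = FALSE)
    owned[[tn]] <- IRanges::reduce(c(have, IRanges::IRanges(piece_s + 1L,
                                                            piece_e)))
  }
  if (!length(out)) return(cs$blocks[0, , drop = FALSE])
  net <- do.call(rbind, out)
  net <- net[order(net$tname, net$tstart), , drop = FALSE]
  rownames(net) <- NULL
  net
}

#' Map target positions through a netted chain set
#'
#' Vectorized liftover of 0-based target positions. A position inside an
#' owned block maps by linear offset (reflectively on minus-strand blocks: a
#' single base maps to the coordinate of the base it aligns to). Positions
#' falling between blocks of the owning chain report reason `deleted`;
#' positions in target space owned by no chain report `unaligned`.
#'
#' @param chainset a `ChainSet` from [build_chains()].
#' @param chrom,pos vectors of target sequence names and 0-based positions.
#' @return data.frame: chrom, pos, mapped (logical), qname, qpos, strand,
#'   chain_id, reason.
#' @export
map_positions <- function(chainset, chrom, pos) {
  known <- names(chainset$tlens)
  bad <- setdiff(unique(chrom), known)
  if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
  net <- chainset$net
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = pos, mapped = FALSE,
                    qname = NA_character_, qpos = NA_integer_,
                    strand = NA_character_, chain_id = NA_integer_,
                    reason = "unaligned", stringsAsFactors = FALSE)
  if (nrow(net) == 0 || n == 0) return(out)
  qgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  bgr <- GenomicRanges::GRanges(net$tname,
                                IRanges::IRanges(net$tstart + 1L, net$tend))
  hits <- GenomicRanges::findOverlaps(qgr, bgr, select = "first")
  hit <- !is.na(hits)
  bi <- hits[hit]
  fwd <- net$strand[bi] == "+"
  qpos <- integer(sum(hit))
  qpos[fwd] <- net$qstart[bi][fwd] + (pos[hit][fwd] - net$tstart[bi][fwd])
  qpos[!fwd] <- net$qend[bi][!fwd] - 1L - (pos[hit][!fwd] - net$tstart[bi][!fwd])
  out$mapped[hit] <- TRUE
  out$qname[hit] <- net$qname[bi]
  out$qpos[hit] <- qpos
  out$strand[hit] <- net$strand[bi]
  out$chain_id[hit] <- net$chain_id[bi]
  out$reason[hit] <- NA_character_
  # distinguish deleted (inside an owning chain's span) from unaligned
  if (any(!hit)) {
    spans <- do.call(rbind, lapply(split(net, net$chain_id), function(d) {
      data.frame(tname = d$tname[1], tstart = min(d$tstart),
                 tend = max(d$tend), stringsAsFactors = FALSE)
    }))
    sgr <- GenomicRanges::GRanges(spans$tname,
                                  IRanges::IRanges(spans$tstart + 1L,
                                                   spans$tend))
    inside <- IRanges::overlapsAny(qgr[!hit], sgr)
    out$reason[!hit][inside] <- "deleted"
  }
  out
}

#' Map a single target position
#'
#' Scalar convenience wrapper around [map_positions()].
#'
#' @inheritParams map_positions
#' @return list with `chrom`, `pos`, `strand` on success, else `reason`
#'   (`deleted` or `unaligned`); field `mapped` always present.
#' @export
map_position <- function(chainset, chrom, pos) {
  m <- map_positions(chainset, chrom, pos)
  if (m$mapped) {
    list(mapped = TRUE, chrom = m$qname, pos = m$qpos, strand = m$strand,
         chain_id = m$chain_id)
  } else {
    list(mapped = FALSE, reason = m$reason)
  }
}

#' Map a target interval through the net
#'
#' Maps both endpoints; fails (with a reason) if they land on different
#' chains or strands, or if the mapped length differs from the source length
#' by more than `max_len_ratio` in either direction.
#'
#' @param chainset a `ChainSet`.
#' @param chrom target sequence name.
#' @param start,end 0-based half-open interval.
#' @param max_len_ratio tolerated mapped/source length ratio (default 2).
#' @return list: `mapped`, then `chrom`, `start`, `end`, `strand` or `reason`
#'   (`split`, `deleted`, `unaligned`, `length_ratio`).
#' @export
map_interval <- function(chainset, chrom, start, end, max_len_ratio = 2) {
  check_that(start < end, "interval start must be < end")
  m <- map_positions(chainset, c(chrom, chrom), c(start, end - 1L))
  if (!all(m$mapped)) {
    return(list(mapped = FALSE,
                reason = m$reason[!m$mapped][1]))
  }
  if (m$chain_id[1] != m$chain_id[2] || m$strand[1] != m$strand[2]) {
    return(list(mapped = FALSE, reason = "split"))
  }
  if (m$strand[1] == "+") {
    qs <- m$qpos[1]; qe <- m$qpos[2] + 1L
  } else {
    qs <- m$qpos[2]; qe <- m$qpos[1] + 1L
  }
  if (qe <= qs) return(list(mapped = FALSE, reason = "split"))
  ratio <- (qe - qs) / (end - start)
  if (ratio > max_len_ratio || ratio < 1 / max_len_ratio) {
    return(list(mapped = FALSE, reason = "length_ratio"))
  }
  list(mapped = TRUE, chrom = m$qname[1], start = qs, end = qe,
       strand = m$strand[1])
}

#' Swap query and target roles of a PAF table
#'
#' Produces the alignments of the reciprocal direction; with PAF semantics
#' the swap is symmetric on both strands.
#'
#' @param aln PAF data frame.
#' @return PAF data frame with query and target exchanged.
#' @export
invert_alignments <- function(aln) {
  out <- aln
  out$qname <- aln$tname; out$qlen <- aln$tlen
  out$qstart <- aln$tstart; out$qend <- aln$tend
  out$tname <- aln$qname; out$tlen <- aln$qlen
  out$tstart <- aln$qstart; out$tend <- aln$qend
  out
}

#' Per-query uniqueness of placement in the net
#'
#' For each query sequence, the fraction of its netted aligned bases that
#' fall in its best single target locus. A locus is a cluster of netted
#' target intervals separated by less than `locus_gap` on one target
#' sequence, so a chain fragmented by repeat breaks still counts as one
#' placement. A query is "unique" when the top-locus fraction is at least
#' `min_frac` — the operational form of the "aligns to one unique location"
#' criterion.
#'
#' @param chainset a `ChainSet`.
#' @param min_frac minimum top-locus fraction (default 0.9).
#' @param locus_gap maximum separation (bp) between netted intervals merged
#'   into one locus (default 100 kb).
#' @return data.frame: qname, total_bp, top_bp, top_tname, unique.
#' @export
scaffold_uniqueness <- function(chainset, min_frac = 0.9,
                                locus_gap = 100000L) {
  net <- chainset$net
  if (nrow(net) == 0)
    return(data.frame(qname = character(), total_bp = integer(),
                      top_bp = integer(), top_tname = character(),
                      unique = logical(), stringsAsFactors = FALSE))
  net$w <- net$qend - net$qstart
  out <- do.call(rbind, lapply(split(net, net$qname), function(d) {
    locus_w <- c()
    for (tn in unique(d$tname)) {
      dt <- d[d$tname == tn, , drop = FALSE]
      ir <- IRanges::IRanges(dt$tstart + 1L, dt$tend)
      red <- IRanges::reduce(ir, min.gapwidth = locus_gap)
      grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red,
                                                          select = "all"))
      w <- tapply(dt$w, grp, sum)
      names(w) <- paste0(tn, ":", names(w))
      locus_w <- c(locus_w, w)
    }
    tot <- sum(locus_w); top <- which.max(locus_w)
    data.frame(qname = d$qname[1], total_bp = tot,
               top_bp = unname(locus_w[top]),
               top_tname = sub(":.*$", "", names(locus_w)[top]),
               unique = locus_w[top] / tot >= min_frac,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Query intervals not covered by the net
#'
#' Complement, per query sequence, of the netted blocks' query projections —
#' the "unaligned sequence" of the query assembly under this alignment method.
#'
#' @param chainset a `ChainSet`.
#' @param qlens named lengths of the query sequences (defaults to lengths
#'   recorded in the chain set).
#' @return interval data.frame: chrom (query name), start, end.
#' @export
query_unaligned <- function(chainset, qlens = chainset$qlens) {
  out <- list()
  for (qn in names(qlens)) {
    b <- chainset$net[chainset$net$qname == qn, , drop = FALSE]
    covered <- if (nrow(b)) IRanges::reduce(IRanges::IRanges(b$qstart + 1L,
                                                             b$qend))
    else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, qlens[[qn]]), covered)
    if (length(gaps))
      out[[length(out) + 1L]] <- data.frame(
        chrom = qn, start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
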