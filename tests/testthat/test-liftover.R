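# hand-built PAF rows for chain construction
paf_row <- function(qname, qlen, qs, qe, strand, tname, tlen, ts, te,
                    nm = NULL) {
  n <- min(qe - qs, te - ts)
  data.frame(qname = qname, qlen = qlen, qstart = qs, qend = qe,
             strand = strand, tname = tname, tlen = tlen, tstart = ts,
             tend = te, nmatch = if (is.null(nm)) n else nm,
             blocklen = max(qe - qs, te - ts), mapq = 60L,
             stringsAsFactors = FALSE)
}

empty_paf_df <- function() {
  paf_row("q", 10L, 0L, 5L, "+", "t", 10L, 0L, 5L)[0, ]
}

test_that("empty alignment input gives an empty chain set", {
  cs <- build_chains(empty_paf_df())
  expect_equal(nrow(cs$net), 0L)
})

test_that("one identity alignment owns the whole target", {
  cs <- build_chains(paf_row("q", 1000L, 0L, 1000L, "+", "t", 1000L, 0L,
                             1000L))
  expect_equal(nrow(cs$chains), 1L)
  expect_equal(sum(cs$net$tend - cs$net$tstart), 1000L)
  m <- map_position(cs, "t", 150L)
  expect_true(m$mapped)
  expect_equal(m$pos, 150L)
  expect_equal(m$strand, "+")
})

test_that("netting gives overlap to the higher-scoring chain", {
  # chain A: q1 covers t[0,1000); chain B: q2 covers t[600,1000) (overlap 400)
  aln <- rbind(paf_row("q1", 1000L, 0L, 1000L, "+", "t", 1000L, 0L, 1000L),
               paf_row("q2", 400L, 0L, 400L, "+", "t", 1000L, 600L, 1000L))
  cs <- build_chains(aln)
  # brute-force per-base ownership: every base should belong to exactly the
  # top chain where covered by both
  own <- rep(NA_character_, 1000)
  for (i in seq_len(nrow(cs$net))) {
    span <- (cs$net$tstart[i] + 1):cs$net$tend[i]
    expect_true(all(is.na(own[span])))  # single ownership
    own[span] <- cs$net$qname[i]
  }
  expect_true(all(own[1:1000] == "q1"))
  # q2's chain kept nothing: the stronger chain spans its whole interval
  expect_false("q2" %in% cs$net$qname)
})

test_that("lower-scoring chain keeps its non-overlapped remainder", {
  aln <- rbind(paf_row("q1", 600L, 0L, 600L, "+", "t", 1000L, 0L, 600L),
               paf_row("q2", 800L, 0L, 800L, "+", "t", 1000L, 200L, 1000L))
  cs <- build_chains(aln)
  # q2 (800) wins its span; q1 keeps [0,200)
  q1own <- cs$net[cs$net$qname == "q1", ]
  expect_equal(sum(q1own$tend - q1own$tstart), 200L)
  expect_equal(q1own$tend, 200L)
})

test_that("co-linear disjoint alignments merge into one chain", {
  aln <- rbind(paf_row("q", 2000L, 0L, 800L, "+", "t", 2100L, 0L, 800L),
               paf_row("q", 2000L, 900L, 2000L, "+", "t", 2100L, 1000L,
                       2100L))
  cs <- build_chains(aln)
  expect_equal(nrow(cs$chains), 1L)
  expect_equal(cs$chains$nblocks, 2L)
  # non-co-linear (query order flipped) must not merge
  aln2 <- rbind(paf_row("q", 2000L, 1200L, 2000L, "+", "t", 2100L, 0L, 800L),
                paf_row("q", 2000L, 0L, 800L, "+", "t", 2100L, 1000L, 1800L))
  expect_equal(nrow(build_chains(aln2)$chains), 2L)
})

test_that("positions in a chain's inter-block gap report deleted", {
  # 5 bp target-only gap at offset 100: blocks t[0,100) and t[105,200)
  aln <- rbind(paf_row("q", 195L, 0L, 100L, "+", "t", 200L, 0L, 100L),
               paf_row("q", 195L, 100L, 195L, "+", "t", 200L, 105L, 200L))
  cs <- build_chains(aln)
  expect_equal(nrow(cs$chains), 1L)
  m <- map_position(cs, "t", 150L)
  expect_equal(m$pos, 145L)
  m2 <- map_position(cs, "t", 102L)
  expect_false(m2$mapped)
  expect_equal(m2$reason, "deleted")
  expect_error(map_position(cs, "chrX", 5L), "unknown chromosome")
})

test_that("reverse-strand mapping reflects coordinates", {
  cs <- build_chains(paf_row("q", 1000L, 0L, 1000L, "-", "t", 1000L, 0L,
                             1000L))
  expect_equal(map_position(cs, "t", 0L)$pos, 999L)
  expect_equal(map_position(cs, "t", 999L)$pos, 0L)
  expect_equal(map_position(cs, "t", 150L)$strand, "-")
})

test_that("interval mapping handles identity, splits and deletions", {
  aln <- rbind(paf_row("q", 195L, 0L, 100L, "+", "t", 200L, 0L, 100L),
               paf_row("q", 195L, 100L, 195L, "+", "t", 200L, 105L, 200L))
  cs <- build_chains(aln)
  ident <- map_interval(cs, "t", 10L, 60L)
  expect_true(ident$mapped)
  expect_equal(c(ident$start, ident$end), c(10L, 60L))
  # interval spanning the 5 bp deletion maps with length -5
  del <- map_interval(cs, "t", 90L, 120L)
  expect_true(del$mapped)
  expect_equal(del$end - del$start, 25L)
  # two separate chains -> split
  aln2 <- rbind(paf_row("q1", 100L, 0L, 100L, "+", "t", 400L, 0L, 100L),
                paf_row("q2", 100L, 0L, 100L, "+", "t", 400L, 300L, 400L))
  cs2 <- build_chains(aln2)
  sp <- map_interval(cs2, "t", 50L, 350L)
  expect_false(sp$mapped)
})

test_that("round trip through both netting directions is identity", {
  sim <- small_sim(seed = 7)
  paf <- small_paf(seed = 7)
  fwd <- small_chainset(seed = 7)
  bwd <- build_chains(invert_alignments(paf))
  set.seed(99)
  pts <- sort(sample.int(sim$cfg$chrom_length - 1L, 300L)) - 1L
  # tandem duplications are inherently ambiguous (either copy is a valid
  # image), so exactness is asserted outside planted DUP neighborhoods
  dup <- sim$truth$svs[sim$truth$svs$svtype == "DUP", , drop = FALSE]
  amb <- rep(FALSE, length(pts))
  for (i in seq_len(nrow(dup)))
    amb <- amb | (pts >= dup$start[i] - 2000L & pts < dup$end[i] + 2000L)
  m <- map_positions(fwd, rep("chr1", length(pts)), pts)
  ok <- which(m$mapped)
  expect_gt(length(ok), 200)  # most of the genome lifts
  back <- map_positions(bwd, m$qname[ok], m$qpos[ok])
  agree <- back$mapped & back$qname == "chr1" & back$qpos == pts[ok]
  expect_true(all(agree[!amb[ok]]))
  expect_gte(mean(agree), 0.99)
})

test_that("net ownership is disjoint by interval sweep", {
  sim <- small_sim(seed = 7)
  cs <- small_chainset(seed = 7)
  for (tn in unique(cs$net$tname)) {
    b <- cs$net[cs$net$tname == tn, ]
    b <- b[order(b$tstart), ]
    expect_true(all(b$tstart[-1] >= b$tend[-nrow(b)]))
  }
  expect_lte(sum(cs$net$tend - cs$net$tstart), sum(cs$tlens))
})

test_that("mapping is monotone within a forward chain", {
  sim <- small_sim(seed = 7)
  cs <- small_chainset(seed = 7)
  top <- cs$chains$chain_id[which.max(cs$chains$score)]
  stopifnot(cs$chains$strand[cs$chains$chain_id == top] == "+")
  b <- cs$net[cs$net$chain_id == top, ]
  pts <- sort(c(b$tstart, b$tend - 1L))
  m <- map_positions(cs, rep(b$tname[1], length(pts)), pts)
  expect_true(all(diff(m$qpos[m$mapped]) > 0))
})
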