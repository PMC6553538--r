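test_that("find_gaps reports planted N-runs and honors exclusion masks", {
  ref <- c(chr1 = paste0(strrep("A", 50), strrep("N", 20), strrep("C", 50),
                         strrep("N", 9), strrep("G", 30)),
           chr2 = paste0(strrep("T", 40), strrep("N", 15), strrep("A", 40)))
  g <- find_gaps(ref)
  expect_equal(nrow(g), 2L)            # the 9 bp run is below threshold
  expect_equal(g$start, c(50L, 40L))
  expect_equal(g$length, c(20L, 15L))
  # gap inside an excluded interval is omitted
  g2 <- find_gaps(ref, exclude = data.frame(chrom = "chr2", start = 30L,
                                            end = 60L))
  expect_equal(g2$chrom, "chr1")
})

test_that("1-based coordinate reports imply end - start + 1 lengths", {
  # the coordinate convention: a gap reported as 172,624,657-172,626,416
  # (1-based inclusive) has length 1,760
  start1 <- 172624657; end1 <- 172626416
  expect_equal(end1 - start1 + 1, 1760)
  # internal half-open gap [start0, end0) reports start0+1 .. end0
  ref <- c(chr = paste0(strrep("A", 100), strrep("N", 25), strrep("C", 100)))
  g <- find_gaps(ref)
  expect_equal(g$end - g$start, g$length)
  expect_equal(sprintf("%d-%d", g$start + 1, g$end), "101-125")
})

test_that("padding clips at chromosome bounds", {
  gaps <- data.frame(gap_id = 1:2, chrom = "chr1",
                     start = c(10000L, 60000L), end = c(10100L, 60400L),
                     length = c(100L, 400L))
  p <- pad_gaps(gaps, flank = 50000L, chrom_lens = c(chr1 = 80000L))
  expect_equal(p$pstart, c(0L, 10000L))
  expect_equal(p$pend, c(60100L, 80000L))
  p2 <- pad_gaps(gaps[2, ], flank = 5000L, chrom_lens = c(chr1 = 80000L))
  expect_equal(p2$pend - p2$pstart, 400L + 10000L)
})

test_that("candidate filters enforce RBH, threshold boundary and uniqueness", {
  padded <- data.frame(gap_id = 1:2, chrom = "chr1",
                       start = c(100L, 900L), end = c(200L, 1000L),
                       length = c(100L, 100L),
                       pstart = c(0L, 800L), pend = c(300L, 1100L),
                       region = c("r1", "r2"), stringsAsFactors = FALSE)
  mk <- function(q, t, nm) data.frame(
    qname = q, qlen = 10000L, qstart = 0L, qend = nm, strand = "+",
    tname = t, tlen = 300L, tstart = 0L, tend = nm, nmatch = nm,
    blocklen = nm, mapq = 60L, stringsAsFactors = FALSE)
  # s1 is best for r1 and vice versa; s2's best region is r1 (not r2)
  aln <- rbind(mk("s1", "r1", 250L), mk("s2", "r1", 100L),
               mk("s2", "r2", 90L))
  res <- filter_candidates(aln, padded, min_total_aln = 250L)
  expect_equal(res$status[1], "candidate")   # threshold inclusive at 250
  expect_equal(res$status[2], "not_reciprocal")
  # exact threshold boundary: just below excludes
  res2 <- filter_candidates(aln, padded, min_total_aln = 251L)
  expect_equal(res2$status[1], "below_min_aln")
  # uniqueness criterion (c)
  uq <- data.frame(qname = "s1", total_bp = 1000L, top_bp = 500L,
                   top_chain = 1L, unique = FALSE)
  res3 <- filter_candidates(aln, padded, min_total_aln = 100L,
                            uniqueness = uq)
  expect_equal(res3$status[1], "not_unique")
})

test_that("a duplicated scaffold placement fails the uniqueness map", {
  # scaffold aligning equally to two target loci -> top fraction 0.5
  aln <- rbind(
    data.frame(qname = "s", qlen = 2000L, qstart = 0L, qend = 1000L,
               strand = "+", tname = "t", tlen = 10000L, tstart = 0L,
               tend = 1000L, nmatch = 1000L, blocklen = 1000L, mapq = 60L),
    data.frame(qname = "s", qlen = 2000L, qstart = 0L, qend = 1000L,
               strand = "+", tname = "t", tlen = 10000L, tstart = 5000L,
               tend = 6000L, nmatch = 1000L, blocklen = 1000L, mapq = 60L))
  cs <- build_chains(aln)
  uq <- scaffold_uniqueness(cs, locus_gap = 1000L)
  expect_false(uq$unique)
  expect_equal(uq$top_bp / uq$total_bp, 0.5)
})

test_that("worked gap examples give the reported discrepancies", {
  # 1,760 bp gap filled by 1,620 bp -> 140 bp relative deletion
  expect_equal(1620 - 1760, -140)
  # 100 bp gap at Chr1:183,334,907-183,335,006 filled by 595 bp -> +495
  expect_equal(183335006 - 183334907 + 1, 100)
  expect_equal(595 - 100, 495)
})

test_that("end-to-end gap filling recovers every planted fill exactly", {
  sim <- small_sim(seed = 7)
  cs <- small_chainset(seed = 7)
  gf <- gapfill_run(sim$ref$sequences, sim$asm$sequences,
                    flank = sim$cfg$flank,
                    min_total_aln = sim$cfg$min_total_aln, chainset = cs)
  tr <- sim$truth$gaps[order(sim$truth$gaps$gap_id), ]
  fl <- gf$fills[order(gf$fills$gap_id), ]
  expect_equal(nrow(fl), nrow(tr))
  expect_true(all(fl$confirmed))
  expect_identical(fl$fill, tr$fill)
  expect_equal(fl$discrepancy, tr$discrepancy)
  expect_equal(fl$scaffold, tr$scaffold)
})

test_that("raising the alignment threshold never increases candidates", {
  sim <- small_sim(seed = 7)
  gaps <- find_gaps(sim$ref$sequences)
  padded <- pad_gaps(gaps, flank = sim$cfg$flank,
                     chrom_lens = vapply(sim$ref$sequences, nchar, 1L))
  regions <- extract_regions(sim$ref$sequences, padded)
  aln <- align_genomes(sim$asm$sequences, regions)
  n_cand <- vapply(c(0L, 2000L, 5000L, 8000L, 20000L), function(th) {
    sum(filter_candidates(aln, padded, min_total_aln = th)$status ==
          "candidate")
  }, 1L)
  expect_true(all(diff(n_cand) <= 0))
})

test_that("reciprocity check is symmetric between directions", {
  sim <- small_sim(seed = 7)
  gaps <- find_gaps(sim$ref$sequences)
  padded <- pad_gaps(gaps, flank = sim$cfg$flank,
                     chrom_lens = vapply(sim$ref$sequences, nchar, 1L))
  regions <- extract_regions(sim$ref$sequences, padded)
  fwd <- align_genomes(sim$asm$sequences, regions)
  rec <- align_genomes(regions, sim$asm$sequences)
  cand <- filter_candidates(fwd, padded,
                            min_total_aln = sim$cfg$min_total_aln)
  i <- which(cand$status == "candidate")[1]
  a <- confirm_and_extract(cand[i, ], rec, fwd, sim$asm$sequences)
  expect_true(a$confirmed)
  # swapped roles: the mirrored candidate confirms too, with negated delta
  # (region ~ query of the forward set is the scaffold there)
  expect_equal(a$fill_len - cand$length[i], a$discrepancy)
})
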