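sv <- function(chrom, start, end, type, caller, size = NULL) {
  data.frame(chrom = chrom, start = start, end = end, svtype = type,
             size = if (is.null(size)) end - start else size,
             caller = caller, stringsAsFactors = FALSE)
}

test_that("identical calls merge into one support-2 record", {
  a <- sv("chr1", 100L, 600L, "DEL", "pb")
  b <- sv("chr1", 100L, 600L, "DEL", "il")
  m <- merge_callsets(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 2L)
  expect_equal(m$callers, "pb,il")
})

test_that("type mismatch blocks merging under type matching", {
  a <- sv("chr1", 100L, 600L, "DEL", "pb")
  b <- sv("chr1", 100L, 600L, "DUP", "il")
  m <- merge_callsets(a, b)
  expect_equal(nrow(m), 2L)
  expect_true(all(m$support == 1L))
  m2 <- merge_callsets(a, b, require_type_match = FALSE)
  expect_equal(nrow(m2), 1L)
})

test_that("breakpoint distance is inclusive at the bound", {
  a <- sv("chr1", 1000L, 5000L, "DEL", "pb")
  at <- merge_callsets(a, sv("chr1", 2000L, 6000L, "DEL", "il"),
                       max_breakpoint_dist = 1000L)
  expect_equal(sum(at$support == 2), 1L)        # exactly 1,000 -> merge
  over <- merge_callsets(a, sv("chr1", 2001L, 6000L, "DEL", "il"),
                         max_breakpoint_dist = 1000L)
  expect_equal(sum(over$support == 2), 0L)      # 1,001 -> no merge
  # per-event oracle on a toy set: events spaced far apart so matching
  # cannot cross events
  a2 <- sv("chr1", seq(10000L, by = 10000L, length.out = 8L), 0L, "DEL",
           "pb")
  a2$end <- a2$start + 500L; a2$size <- 500L
  b2 <- a2
  b2$start <- b2$start + c(-1500L, -800L, 0L, 900L, 1600L, 200L,
                           -100L, 50L)
  b2$end <- b2$start + 500L
  b2$caller <- "il"
  m <- merge_callsets(a2, b2, max_breakpoint_dist = 1000L)
  mergeable <- sum(abs(b2$start - a2$start) <= 1000L)
  expect_equal(sum(m$support == 2), mergeable)
})

test_that("merging is symmetric and self-merge is total", {
  sim <- small_sim(seed = 7)
  cls <- simulate_sv_callsets(sim$truth, sim$cfg)
  ab <- merge_callsets(cls$longread, cls$shortread)
  ba <- merge_callsets(cls$shortread, cls$longread)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sum(ab$support == 2), sum(ba$support == 2))
  self <- merge_callsets(cls$longread, cls$longread)
  expect_equal(nrow(self), nrow(cls$longread))
  expect_true(all(self$support == 2L))
})

test_that("widening the merge distance never shrinks the common set", {
  sim <- small_sim(seed = 7)
  cls <- simulate_sv_callsets(sim$truth, sim$cfg)
  common <- vapply(c(0L, 10L, 100L, 1000L, 5000L), function(d)
    sum(merge_callsets(cls$longread, cls$shortread,
                       max_breakpoint_dist = d)$support == 2), 1L)
  expect_true(all(diff(common) >= 0))
})

test_that("consensus of simulated callsets recovers planted truth per class", {
  sim <- small_sim(seed = 7)
  cls <- simulate_sv_callsets(sim$truth, sim$cfg)
  m <- merge_callsets(cls$longread, cls$shortread)
  common <- m[m$support == 2, ]
  truth_non_ins <- sim$truth$svs[sim$truth$svs$svtype != "INS", ]
  expect_equal(as.vector(table(common$svtype)[c("DEL", "DUP", "INV")]),
               as.vector(table(truth_non_ins$svtype)[c("DEL", "DUP",
                                                       "INV")]))
})

test_that("summaries use the lower median and count gene overlap", {
  s <- rbind(sv("chr1", 0L, 901L, "DUP", "x", size = 901L),
             sv("chr1", 1000L, 1001L, "INS", "x", size = 1L),
             sv("chr1", 2000L, 2002L, "INS", "x", size = 2L),
             sv("chr1", 3000L, 3003L, "INS", "x", size = 3L),
             sv("chr1", 4000L, 4004L, "INS", "x", size = 4L))
  genes <- data.frame(chrom = "chr1", start = 850L, end = 950L)
  out <- summarize_sv(s, genes)
  expect_equal(out$median_size[out$svtype == "DUP"], 901)
  expect_equal(out$median_size[out$svtype == "INS"], 2)  # lower median of 1:4
  expect_equal(out$n_gene_overlap[out$svtype == "DUP"], 1L)
  expect_equal(out$n[out$svtype == "DEL"], 0L)
  expect_true(is.na(out$median_size[out$svtype == "DEL"]))
})

test_that("SV callsets round-trip through TSV and parse from VCF INFO", {
  p <- withr::local_tempfile(fileext = ".tsv")
  a <- rbind(sv("chr1", 100L, 600L, "DEL", "pb"),
             sv("chr2", 50L, 51L, "INS", "pb", size = 120L))
  write.table(a[, 1:5], p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_sv_callset(p, caller = "pb")
  expect_equal(back, a)
  pv <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="x">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t101\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600;SVLEN=-500",
    "chr1\t900\t.\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=120"), pv)
  v <- read_sv_callset(pv, caller = "pb")
  expect_equal(v$svtype, c("DEL", "INS"))
  expect_equal(v$start[1], 100L)
  expect_equal(v$end[1], 600L)
  expect_equal(v$size, c(500L, 120L))
})
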