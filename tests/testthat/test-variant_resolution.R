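mk_vcf <- function(gt_rows, pos = NULL) {
  n <- nrow(gt_rows)
  sites <- data.frame(chrom = "chr1",
                      pos = if (is.null(pos)) seq(100, by = 100,
                                                  length.out = n) else pos,
                      ref = rep("A", n), alt = rep("T", n),
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, gt = gt_rows,
                 samples = colnames(gt_rows)), class = "multi_vcf")
}

test_that("recurrence selection is inclusive at the threshold", {
  gt <- rbind(c("hom-alt", "hom-alt", "hom-alt", "hom-ref"),   # 0.75
              c("hom-alt", "hom-alt", "het", "hom-alt"),       # het present
              c("hom-alt", "hom-alt", "hom-ref", "hom-ref"))   # 0.5
  colnames(gt) <- paste0("s", 1:4)
  v <- mk_vcf(gt)
  sel <- select_recurring(v, min_frac = 0.75, homozygous_only = TRUE)
  expect_equal(sel$pos, 100)
  expect_equal(sel$recurrence, 0.75)
  # without the homozygosity restriction, the het row passes too
  sel2 <- select_recurring(v, min_frac = 0.75, homozygous_only = FALSE)
  expect_setequal(sel2$pos, c(100, 200))
})

test_that("missing genotypes are excluded from the recurrence denominator", {
  gt <- rbind(c("hom-alt", "hom-alt", "hom-alt", "missing"),
              c("hom-alt", "missing", "missing", "missing"))
  colnames(gt) <- paste0("s", 1:4)
  sel <- select_recurring(mk_vcf(gt), min_frac = 0.75)
  expect_equal(sel$recurrence, c(1, 1))
  expect_equal(sel$n_informative, c(3L, 1L))
  expect_error(select_recurring(structure(list(sites = NULL,
                                               gt = matrix(nrow = 0, ncol = 0),
                                               samples = character()),
                                          class = "multi_vcf")),
               "zero samples")
})

test_that("raising the recurrence threshold never grows the selected set", {
  sim <- small_sim(seed = 7)
  pan <- make_strain_vcfs(sim$cfg, sim$truth)
  ns <- vapply(c(0.5, 0.75, 0.9, 1), function(th)
    nrow(select_recurring(pan$vcf, min_frac = th)), 1L)
  expect_true(all(diff(ns) <= 0))
})

test_that("selected recurring set equals the planted truth set", {
  sim <- small_sim(seed = 7)
  pan <- make_strain_vcfs(sim$cfg, sim$truth)
  sel <- select_recurring(pan$vcf)
  tr <- pan$truth$recurrent
  planted <- tr[tr$planted %in% c("error", "shared"), ]
  expect_setequal(paste(sel$chrom, sel$pos), paste(planted$chrom, planted$pos))
})

test_that("classification statuses are conserved and truth-faithful", {
  sim <- small_sim(seed = 7)
  pan <- make_strain_vcfs(sim$cfg, sim$truth)
  sel <- select_recurring(pan$vcf)
  cs <- truth_chainset(pan$truth)
  calls <- classify_resolved(sel, cs, sim$asm$sequences)
  expect_equal(sum(calls$status == "resolved") +
                 sum(calls$status == "unresolved") +
                 sum(calls$status == "unmappable"), nrow(sel))
  tr <- pan$truth$recurrent
  key <- paste(tr$chrom, tr$pos)
  planted <- tr$planted[match(paste(calls$chrom, calls$pos), key)]
  expect_true(all(calls$status[planted == "error"] == "resolved"))
  expect_true(all(calls$status[planted == "shared"] == "unresolved"))
  # exact planted reference-error recovery
  expect_equal(sum(calls$status == "resolved"), pan$truth$n_error_sites)
})

test_that("sites outside any chain are unmappable, never an error", {
  cs <- build_chains(data.frame(
    qname = "s", qlen = 1000L, qstart = 0L, qend = 1000L, strand = "+",
    tname = "chr1", tlen = 5000L, tstart = 0L, tend = 1000L,
    nmatch = 1000L, blocklen = 1000L, mapq = 60L))
  v <- data.frame(chrom = "chr1", pos = c(500L, 3000L), ref = "A", alt = "T",
                  stringsAsFactors = FALSE)
  asm <- c(s = random_dna(1000, seed = 50))
  calls <- classify_resolved(v, cs, asm)
  expect_equal(calls$status[2], "unmappable")
  expect_equal(calls$reason[2], "unaligned")
})

test_that("minus-strand mapping compares the reverse-complemented allele", {
  s <- random_dna(400, seed = 51)
  cs <- build_chains(data.frame(
    qname = "s", qlen = 400L, qstart = 0L, qend = 400L, strand = "-",
    tname = "chr1", tlen = 400L, tstart = 0L, tend = 400L,
    nmatch = 400L, blocklen = 400L, mapq = 60L))
  pos <- 100L  # 1-based; maps to s[400 - 100] on the minus strand
  asm_base <- substr(s, 400L - pos + 1L, 400L - pos + 1L)
  v <- data.frame(chrom = "chr1", pos = pos, ref = "A",
                  alt = revcomp(asm_base), stringsAsFactors = FALSE)
  calls <- classify_resolved(v, cs, c(s = s))
  expect_equal(calls$status, "resolved")
})

test_that("resolution summaries reproduce the three reported percentages", {
  fake_calls <- function(res, unres, unmap) {
    data.frame(status = c(rep("resolved", res), rep("unresolved", unres),
                          rep("unmappable", unmap)))
  }
  s1 <- summarize_resolution(fake_calls(10, 116, 0), total_considered = 126)
  expect_equal(s1$resolved_pct, 7.9)
  s2 <- summarize_resolution(fake_calls(307, 2100, 0),
                             total_considered = 2407)
  expect_equal(s2$resolved_pct, 12.8)
  s3 <- summarize_resolution(fake_calls(393, 1801, 1009),
                             total_considered = 3203, denominator = "net")
  expect_equal(s3$denominator, 2194)
  expect_equal(s3$resolved_pct, 17.9)
  expect_equal(s3$net_pct, 68.5)
  expect_error(summarize_resolution(fake_calls(0, 0, 1), denominator = "net"),
               "zero denominator")
})

test_that("CDS indel classification follows the mod-3 rule with FS dominance", {
  gaps <- data.frame(placement = c("t1", "t2", "t3", "t3", "t4"),
                     len = c(3L, 2L, 3L, 1L, 6L),
                     in_cds = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  r <- classify_cds_indels(gaps)
  cls <- setNames(r$per_placement$class, r$per_placement$placement)
  expect_equal(unname(cls[c("t1", "t2", "t3", "t4")]),
               c("NFS", "FS", "FS", "none"))
  expect_equal(r$fs, 2L)
  expect_equal(r$nfs, 1L)
  # hand-enumerated closure: any non-multiple-of-3 gap forces FS
  combos <- expand.grid(a = 1:6, b = 1:6)
  for (i in seq_len(nrow(combos))) {
    g <- data.frame(placement = "p", len = c(combos$a[i], combos$b[i]),
                    in_cds = TRUE)
    expected <- if (any(c(combos$a[i], combos$b[i]) %% 3 != 0)) "FS" else "NFS"
    expect_equal(classify_cds_indels(g)$per_placement$class, expected)
  }
  # gaps located outside CDS intervals are ignored via coordinates
  gaps2 <- data.frame(placement = "t", len = c(2L, 3L), chrom = "chr1",
                      start = c(10L, 100L), end = c(12L, 103L))
  cds <- data.frame(chrom = "chr1", start = 90L, end = 200L)
  expect_equal(classify_cds_indels(gaps2, cds)$per_placement$class, "NFS")
})
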