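test_that("configuration validation rejects bad rates and compositions", {
  expect_error(sim_config(snv_rate = 1.5), "rates")
  expect_error(sim_config(repeat_composition = c(satellite = 0.7,
                                                 microsatellite = 0.2,
                                                 line = 0.2)),
               "sum to more than 1")
})

test_that("zero gaps means no N in the reference", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 50000L, gap_count = 0L,
                    seed = 3)
  ref <- make_reference(cfg)
  expect_false(any(grepl("N", ref$sequences)))
})

test_that("planted gaps appear as maximal N-runs at the recorded coordinates", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 150000L, gap_count = 3L,
                    gap_length_range = c(100L, 100L), flank = 2000L, seed = 4)
  ref <- make_reference(cfg)
  found <- find_gaps(ref$sequences)
  expect_equal(nrow(found), 3L)
  tr <- ref$truth$gaps[order(ref$truth$gaps$start), ]
  expect_equal(found$start, tr$start)
  expect_equal(found$length, rep(100L, 3))
  # the recorded fill is the sequence the N-run replaced
  expect_true(all(nchar(tr$fill) == tr$length))
})

test_that("repeat composition hits its target within two percent", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 1e6, gap_count = 0L,
                    repeat_composition = c(satellite = 0.6), seed = 5)
  ref <- make_reference(cfg)
  sat_bp <- with(ref$repeats[ref$repeats$label == "satellite", ],
                 sum(end - start))
  expect_gte(sat_bp / 1e6, 0.58)
  expect_lte(sat_bp / 1e6, 0.62)
})

test_that("generator output is bit-identical under a fixed seed", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 60000L, gap_count = 2L,
                    gap_length_range = c(100L, 300L), flank = 1500L, seed = 9)
  a <- make_reference(cfg); b <- make_reference(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth$gaps, b$truth$gaps)
  da <- derive_assembly(a, a$truth, cfg)
  db <- derive_assembly(b, b$truth, cfg)
  expect_identical(da$sequences, db$sequences)
})

test_that("assembly length conservation holds exactly", {
  sim <- small_sim(seed = 21)
  expect_identical(sum(nchar(sim$asm$sequences)) -
                     sum(nchar(sim$ref$sequences)),
                   as.integer(sim$truth$length_delta))
})

test_that("zero rates and zero deltas give reference with Ns replaced by fill", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L, gap_count = 2L,
                    gap_length_range = c(100L, 200L), flank = 1500L,
                    fill_delta_prob = 0, snv_rate = 0, indel_rate = 0,
                    sv_spec = data.frame(type = "DEL", count = 0L,
                                         minsize = 100L, maxsize = 200L),
                    seed = 10)
  ref <- make_reference(cfg)
  asm <- derive_assembly(ref, ref$truth, cfg)
  rebuilt <- ref$sequences[[1]]
  for (i in seq_len(nrow(asm$truth$gaps))) {
    g <- asm$truth$gaps[i, ]
    substr(rebuilt, g$start + 1, g$end) <- g$fill
  }
  expect_identical(paste(asm$sequences, collapse = ""), rebuilt)
  expect_true(all(asm$truth$gaps$discrepancy == 0))
})

test_that("planted fill deltas are recorded as gap discrepancies", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 120000L, gap_count = 2L,
                    gap_length_range = c(400L, 500L), flank = 1500L,
                    fill_delta_prob = 1, fill_delta_range = c(140L, 140L),
                    snv_rate = 0, indel_rate = 0,
                    sv_spec = data.frame(type = "DEL", count = 0L,
                                         minsize = 100L, maxsize = 200L),
                    seed = 11)
  ref <- make_reference(cfg)
  asm <- derive_assembly(ref, ref$truth, cfg)
  expect_true(all(abs(asm$truth$gaps$discrepancy) == 140L))
  expect_equal(asm$truth$gaps$fill_len,
               asm$truth$gaps$length + asm$truth$gaps$discrepancy)
})

test_that("planted SNV count is binomially plausible", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 1e6, gap_count = 0L,
                    snv_rate = 1e-3, indel_rate = 0,
                    sv_spec = data.frame(type = "DEL", count = 0L,
                                         minsize = 100L, maxsize = 200L),
                    seed = 12)
  ref <- make_reference(cfg)
  asm <- derive_assembly(ref, ref$truth, cfg)
  n <- nrow(asm$truth$snvs)
  expect_lt(abs(n - 1e6 * 1e-3), 3 * sqrt(1e6 * 1e-3 * (1 - 1e-3)))
  # planted substitutions are real differences at the recorded positions
  idx <- sample.int(n, 50)
  for (i in idx) {
    snv <- asm$truth$snvs[i, ]
    expect_identical(substr(ref$sequences[[snv$chrom]], snv$pos + 1,
                            snv$pos + 1), snv$ref_base)
  }
})

test_that("strain panel plants the exact recurrent structure", {
  sim <- small_sim(seed = 22)
  pan <- make_strain_vcfs(sim$cfg, sim$truth)
  tr <- pan$truth$recurrent
  planted <- tr[tr$planted %in% c("error", "shared"), ]
  expect_equal(nrow(planted), sim$cfg$recurrent_site_count)
  # error count follows round-half-up(f * sites)
  expect_equal(pan$truth$n_error_sites,
               as.integer(round_half_up(sim$cfg$reference_error_fraction *
                                          sim$cfg$recurrent_site_count)))
  # recurrence >= 75% hom-alt, no hets at planted sites
  expect_true(all(planted$n_homalt / planted$n_strains >= 0.75))
  expect_true(all(planted$n_het == 0))
  # decoys are either below threshold or het-contaminated
  dec <- tr[startsWith(tr$planted, "decoy"), ]
  expect_true(all(dec$n_homalt / dec$n_strains < 0.75 | dec$n_het > 0))
  # error sites: assembly (via exact liftover) carries the ALT base
  cs <- truth_chainset(pan$truth)
  err <- tr[tr$planted == "error", ]
  m <- map_positions(cs, err$chrom, err$pos - 1L)
  expect_true(all(m$mapped))
  base <- substr(sim$asm$sequences[m$qname], m$qpos + 1, m$qpos + 1)
  expect_equal(unname(base), err$alt)
  # shared sites: assembly carries the reference base
  sh <- tr[tr$planted == "shared", ]
  m2 <- map_positions(cs, sh$chrom, sh$pos - 1L)
  base2 <- substr(sim$asm$sequences[m2$qname], m2$qpos + 1, m2$qpos + 1)
  expect_equal(unname(base2), sh$ref)
})

test_that("f = 1 and f = 0 are the planted extremes", {
  base_cfg <- function(f) sim_config(
    n_chroms = 1L, chrom_length = 200000L, gap_count = 2L,
    gap_length_range = c(150L, 300L), flank = 2000L, snv_rate = 5e-4,
    indel_rate = 0,
    sv_spec = data.frame(type = "DEL", count = 0L, minsize = 100L,
                         maxsize = 200L),
    n_strains = 6L, recurrent_site_count = 30L,
    reference_error_fraction = f, decoy_site_count = 0L, seed = 30)
  for (f in c(0, 1)) {
    cfg <- base_cfg(f)
    ref <- make_reference(cfg)
    asm <- derive_assembly(ref, ref$truth, cfg)
    pan <- make_strain_vcfs(cfg, asm$truth)
    cs <- truth_chainset(pan$truth)
    rec <- pan$truth$recurrent
    m <- map_positions(cs, rec$chrom, rec$pos - 1L)
    base <- substr(asm$sequences[m$qname], m$qpos + 1, m$qpos + 1)
    if (f == 1) expect_true(all(base == rec$alt))
    else expect_true(all(base != rec$alt))
  }
})

test_that("simulated SV callsets mirror planted truth per class", {
  sim <- small_sim(seed = 23)
  cls <- simulate_sv_callsets(sim$truth, sim$cfg)
  truth_tab <- table(sim$truth$svs$svtype)
  expect_equal(as.vector(table(cls$longread$svtype)[names(truth_tab)]),
               as.vector(truth_tab))
  expect_false("INS" %in% cls$shortread$svtype)
})
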