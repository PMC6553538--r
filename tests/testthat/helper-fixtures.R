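# Shared fixture builders: everything is generated in code at test time.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate a sequence to a given SNP divergence (no indels).
diverge_dna <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- rbinom(1, length(v), rate)
  if (k > 0) {
    pos <- sample.int(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

.sim_cache <- new.env(parent = emptyenv())

# Tiny desk simulation used by several modules (fast: 1 x 200 kb); cached
# per seed since generation is deterministic.
small_sim <- function(seed = 7) {
  key <- as.character(seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  .sim_cache[[key]] <- small_sim_build(seed)
  .sim_cache[[key]]
}

# Whole-assembly alignment + chain set for a cached sim (also cached).
small_paf <- function(seed = 7) {
  key <- paste0("paf", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- small_sim(seed)
    .sim_cache[[key]] <- align_genomes(sim$asm$sequences, sim$ref$sequences)
  }
  .sim_cache[[key]]
}

small_chainset <- function(seed = 7) {
  key <- paste0("cs", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- build_chains(small_paf(seed))
  .sim_cache[[key]]
}

small_sim_build <- function(seed) {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 200000L, gap_count = 3L,
                    gap_length_range = c(150L, 600L), flank = 2000L,
                    min_total_aln = 3000L, snv_rate = 1e-4, indel_rate = 1e-5,
                    sv_spec = data.frame(type = c("DEL", "DUP", "INV", "INS"),
                                         count = c(2L, 1L, 1L, 2L),
                                         minsize = c(100L, 100L, 300L, 100L),
                                         maxsize = c(500L, 400L, 800L, 300L)),
                    repeat_composition = c(satellite = 0.05,
                                           microsatellite = 0.02,
                                           line = 0.08),
                    n_strains = 8L, recurrent_site_count = 40L,
                    reference_error_fraction = 0.25,
                    decoy_site_count = 20L, seed = seed)
  ref <- make_reference(cfg)
  asm <- derive_assembly(ref, ref$truth, cfg)
  list(cfg = cfg, ref = ref, asm = asm, truth = asm$truth)
}

# Smith-Waterman local alignment oracle (match +1, mismatch/gap -1);
# returns best score and 0-based half-open endpoints of one optimal local
# alignment. Exhaustive O(nm) DP, for small test pairs only.
sw_oracle <- function(q, t) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(tv)
  H <- matrix(0L, n + 1, m + 1)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- max(0L,
                H[i, j] + if (qv[i] == tv[j]) 1L else -1L,
                H[i, j + 1] - 1L,
                H[i + 1, j] - 1L)
      H[i + 1, j + 1] <- sc
      if (sc > best) { best <- sc; bi <- i; bj <- j }
    }
  }
  # traceback for the start
  i <- bi; j <- bj
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    sc <- H[i + 1, j + 1]
    if (sc == H[i, j] + (if (qv[i] == tv[j]) 1L else -1L)) {
      i <- i - 1L; j <- j - 1L
    } else if (sc == H[i, j + 1] - 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = best, qstart = i, qend = bi, tstart = j, tend = bj)
}

# Global match count oracle (Needleman-Wunsch, match +1, mismatch/gap 0 --
# maximizes matched bases).
nw_match_oracle <- function(q, t) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(tv)
  H <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(H[i, j] + (qv[i] == tv[j]),
                             H[i, j + 1], H[i + 1, j])
    }
  }
  H[n + 1, m + 1]
}
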