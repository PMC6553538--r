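#' Simulation configuration for a reference/assembly pair
#'
#' Defines the study conditions for the synthetic substrate: a chromosome-scale
#' reference with N-run gaps of known true fill, a derived assembly carrying
#' planted SNVs, indels, SVs and gap fills, a multi-strain panel with a known
#' fraction of planted reference errors, and repeat annotation with
#' controllable composition. Defaults are the desk-scale conditions: two 2 Mb
#' chromosomes, 5 kb flanks and an 8 kb minimum alignment (the production-scale
#' 50 kb / 80 kb thresholds scaled by 1/10), 24 strains, 2,194 recurrent sites
#' with reference-error fraction 0.126.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param gap_count total number of N-run gaps planted across the genome.
#' @param gap_length_range min/max planted gap length (bp).
#' @param fill_delta_prob probability that a gap's true fill differs in length
#'   from the N-run.
#' @param fill_delta_range magnitude range of planted fill-length deltas (bp);
#'   sign is chosen uniformly.
#' @param flank flank padding either side of a gap (bp).
#' @param min_total_aln minimum total aligned bases for a gap-fill candidate.
#' @param snv_rate per-bp substitution rate between reference and assembly.
#' @param indel_rate per-bp small-indel rate (lengths 1-10).
#' @param sv_spec data.frame(type, count, minsize, maxsize) of planted SVs.
#' @param repeat_composition named fractions for classes `satellite`,
#'   `microsatellite`, `line` (must sum to <= 1).
#' @param n_strains strains in the simulated panel.
#' @param recurrent_site_count number of planted recurrent sites.
#' @param reference_error_fraction fraction f of recurrent sites planted as
#'   reference errors (assembly carries the ALT base).
#' @param decoy_site_count non-recurrent decoy sites (below threshold or
#'   het-containing) added to the panel.
#' @param missing_rate per-genotype missing rate in the panel.
#' @param n_genes random gene intervals annotated per chromosome (for SV
#'   overlap reporting).
#' @param seed RNG seed; every generator operation is deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 2e6, gap_count = 10L,
                       gap_length_range = c(200L, 1500L),
                       fill_delta_prob = 0.5,
                       fill_delta_range = c(20L, 150L),
                       flank = 5000L, min_total_aln = 8000L,
                       snv_rate = 2e-4, indel_rate = 2e-5,
                       sv_spec = data.frame(
                         type = c("DEL", "DUP", "INV", "INS"),
                         count = c(6L, 5L, 3L, 6L),
                         minsize = c(100L, 100L, 300L, 100L),
                         maxsize = c(2000L, 1000L, 3000L, 800L)),
                       repeat_composition = c(satellite = 0.06,
                                              microsatellite = 0.03,
                                              line = 0.10),
                       n_strains = 24L, recurrent_site_count = 2194L,
                       reference_error_fraction = 0.126,
                       decoy_site_count = 150L,
                       missing_rate = 0,
                       n_genes = 40L,
                       seed = 42L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              gap_count = as.integer(gap_count),
              gap_length_range = as.integer(gap_length_range),
              fill_delta_prob = fill_delta_prob,
              fill_delta_range = as.integer(fill_delta_range),
              flank = as.integer(flank),
              min_total_aln = as.integer(min_total_aln),
              snv_rate = snv_rate, indel_rate = indel_rate,
              sv_spec = sv_spec,
              repeat_composition = repeat_composition,
              n_strains = as.integer(n_strains),
              recurrent_site_count = as.integer(recurrent_site_count),
              reference_error_fraction = reference_error_fraction,
              decoy_site_count = as.integer(decoy_site_count),
              missing_rate = missing_rate,
              n_genes = as.integer(n_genes),
              seed = as.integer(seed))
  check_that(all(c(cfg$snv_rate, cfg$indel_rate, cfg$missing_rate,
                   cfg$reference_error_fraction) >= 0 &
                 c(cfg$snv_rate, cfg$indel_rate, cfg$missing_rate,
                   cfg$reference_error_fraction) <= 1),
             "rates must lie in [0, 1]")
  check_that(cfg$chrom_length > 0 && all(cfg$gap_length_range > 0),
             "lengths must be positive")
  check_that(sum(cfg$repeat_composition) <= 1,
             "repeat composition fractions sum to more than 1")
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer in [lo, hi], safe when lo == hi (unlike sample(lo:hi, 1))
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Mutate a fraction of positions of a DNA string to a different base.
mutate_dna <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# Sample a block start so that [start, start+len) avoids `occupied`
# (IRanges) and stays >= margin from both chromosome ends.
sample_free_start <- function(len, chrom_len, occupied, margin = 0L,
                              max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- sample.int(chrom_len - len - 2L * margin, 1L) + margin
    cand <- IRanges::IRanges(s + 1L, s + len)
    if (length(occupied) == 0 ||
        !any(IRanges::overlapsAny(cand, occupied))) return(s)
  }
  NA_integer_
}

#' Generate a synthetic reference genome with planted gaps and repeats
#'
#' Chromosomes are uniform random DNA into which repeat blocks are written
#' until each class reaches its target fraction within +-2% (satellite: tandem
#' copies of a 120 bp monomer; microsatellite: 2-6 bp motifs; LINE-like:
#' mutated copies of a fixed 4 kb decoy master). N-run gaps are then planted at
#' recorded positions, replacing recorded true-fill sequence. Gaps avoid repeat
#' blocks and keep `2*flank + 1000` bp separation so every padded region is
#' well defined.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (named character), `repeats` (interval
#'   data.frame with class labels), `genes` (interval data.frame), and `truth`
#'   (the planted-feature ledger; see vignette).
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  comp <- config$repeat_composition
  check_that(sum(comp) <= 1, "repeat composition fractions sum to more than 1")
  L <- config$chrom_length
  nchr <- config$n_chroms
  chroms <- paste0("chr", seq_len(nchr))
  sat_monomer <- rand_dna(120)
  line_master <- rand_dna(4000)
  seqs <- character(nchr); names(seqs) <- chroms
  rep_list <- list(); gene_list <- list()
  occupied_all <- list()
  seq_vecs <- vector("list", nchr)
  for (ci in seq_len(nchr)) {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    occupied <- IRanges::IRanges()
    reps <- list()
    for (cls in names(comp)) {
      target <- comp[[cls]] * L
      placed <- 0
      while (placed < target - 50) {
        remaining <- target - placed
        blk_len <- switch(cls,
          satellite = sample_range(500L, 2000L),
          microsatellite = sample_range(100L, 400L),
          line = sample_range(1000L, 4000L))
        blk_len <- min(blk_len, as.integer(remaining))
        if (blk_len < 20) break
        blk <- switch(cls,
          satellite = substr(strrep(sat_monomer, ceiling(blk_len / 120)),
                             1, blk_len),
          microsatellite = {
            motif <- rand_dna(sample_range(2L, 6L))
            substr(strrep(motif, ceiling(blk_len / nchar(motif))), 1, blk_len)
          },
          line = {
            off <- sample.int(4000 - blk_len + 1L, 1L)
            mutate_dna(substr(line_master, off, off + blk_len - 1L), 0.10)
          })
        s <- sample_free_start(blk_len, L, occupied, margin = 1000L)
        if (is.na(s)) break
        base[(s + 1L):(s + blk_len)] <- strsplit(blk, "", fixed = TRUE)[[1]]
        occupied <- c(occupied, IRanges::IRanges(s + 1L, s + blk_len))
        reps[[length(reps) + 1L]] <-
          data.frame(chrom = chroms[ci], start = s, end = s + blk_len,
                     label = cls, stringsAsFactors = FALSE)
        placed <- placed + blk_len
      }
    }
    seq_vecs[[ci]] <- base
    rep_list[[ci]] <- if (length(reps)) do.call(rbind, reps) else NULL
    # random gene intervals (non-overlapping), for SV/gene overlap reporting
    genes <- list()
    gocc <- IRanges::IRanges()
    for (gi in seq_len(config$n_genes)) {
      glen <- sample_range(2000L, 20000L)
      s <- sample_free_start(glen, L, gocc, margin = 100L, max_tries = 50L)
      if (is.na(s)) next
      gocc <- c(gocc, IRanges::IRanges(s + 1L, s + glen))
      genes[[length(genes) + 1L]] <-
        data.frame(chrom = chroms[ci], start = s, end = s + glen,
                   label = sprintf("gene_%s_%d", chroms[ci], gi),
                   stringsAsFactors = FALSE)
    }
    gene_list[[ci]] <- if (length(genes)) do.call(rbind, genes) else NULL
    occupied_all[[ci]] <- occupied
  }
  repeats <- do.call(rbind, rep_list)
  genes <- do.call(rbind, gene_list)
  # plant gaps, avoiding repeat blocks, with wide separation
  per_chrom <- diff(round(seq(0, config$gap_count, length.out = nchr + 1)))
  sep <- 2L * config$flank + 1000L
  gap_rows <- list()
  gid <- 0L
  for (ci in seq_len(nchr)) {
    occ <- occupied_all[[ci]]        # repeat blocks: the gap itself avoids them
    reserved <- IRanges::IRanges()   # gap +- sep: other gaps keep out
    for (gi in seq_len(per_chrom[ci])) {
      glen <- sample_range(config$gap_length_range[1],
                           config$gap_length_range[2])
      s <- NA_integer_
      for (try in 1:500) {
        cand <- sample.int(L - glen - 2L * (config$flank + 1000L), 1L) +
          config$flank + 1000L
        gapiv <- IRanges::IRanges(cand - 200L, cand + glen + 200L)
        sepiv <- IRanges::IRanges(cand - sep + 1L, cand + glen + sep)
        if (!any(IRanges::overlapsAny(gapiv, occ)) &&
            !any(IRanges::overlapsAny(sepiv, reserved))) { s <- cand; break }
      }
      if (is.na(s)) stop("could not place gap ", gi, " on ", chroms[ci],
                         " (genome too crowded)")
      fill <- paste(seq_vecs[[ci]][(s + 1L):(s + glen)], collapse = "")
      seq_vecs[[ci]][(s + 1L):(s + glen)] <- "N"
      reserved <- c(reserved, IRanges::IRanges(s - sep + 1L, s + glen + sep))
      gid <- gid + 1L
      gap_rows[[gid]] <- data.frame(
        gap_id = gid, chrom = chroms[ci], start = s, end = s + glen,
        length = glen, fill = fill, stringsAsFactors = FALSE)
    }
    occupied_all[[ci]] <- c(occ, reserved)
    seqs[ci] <- paste(seq_vecs[[ci]], collapse = "")
  }
  if (length(gap_rows)) {
    gaps <- do.call(rbind, gap_rows)
    gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
    gaps$gap_id <- seq_len(nrow(gaps))   # ids follow coordinate order
    rownames(gaps) <- NULL
  } else gaps <-
    data.frame(gap_id = integer(), chrom = character(), start = integer(),
               end = integer(), length = integer(), fill = character(),
               stringsAsFactors = FALSE)
  truth <- list(seed = config$seed,
                chrom_lens = stats::setNames(nchar(seqs), names(seqs)),
                gaps = gaps, repeats = repeats, genes = genes,
                ref_sequences = seqs)
  class(truth) <- "truth_table"
  list(sequences = seqs, repeats = repeats, genes = genes, truth = truth)
}

#' Derive a synthetic assembly from a reference and its truth table
#'
#' Replaces each N-run gap by its true fill (optionally with a planted length
#' delta inside the fill), applies drift SNVs, small indels and structural
#' variants at the configured rates, splits the edited chromosomes into
#' scaffolds at midpoints between gap fills (so each scaffold spans at most one
#' gap plus its padded flanks), and logs every edit with both reference and
#' assembly coordinates. SVs that would overlap a gap or another edit are
#' rejected and resampled (counted in the truth table).
#'
#' @param reference result of [make_reference()] (list with `sequences`).
#' @param truth the truth table from [make_reference()].
#' @param config the same [sim_config()].
#' @return list with `sequences` (named scaffolds) and `truth` (augmented:
#'   gap fills with final sequence and discrepancy, `snvs`, `indels`, `svs`,
#'   identity `blocks` mapping reference to scaffold coordinates, scaffold
#'   lengths, and the exact expected length delta).
#' @export
derive_assembly <- function(reference, truth, config) {
  set.seed(config$seed + 1L)
  seqs <- reference$sequences
  gaps <- truth$gaps
  sv_rejected <- 0L
  edits_all <- list(); snv_all <- list(); indel_all <- list(); sv_all <- list()
  for (chrom in names(seqs)) {
    L <- nchar(seqs[[chrom]])
    g <- gaps[gaps$chrom == chrom, , drop = FALSE]
    # edit ledger: ref_start/ref_end half-open, replacement string, kind
    edits <- list()
    occupied <- IRanges::IRanges(g$start + 1L, g$end)  # gaps are reserved
    for (i in seq_len(nrow(g))) {
      fill <- g$fill[i]
      if (stats::runif(1) < config$fill_delta_prob) {
        mag <- sample_range(config$fill_delta_range[1], config$fill_delta_range[2])
        mag <- min(mag, nchar(fill) - 20L)
        if (stats::runif(1) < 0.5 && mag > 0) {   # deletion inside fill
          cut <- sample.int(nchar(fill) - mag, 1)
          fill <- paste0(substr(fill, 1, cut),
                         substr(fill, cut + mag + 1L, nchar(fill)))
        } else {                                   # insertion inside fill
          at <- sample.int(nchar(fill), 1)
          fill <- paste0(substr(fill, 1, at), rand_dna(mag),
                         substr(fill, at + 1L, nchar(fill)))
        }
      }
      edits[[length(edits) + 1L]] <- list(
        kind = "gap_fill", gap_id = g$gap_id[i],
        ref_start = g$start[i], ref_end = g$end[i], repl = fill)
    }
    # structural variants
    spec <- config$sv_spec
    for (si in seq_len(nrow(spec))) {
      for (k in seq_len(spec$count[si])) {
        repeat {
          size <- sample_range(spec$minsize[si], spec$maxsize[si])
          span <- if (spec$type[si] == "INS") 1L else size
          s <- sample.int(L - span - 2000L, 1L) + 1000L
          cand <- IRanges::IRanges(s + 1L, s + span)
          if (any(IRanges::overlapsAny(cand, occupied))) {
            sv_rejected <- sv_rejected + 1L
            next
          }
          occupied <- c(occupied, IRanges::IRanges(s - 9L, s + span + 10L))
          seg <- substr(seqs[[chrom]], s + 1L, s + span)
          repl <- switch(spec$type[si],
            DEL = "",
            DUP = paste0(seg, seg),
            INV = revcomp(seg),
            INS = paste0(seg, rand_dna(size)))
          edits[[length(edits) + 1L]] <- list(
            kind = "sv", svtype = spec$type[si],
            ref_start = s, ref_end = s + span, repl = repl, size = size)
          sv_all[[length(sv_all) + 1L]] <- data.frame(
            chrom = chrom, start = s, end = s + span,
            svtype = spec$type[si], size = size, stringsAsFactors = FALSE)
          break
        }
      }
    }
    # small indels
    n_ind <- stats::rbinom(1, L, config$indel_rate)
    placed <- 0L
    while (placed < n_ind) {
      len <- sample.int(10L, 1L)
      is_del <- stats::runif(1) < 0.5
      span <- if (is_del) len else 1L
      s <- sample_free_start(span + 20L, L, occupied, margin = 1000L,
                             max_tries = 50L)
      if (is.na(s)) break
      s <- s + 10L
      occupied <- c(occupied, IRanges::IRanges(s - 9L, s + span + 10L))
      if (is_del) {
        edits[[length(edits) + 1L]] <- list(kind = "indel", ref_start = s,
                                            ref_end = s + len, repl = "")
        indel_all[[length(indel_all) + 1L]] <- data.frame(
          chrom = chrom, start = s, len = len, type = "DEL",
          stringsAsFactors = FALSE)
      } else {
        ins <- rand_dna(len)
        base <- substr(seqs[[chrom]], s + 1L, s + 1L)
        edits[[length(edits) + 1L]] <- list(kind = "indel", ref_start = s,
                                            ref_end = s + 1L,
                                            repl = paste0(base, ins))
        indel_all[[length(indel_all) + 1L]] <- data.frame(
          chrom = chrom, start = s, len = len, type = "INS",
          stringsAsFactors = FALSE)
      }
      placed <- placed + 1L
    }
    # SNVs: coordinate-preserving, applied in place (stay inside blocks)
    n_snv <- stats::rbinom(1, L, config$snv_rate)
    free_pos <- setdiff(seq_len(L) - 1L,
                        unlist(lapply(edits, function(e)
                          seq(e$ref_start - 10L, e$ref_end + 10L))))
    snv_pos <- sort(sample(free_pos, min(n_snv, length(free_pos))))
    chrom_seq <- seqs[[chrom]]
    if (length(snv_pos)) {
      vec <- strsplit(chrom_seq, "", fixed = TRUE)[[1]]
      old <- vec[snv_pos + 1L]
      keep <- old != "N"
      snv_pos <- snv_pos[keep]; old <- old[keep]
      new <- vapply(old, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "",
        USE.NAMES = FALSE)
      vec[snv_pos + 1L] <- new
      chrom_seq <- paste(vec, collapse = "")
      snv_all[[length(snv_all) + 1L]] <- data.frame(
        chrom = chrom, pos = snv_pos, ref_base = old, alt_base = new,
        stringsAsFactors = FALSE)
    }
    edits_all[[chrom]] <- list(seq = chrom_seq, edits = edits)
  }
  # apply length-changing edits per chromosome and build the block map
  asm_seqs <- character(0)
  blocks_list <- list(); gapfill_rows <- list()
  for (chrom in names(seqs)) {
    ch <- edits_all[[chrom]]
    ed <- ch$edits
    if (length(ed)) {
      ord <- order(vapply(ed, function(e) e$ref_start, 1))
      ed <- ed[ord]
    }
    segs <- character(0)
    blocks <- list()
    cursor <- 0L; asm_cursor <- 0L
    add_block <- function(rs, re, qs) {
      if (re > rs)
        blocks[[length(blocks) + 1L]] <<- data.frame(
          tname = chrom, tstart = rs, tend = re,
          qstart = qs, qend = qs + (re - rs), stringsAsFactors = FALSE)
    }
    for (e in ed) {
      pre <- substr(ch$seq, cursor + 1L, e$ref_start)
      add_block(cursor, e$ref_start, asm_cursor)
      segs <- c(segs, pre, e$repl)
      asm_cursor <- asm_cursor + nchar(pre)
      e_asm_start <- asm_cursor
      asm_cursor <- asm_cursor + nchar(e$repl)
      if (e$kind == "gap_fill") {
        gapfill_rows[[length(gapfill_rows) + 1L]] <- data.frame(
          gap_id = e$gap_id, chrom = chrom,
          asm_start = e_asm_start, asm_end = asm_cursor,
          fill = e$repl, fill_len = nchar(e$repl),
          scaffold = NA_character_, fill_start = NA_integer_,
          fill_end = NA_integer_, stringsAsFactors = FALSE)
      }
      cursor <- e$ref_end
    }
    tail_seg <- substr(ch$seq, cursor + 1L, nchar(ch$seq))
    add_block(cursor, nchar(ch$seq), asm_cursor)
    segs <- c(segs, tail_seg)
    asm_chrom <- paste(segs, collapse = "")
    blocks <- do.call(rbind, blocks)
    # split into scaffolds at midpoints between consecutive gap fills
    gf <- if (length(gapfill_rows)) do.call(rbind, gapfill_rows) else
      data.frame(gap_id = integer(), chrom = character(),
                 asm_start = integer(), asm_end = integer(),
                 fill = character(), fill_len = integer(),
                 stringsAsFactors = FALSE)
    gf <- gf[gf$chrom == chrom, , drop = FALSE]
    gf <- gf[order(gf$asm_start), , drop = FALSE]
    brk <- if (nrow(gf) >= 2)
      as.integer(round((gf$asm_end[-nrow(gf)] + gf$asm_start[-1]) / 2))
    else integer(0)
    bounds <- c(0L, brk, nchar(asm_chrom))
    for (si in seq_len(length(bounds) - 1L)) {
      s0 <- bounds[si]; s1 <- bounds[si + 1L]
      sname <- sprintf("scaf_%s_%d", chrom, si)
      asm_seqs[sname] <- substr(asm_chrom, s0 + 1L, s1)
      # clip blocks to this scaffold, re-basing query coordinates
      b <- blocks[blocks$qend > s0 & blocks$qstart < s1, , drop = FALSE]
      if (nrow(b)) {
        lt <- pmax(b$qstart, s0); rt <- pmin(b$qend, s1)
        b$tstart <- b$tstart + (lt - b$qstart)
        b$tend <- b$tend - (b$qend - rt)
        b$qstart <- lt - s0; b$qend <- rt - s0
        b$qname <- sname
        blocks_list[[length(blocks_list) + 1L]] <- b
      }
      # assign gap fills to scaffolds (scaffold-local coordinates)
      sel <- gf$asm_start >= s0 & gf$asm_end <= s1
      if (any(sel)) {
        for (ri in which(sel)) {
          row_id <- which(vapply(gapfill_rows, function(r)
            r$gap_id == gf$gap_id[ri], TRUE))
          gapfill_rows[[row_id]]$scaffold <- sname
          gapfill_rows[[row_id]]$fill_start <- gf$asm_start[ri] - s0
          gapfill_rows[[row_id]]$fill_end <- gf$asm_end[ri] - s0
        }
      }
    }
  }
  if (length(gapfill_rows)) {
    gf_all <- do.call(rbind, gapfill_rows)
    gaps2 <- merge(truth$gaps[, c("gap_id", "chrom", "start", "end",
                                  "length")],
                   gf_all[, c("gap_id", "scaffold", "fill_start", "fill_end",
                              "fill", "fill_len")], by = "gap_id")
    gaps2$discrepancy <- gaps2$fill_len - gaps2$length
    gaps2 <- gaps2[order(gaps2$gap_id), , drop = FALSE]
  } else {
    gaps2 <- cbind(truth$gaps[0, c("gap_id", "chrom", "start", "end",
                                   "length")],
                   data.frame(scaffold = character(), fill_start = integer(),
                              fill_end = integer(), fill = character(),
                              fill_len = integer(), discrepancy = integer(),
                              stringsAsFactors = FALSE))
  }
  blocks <- do.call(rbind, blocks_list)
  rownames(blocks) <- NULL
  snvs <- if (length(snv_all)) do.call(rbind, snv_all) else
    data.frame(chrom = character(), pos = integer(), ref_base = character(),
               alt_base = character(), stringsAsFactors = FALSE)
  svs <- if (length(sv_all)) do.call(rbind, sv_all) else NULL
  indels <- if (length(indel_all)) do.call(rbind, indel_all) else NULL
  sv_delta <- if (!is.null(svs)) sum(ifelse(svs$svtype == "DEL", -svs$size,
                                     ifelse(svs$svtype %in% c("DUP", "INS"),
                                            svs$size, 0L))) else 0L
  indel_delta <- if (!is.null(indels))
    sum(ifelse(indels$type == "DEL", -indels$len, indels$len)) else 0L
  truth$gaps <- gaps2
  truth$snvs <- snvs
  truth$indels <- indels
  truth$svs <- svs
  truth$sv_rejected <- sv_rejected
  truth$blocks <- blocks
  truth$scaffold_lens <- stats::setNames(nchar(asm_seqs), names(asm_seqs))
  truth$length_delta <- sum(gaps2$fill_len) - sum(gaps2$length) +
    sv_delta + indel_delta
  list(sequences = asm_seqs, truth = truth)
}

#' Perfect liftover built from the truth table
#'
#' Converts the generator's identity-segment ledger into a [ChainSet] (one
#' chain per reference-chromosome/scaffold pair), giving an exact
#' reference-to-assembly coordinate map independent of the micro-aligner.
#'
#' @param truth truth table from [derive_assembly()].
#' @return a `ChainSet` (see [build_chains()]).
#' @export
truth_chainset <- function(truth) {
  b <- truth$blocks
  b$strand <- "+"
  b$nmatch <- b$tend - b$tstart
  key <- paste(b$tname, b$qname)
  ids <- match(key, unique(key))
  b$chain_id <- ids
  chains <- do.call(rbind, lapply(split(b, b$chain_id), function(d) {
    data.frame(chain_id = d$chain_id[1], qname = d$qname[1],
               tname = d$tname[1], strand = "+",
               qstart = min(d$qstart), qend = max(d$qend),
               tstart = min(d$tstart), tend = max(d$tend),
               score = sum(d$nmatch), nblocks = nrow(d),
               stringsAsFactors = FALSE)
  }))
  cs <- structure(list(chains = chains,
                       blocks = b[, c("chain_id", "qname", "tname", "strand",
                                      "qstart", "qend", "tstart", "tend")],
                       tlens = truth$chrom_lens,
                       qlens = truth$scaffold_lens),
                  class = "ChainSet")
  cs$net <- cs$blocks   # truth blocks are disjoint on the target by design
  cs
}

#' Simulate a multi-strain VCF panel with planted reference errors
#'
#' Emits `recurrent_site_count` sites at which at least 75% of strains are
#' homozygous-ALT. A fraction `f = reference_error_fraction` of these are
#' planted reference errors: the site coincides with a planted assembly SNV,
#' so the derived assembly carries the ALT base at the lifted position. The
#' remainder are true shared variants (assembly carries REF). The planted
#' error count is `round-half-up(f * recurrent_site_count)` and is recorded in
#' the truth table. Decoy sites (below threshold, or recurrent but with het
#' calls) are added so that the selection step is exercised.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [derive_assembly()].
#' @return list with `vcf` (a `multi_vcf`) and the augmented `truth`
#'   (`recurrent` site table with planted status and genotype counts).
#' @export
make_strain_vcfs <- function(config, truth) {
  check_that(config$n_strains >= 2, "need at least 2 strains")
  set.seed(config$seed + 2L)
  n_sites <- config$recurrent_site_count
  f <- config$reference_error_fraction
  n_err <- as.integer(round_half_up(f * n_sites))
  check_that(nrow(truth$snvs) >= n_err,
             "not enough planted SNVs (%d) for %d reference-error sites; raise snv_rate",
             nrow(truth$snvs), n_err)
  err_idx <- sort(sample.int(nrow(truth$snvs), n_err))
  err <- truth$snvs[err_idx, , drop = FALSE]
  # true shared sites: untouched positions strictly inside identity blocks
  n_true <- n_sites - n_err
  pool <- position_pool(truth, n_true + config$decoy_site_count)
  pool <- attach_base(pool, truth$ref_sequences)
  shared <- pool[seq_len(n_true), , drop = FALSE]
  decoy <- pool[-seq_len(n_true), , drop = FALSE]
  base_other <- function(b) vapply(b, function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  sites <- rbind(
    data.frame(chrom = err$chrom, pos = err$pos + 1L, ref = err$ref_base,
               alt = err$alt_base,
               planted = rep("error", nrow(err)),
               stringsAsFactors = FALSE),
    data.frame(chrom = shared$chrom, pos = shared$pos + 1L, ref = shared$base,
               alt = base_other(shared$base),
               planted = rep("shared", nrow(shared)),
               stringsAsFactors = FALSE))
  n <- config$n_strains
  gt <- matrix("hom-ref", nrow(sites), n)
  for (i in seq_len(nrow(sites))) {
    q <- stats::runif(1, 0.75, 1)
    k <- min(n, max(ceiling(q * n), ceiling(0.75 * n)))
    gt[i, sample.int(n, k)] <- "hom-alt"
  }
  # decoys
  if (nrow(decoy)) {
    half <- nrow(decoy) %/% 2
    dsites <- data.frame(chrom = decoy$chrom, pos = decoy$pos + 1L,
                         ref = decoy$base, alt = base_other(decoy$base),
                         planted = c(rep("decoy_low", half),
                                     rep("decoy_het", nrow(decoy) - half)),
                         stringsAsFactors = FALSE)
    dgt <- matrix("hom-ref", nrow(decoy), n)
    for (i in seq_len(nrow(decoy))) {
      if (i <= half) {   # recurrence strictly below threshold
        k <- sample.int(max(1L, ceiling(0.75 * n) - 1L), 1)
        dgt[i, sample.int(n, k)] <- "hom-alt"
      } else {           # above threshold but het-contaminated
        k <- min(n - 1L, ceiling(stats::runif(1, 0.75, 0.95) * n))
        idx <- sample.int(n, k + 1L)
        dgt[i, idx[seq_len(k)]] <- "hom-alt"
        dgt[i, idx[k + 1L]] <- "het"
      }
    }
    sites <- rbind(sites, dsites)
    gt <- rbind(gt, dgt)
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(gt)) < config$missing_rate
    gt[drop] <- "missing"
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]; gt <- gt[ord, , drop = FALSE]
  rownames(sites) <- NULL
  samples <- sprintf("strain%02d", seq_len(n))
  colnames(gt) <- samples
  vcf <- structure(list(sites = sites[, c("chrom", "pos", "ref", "alt")],
                        gt = gt, samples = samples), class = "multi_vcf")
  truth$recurrent <- cbind(sites,
                           n_homalt = rowSums(gt == "hom-alt"),
                           n_het = rowSums(gt == "het"),
                           n_strains = n)
  truth$n_error_sites <- n_err
  list(vcf = vcf, truth = truth)
}

# Sample n untouched 0-based reference positions inside identity blocks,
# avoiding planted SNVs; returns chrom, pos.
position_pool <- function(truth, n) {
  b <- truth$blocks
  # interiors, 10 bp clear of block edges
  ok <- b$tend - b$tstart > 40
  b <- b[ok, , drop = FALSE]
  w <- (b$tend - b$tstart) - 20L
  pick_block <- sample.int(nrow(b), n * 2L, replace = TRUE, prob = w)
  off <- floor(stats::runif(n * 2L) * w[pick_block])
  pos <- b$tstart[pick_block] + 10L + as.integer(off)
  chrom <- b$tname[pick_block]
  keep <- !duplicated(paste(chrom, pos))
  bad <- paste(truth$snvs$chrom, truth$snvs$pos)
  keep <- keep & !(paste(chrom, pos) %in% bad)
  chrom <- chrom[keep][seq_len(n)]; pos <- pos[keep][seq_len(n)]
  if (anyNA(pos)) stop("could not sample enough untouched panel positions")
  df <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  df
}

# Attach the reference base at each pooled position (needs sequences).
attach_base <- function(df, sequences) {
  df$base <- mapply(function(ch, p) substr(sequences[[ch]], p + 1, p + 1),
                    df$chrom, df$pos, USE.NAMES = FALSE)
  df
}

#' Simulate two technology-specific SV callsets from planted truth
#'
#' Caller A ("longread") reports every planted SV with small breakpoint
#' jitter; caller B ("shortread") reports all classes except insertions, with
#' larger jitter. Mirrors a long-read/short-read caller pair feeding the
#' consensus merge.
#'
#' @param truth truth table from [derive_assembly()].
#' @param config a [sim_config()].
#' @param jitter_a,jitter_b max absolute breakpoint jitter per caller (bp).
#' @return list of two SV data.frames (`chrom, start, end, svtype, size,
#'   caller`).
#' @export
simulate_sv_callsets <- function(truth, config, jitter_a = 10L,
                                 jitter_b = 50L) {
  set.seed(config$seed + 3L)
  sv <- truth$svs
  jit <- function(x, j) pmax(0L, x + sample(seq(-j, j), length(x),
                                            replace = TRUE))
  a <- data.frame(chrom = sv$chrom, start = jit(sv$start, jitter_a),
                  end = jit(sv$end, jitter_a), svtype = sv$svtype,
                  size = sv$size, caller = "longread",
                  stringsAsFactors = FALSE)
  a$end <- pmax(a$end, a$start + ifelse(a$svtype == "INS", 1L, 20L))
  bsv <- sv[sv$svtype != "INS", , drop = FALSE]
  b <- data.frame(chrom = bsv$chrom, start = jit(bsv$start, jitter_b),
                  end = jit(bsv$end, jitter_b), svtype = bsv$svtype,
                  size = bsv$size, caller = "shortread",
                  stringsAsFactors = FALSE)
  b$end <- pmax(b$end, b$start + 20L)
  a$size <- ifelse(a$svtype == "INS", a$size, a$end - a$start)
  b$size <- b$end - b$start
  list(longread = a, shortread = b)
}
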