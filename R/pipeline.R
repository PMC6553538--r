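#' Pipeline run configuration
#'
#' Stage toggles plus all stage parameters; serialized verbatim into the run
#' report for reproducibility.
#'
#' @param sim a [sim_config()]; its seed drives every stochastic step.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "align", "stats", "gapfill", "resolve", "svmerge",
#'   "unaligned")`.
#' @param min_frac recurrence threshold for variant resolution.
#' @param max_breakpoint_dist SV merge distance.
#' @param use_truth_liftover classify variants through the truth-derived
#'   chain set (exact coordinate map) instead of the aligner-derived one.
#' @param aligner_args list of overrides for [align_genomes()].
#' @param out_dir optional directory; when given, stage tables and the JSON
#'   report are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "align", "stats", "gapfill",
                                  "resolve", "svmerge", "unaligned"),
                       min_frac = 0.75, max_breakpoint_dist = 1000L,
                       use_truth_liftover = FALSE,
                       aligner_args = list(), out_dir = NULL) {
  structure(list(sim = sim, stages = stages, min_frac = min_frac,
                 max_breakpoint_dist = max_breakpoint_dist,
                 use_truth_liftover = use_truth_liftover,
                 aligner_args = aligner_args, out_dir = out_dir),
            class = "run_config")
}

#' Run the synthetic curation pipeline end to end
#'
#' simulate a reference/assembly pair with planted truth, align the assembly
#' to the reference and build the chain/net, then run the requested curation
#' stages (assembly statistics, gap filling, recurring-variant resolution,
#' SV consensus, unaligned-region repeat composition) and assemble a report
#' comparing every stage against the planted truth.
#'
#' @param config a [run_config()].
#' @return a report list; also written as `report.json` (plus stage TSVs)
#'   when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stages <- config$stages
  need <- function(s) s %in% stages
  report <- list(parameters = config[setdiff(names(config), "out_dir")],
                 seed = config$sim$seed)
  if (!need("simulate"))
    stop("stage 'simulate' is required (synthetic substrate): enable it")
  ref <- make_reference(config$sim)
  asm <- derive_assembly(ref, ref$truth, config$sim)
  truth <- asm$truth
  panel <- make_strain_vcfs(config$sim, truth)
  truth <- panel$truth
  report$simulate <- list(
    n_chroms = length(ref$sequences),
    reference_bp = sum(nchar(ref$sequences)),
    assembly_bp = sum(nchar(asm$sequences)),
    n_scaffolds = length(asm$sequences),
    n_gaps = nrow(truth$gaps),
    n_snvs = nrow(truth$snvs),
    n_svs = if (is.null(truth$svs)) 0L else nrow(truth$svs),
    length_delta_expected = truth$length_delta,
    length_delta_observed = sum(nchar(asm$sequences)) -
      sum(nchar(ref$sequences)))
  cs <- NULL
  if (need("align") || need("gapfill") || need("resolve") ||
      need("unaligned")) {
    paf <- do.call(align_genomes,
                   c(list(queries = asm$sequences, targets = ref$sequences),
                     config$aligner_args))
    cs <- build_chains(paf)
    owned <- sum(cs$net$tend - cs$net$tstart)
    report$align <- list(n_records = nrow(paf),
                         n_chains = nrow(cs$chains),
                         net_owned_bp = owned,
                         target_bp = sum(cs$tlens))
  }
  if (need("stats")) {
    rs <- assembly_stats(ref$sequences, split = TRUE)
    as_ <- assembly_stats(asm$sequences)
    report$stats <- list(
      reference = rs[c("n_sequences", "total_bp", "n50")],
      reference_contigs = rs$contigs[c("n_sequences", "total_bp", "n50")],
      assembly = as_[c("n_sequences", "total_bp", "n50")],
      n50_improvement = n50_improvement(as_$n50, rs$contigs$n50),
      kmer_completeness = round(kmer_completeness(ref$sequences,
                                                  asm$sequences), 4))
  }
  if (need("gapfill")) {
    gf <- gapfill_run(ref$sequences, asm$sequences,
                      flank = config$sim$flank,
                      min_total_aln = config$sim$min_total_aln,
                      chainset = cs, aligner_args = config$aligner_args)
    tr <- truth$gaps[order(truth$gaps$gap_id), ]
    fl <- gf$fills[order(gf$fills$gap_id), ]
    hit <- fl$confirmed & !is.na(fl$fill) & fl$fill == tr$fill
    report$gapfill <- list(
      n_gaps = nrow(tr),
      n_confirmed = sum(fl$confirmed),
      recall = round(sum(hit) / nrow(tr), 4),
      exact_fill_recovery = isTRUE(all(hit)),
      discrepancy_matches_truth = isTRUE(all(
        fl$confirmed & fl$discrepancy == tr$discrepancy)))
    report$gapfill_table <- fl[, c("gap_id", "chrom", "start", "end",
                                   "length", "scaffold", "fill_len",
                                   "discrepancy", "confirmed", "reason")]
  }
  if (need("resolve")) {
    rec <- select_recurring(panel$vcf, min_frac = config$min_frac)
    lift <- if (config$use_truth_liftover) truth_chainset(truth) else cs
    calls <- classify_resolved(rec, lift, asm$sequences)
    summ <- summarize_resolution(calls, total_considered = nrow(rec),
                                 denominator = "net")
    planted <- truth$recurrent
    sel_truth <- planted[planted$planted %in% c("error", "shared"), ]
    report$resolve <- list(
      n_recurrent_selected = nrow(rec),
      n_recurrent_planted = nrow(sel_truth),
      selection_exact = setequal(paste(rec$chrom, rec$pos),
                                 paste(sel_truth$chrom, sel_truth$pos)),
      resolved = summ$resolved, unresolved = summ$unresolved,
      unmappable = summ$unmappable,
      resolved_pct_net = summ$resolved_pct,
      planted_error_sites = truth$n_error_sites)
  }
  if (need("svmerge")) {
    callsets <- simulate_sv_callsets(truth, config$sim)
    cons <- merge_callsets(callsets$longread, callsets$shortread,
                           max_breakpoint_dist = config$max_breakpoint_dist)
    common <- cons[cons$support == 2, , drop = FALSE]
    report$svmerge <- list(
      n_a = nrow(callsets$longread), n_b = nrow(callsets$shortread),
      n_consensus = nrow(cons), n_common = nrow(common),
      common_by_class = summarize_sv(common, genes = truth$genes),
      truth_by_class = summarize_sv(truth$svs))
  }
  if (need("unaligned")) {
    # reference-side space owned by no chain, against reference repeats
    owned <- cs$net
    ref_unaligned <- query_unaligned(
      structure(list(net = data.frame(qname = owned$tname,
                                      qstart = owned$tstart,
                                      qend = owned$tend)),
                class = "ChainSet"),
      qlens = truth$chrom_lens)
    sets <- perturb_interval_sets(ref_unaligned, n = 3,
                                  seqlens = truth$chrom_lens,
                                  seed = config$sim$seed + 4L)
    consensus <- consensus_unaligned(sets, seqlens = truth$chrom_lens)
    report$unaligned <- list(n_intervals = nrow(consensus),
                             total_bp = sum(consensus$end - consensus$start))
    if (nrow(consensus) > 0 &&
        sum(consensus$end - consensus$start) > 0) {
      comp_un <- repeat_composition(consensus, truth$repeats)
      genome_region <- data.frame(chrom = names(truth$chrom_lens),
                                  start = 0L,
                                  end = as.integer(truth$chrom_lens))
      comp_gen <- repeat_composition(genome_region, truth$repeats)
      sat_un <- comp_un$table[comp_un$table$class == "satellite", ]
      sat_gen <- comp_gen$table[comp_gen$table$class == "satellite", ]
      enr <- if (nrow(sat_un) && nrow(sat_gen))
        class_enrichment(sat_un$bp, comp_un$total_bp,
                         sat_gen$bp, comp_gen$total_bp) else NULL
      report$unaligned$repeat_pct <- comp_un$repeat_pct
      report$unaligned$genome_repeat_pct <- comp_gen$repeat_pct
      report$unaligned$composition <- comp_un$table
      if (!is.null(enr))
        report$unaligned$satellite_enrichment <-
          list(chi2 = enr$chi2, p = enr$p)
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  report
}
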