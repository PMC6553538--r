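#!/usr/bin/env Rscript
# Repeat analysis of consensus unaligned regions: take the reference space
# owned by no chain, perturb it into three method-like interval sets,
# intersect them per base, and compare repeat-class composition of the
# consensus against the genome-wide annotation with a chi-square test.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

cs <- build_chains(read_paf(path("alignments.paf")))
truth <- read_truth()
repeats <- read_bed(path("repeats.bed"))

# reference space owned by no chain
owned <- cs$net
ref_unaligned <- query_unaligned(
  structure(list(net = data.frame(qname = owned$tname, qstart = owned$tstart,
                                  qend = owned$tend)), class = "ChainSet"),
  qlens = truth$chrom_lens)
sets <- perturb_interval_sets(ref_unaligned, n = 3,
                              seqlens = truth$chrom_lens, seed = seed + 4L)
consensus <- consensus_unaligned(sets, seqlens = truth$chrom_lens)
write_bed(consensus, path("consensus_unaligned.bed"))

comp_un <- repeat_composition(consensus, repeats)
genome <- data.frame(chrom = names(truth$chrom_lens), start = 0L,
                     end = as.integer(truth$chrom_lens))
comp_gen <- repeat_composition(genome, repeats)

tab <- merge(comp_un$table, comp_gen$table, by = "class",
             suffixes = c("_unaligned", "_genome"))
enr <- lapply(seq_len(nrow(tab)), function(i)
  class_enrichment(tab$bp_unaligned[i], comp_un$total_bp,
                   tab$bp_genome[i], comp_gen$total_bp))
tab$chi2 <- vapply(enr, function(e) e$chi2, 1)
tab$p <- vapply(enr, function(e) e$p, 1)
write.table(tab, path("unaligned_composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("consensus unaligned: %d intervals, %d bp (repeat content %.1f%% vs %.1f%% genome-wide)\n",
            nrow(consensus), comp_un$total_bp, comp_un$repeat_pct,
            comp_gen$repeat_pct))
print(tab, row.names = FALSE)
cat(sprintf("(%d repeat classes tested; p-values are per class, uncorrected)\n",
            nrow(tab)))
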