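#!/usr/bin/env Rscript
# SV consensus: merge the two simulated technology callsets (long-read: all
# classes; short-read: no insertions) and summarize the common set per class
# with gene overlap.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

truth <- read_truth()
genes <- read_bed(path("genes.bed"))

callsets <- simulate_sv_callsets(truth, cfg)
cons <- merge_callsets(callsets$longread, callsets$shortread,
                       max_breakpoint_dist = 1000L)
write.table(cons, path("sv_consensus.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

common <- cons[cons$support == 2, ]
tab <- summarize_sv(common, genes = genes)
write.table(tab, path("sv_common_by_class.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("callsets: %d long-read, %d short-read calls; common: %d\n",
            nrow(callsets$longread), nrow(callsets$shortread), nrow(common)))
print(tab, row.names = FALSE)
tt <- summarize_sv(truth$svs)
cat("planted truth per class:\n")
print(tt[, c("svtype", "n", "median_size")], row.names = FALSE)
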