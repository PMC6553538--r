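#!/usr/bin/env Rscript
# Assembly quality metrics: sequence counts, N50 for the gapped reference,
# its contig version after splitting at N-runs >= 10, the derived assembly,
# the N50 improvement ratio, and k-mer completeness of the assembly against
# the reference.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ref <- read_fasta(path("ref.fa"))
asm <- read_fasta(path("asm.fa"))

rs <- assembly_stats(ref, split = TRUE)
as_ <- assembly_stats(asm)
kc <- kmer_completeness(ref, asm)

tab <- data.frame(
  assembly = c("reference (scaffolds)", "reference (contigs)",
               "derived assembly"),
  n_sequences = c(rs$n_sequences, rs$contigs$n_sequences, as_$n_sequences),
  total_bp = c(rs$total_bp, rs$contigs$total_bp, as_$total_bp),
  n50 = c(rs$n50, rs$contigs$n50, as_$n50),
  longest = c(rs$longest, rs$contigs$longest, as_$longest))
write.table(tab, path("assembly_stats.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("N50 improvement (assembly vs reference contigs): %.1f\n",
            n50_improvement(as_$n50, rs$contigs$n50)))
cat(sprintf("k-mer completeness (k = 21): %.4f\n", kc))
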