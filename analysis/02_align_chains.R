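#!/usr/bin/env Rscript
# Align every assembly scaffold to every reference chromosome with the
# micro-aligner, write the PAF, and net the chains. The net is the liftover
# substrate used by all later steps.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ref <- read_fasta(path("ref.fa"))
asm <- read_fasta(path("asm.fa"))

paf <- align_genomes(asm, ref)
write_paf(paf, path("alignments.paf"))

cs <- build_chains(paf)
uq <- scaffold_uniqueness(cs)
write.table(uq, path("scaffold_uniqueness.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

owned <- sum(cs$net$tend - cs$net$tstart)
cat(sprintf("%d alignment records -> %d chains; net owns %d of %d bp (%.1f%%)\n",
            nrow(paf), nrow(cs$chains), owned, sum(cs$tlens),
            100 * owned / sum(cs$tlens)))
cat(sprintf("%d of %d scaffolds place uniquely\n", sum(uq$unique), nrow(uq)))
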