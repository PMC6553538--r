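#!/usr/bin/env Rscript
# Gap-fill discovery: find reference N-runs, pad them, filter candidate
# scaffolds (reciprocal best hit, minimum alignment, unique placement),
# confirm reciprocally and extract the fill sequences; compare to truth.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ref <- read_fasta(path("ref.fa"))
asm <- read_fasta(path("asm.fa"))
cs <- build_chains(read_paf(path("alignments.paf")))
truth <- read_truth()

gf <- gapfill_run(ref, asm, flank = cfg$flank,
                  min_total_aln = cfg$min_total_aln, chainset = cs)

out <- gf$fills
out$gap_start_1based <- out$start + 1L
tab <- out[, c("gap_id", "chrom", "gap_start_1based", "end", "length",
               "scaffold", "fill_len", "discrepancy", "confirmed", "reason")]
write.table(tab, path("gapfills.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
fills <- out$fill[out$confirmed]
names(fills) <- sprintf("fill_gap%d_%s", out$gap_id[out$confirmed],
                        out$scaffold[out$confirmed])
if (length(fills)) write_fasta(fills, path("fills.fa"))

tr <- truth$gaps[order(truth$gaps$gap_id), ]
fl <- out[order(out$gap_id), ]
exact <- sum(!is.na(fl$fill) & fl$fill == tr$fill)
cat(sprintf("gaps: %d; confirmed fills: %d; exact fill recovery: %d/%d\n",
            nrow(tr), sum(fl$confirmed), exact, nrow(tr)))
cat(sprintf("discrepancies (fill - gap bp): %s\n",
            paste(fl$discrepancy, collapse = ", ")))
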