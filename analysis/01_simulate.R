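#!/usr/bin/env Rscript
# Build the study substrate: a reference genome with N-run gaps and repeat
# annotation, a derived assembly carrying planted SNVs/indels/SVs and gap
# fills, and a 24-strain panel with planted reference errors. Everything is
# written under results/ with its machine-readable truth ledger.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))),
                 "00_common.R"))

ref <- make_reference(cfg)
asm <- derive_assembly(ref, ref$truth, cfg)
panel <- make_strain_vcfs(cfg, asm$truth)
truth <- panel$truth

write_fasta(ref$sequences, path("ref.fa"))
write_fasta(asm$sequences, path("asm.fa"))
write_bed(ref$repeats, path("repeats.bed"))
write_bed(ref$genes, path("genes.bed"))
write_vcf_multisample(panel$vcf, path("strains.vcf"))
truth$ref_sequences <- NULL   # sequences live in the FASTAs
truth$chrom_lens <- as.list(truth$chrom_lens)       # keep names in JSON
truth$scaffold_lens <- as.list(truth$scaffold_lens)
jsonlite::write_json(unclass(truth), path("truth.json"), auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("reference: %d chromosomes, %d bp, %d gaps\n",
            length(ref$sequences), sum(nchar(ref$sequences)),
            nrow(truth$gaps)))
cat(sprintf("assembly:  %d scaffolds, %d bp (expected length delta %+d bp)\n",
            length(asm$sequences), sum(nchar(asm$sequences)),
            truth$length_delta))
cat(sprintf("panel:     %d strains, %d recurrent sites (%d planted errors)\n",
            cfg$n_strains, cfg$recurrent_site_count, truth$n_error_sites))
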