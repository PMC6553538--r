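# Shared setup for the numbered analysis drivers. Each driver is a thin
# narrative over package functions: it states what it computes, runs it, and
# writes its tables under results/. Re-run the scripts in order; every step
# is deterministic under the seed below.

suppressPackageStartupMessages(library(asmcurate))

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

seed <- as.integer(Sys.getenv("ASMCURATE_SEED", "42"))
cfg <- sim_config(seed = seed)

path <- function(...) file.path(res_dir, ...)

read_truth <- function() {
  tr <- jsonlite::read_json(path("truth.json"), simplifyVector = TRUE)
  tr$chrom_lens <- unlist(tr$chrom_lens)
  tr$scaffold_lens <- unlist(tr$scaffold_lens)
  tr
}
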