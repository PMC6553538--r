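#' Split scaffolds into contigs at long N-runs
#'
#' Breaks each scaffold at every maximal run of N of length at least
#' `min_n_run` (the QUAST `--split-scaffolds` rule); shorter N-runs are
#' retained inside contigs. Contigs are named `parent.1`, `parent.2`, ...
#' An all-N scaffold yields no contigs.
#'
#' @param records named character vector of scaffold sequences.
#' @param min_n_run minimum N-run length that breaks a scaffold (default 10).
#' @return named character vector of contigs.
#' @export
split_scaffolds <- function(records, min_n_run = 10L) {
  out <- character(0)
  pat <- sprintf("N{%d,}", min_n_run)
  for (nm in names(records)) {
    pieces <- strsplit(gsub(pat, "\r", records[[nm]]), "\r", fixed = TRUE)[[1]]
    pieces <- pieces[nzchar(pieces)]
    if (!length(pieces)) next
    names(pieces) <- sprintf("%s.%d", nm, seq_along(pieces))
    out <- c(out, pieces)
  }
  out
}

#' Nxx length statistic
#'
#' Smallest length L such that sequences of length >= L cover at least x% of
#' the total assembly length (N50 for x = 50).
#'
#' @param lengths sequence lengths (non-empty).
#' @param x coverage percentage (default 50).
#' @return the Nxx value in bp.
#' @export
nxx <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty length vector")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= x / 100 * cum[length(cum)])[1]]
}

#' Assembly summary statistics
#'
#' Sequence count, total length, N50 and longest sequence, for the scaffold
#' set and (optionally) its contig version after N-run splitting.
#'
#' @param records named character vector of sequences.
#' @param split also compute contig-version stats via [split_scaffolds()].
#' @param min_n_run N-run splitting threshold.
#' @return list with `n_sequences`, `total_bp`, `n50`, `longest`, and if
#'   `split`, a nested `contigs` list of the same shape.
#' @export
assembly_stats <- function(records, split = FALSE, min_n_run = 10L) {
  lens <- nchar(records)
  out <- list(n_sequences = length(records), total_bp = sum(lens),
              n50 = nxx(lens), longest = max(lens))
  if (split) {
    contigs <- split_scaffolds(records, min_n_run)
    out$contigs <- assembly_stats(contigs, split = FALSE)
  }
  out
}

#' N50 improvement ratio
#'
#' Ratio of two N50 values, reported at one decimal with half-up rounding
#' (the convention of assembly comparison tables).
#'
#' @param n50_new,n50_old N50 of the improved and the baseline assembly.
#' @return ratio rounded to 1 decimal.
#' @export
n50_improvement <- function(n50_new, n50_old) {
  check_that(n50_old > 0, "baseline N50 must be positive")
  round_half_up(n50_new / n50_old, 1)
}

# Canonical k-mer hash sets (double-precision exact packing; k <= 26 keeps
# 2k bits within the 53-bit mantissa). N-containing k-mers are excluded.
kmer_hash_set <- function(seqs, k) {
  acc <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    codes <- encode_dna(s)
    m <- n - k + 1L
    fwd <- numeric(m); ok <- rep(TRUE, m)
    for (j in 0:(k - 1L)) {
      cj <- codes[(1L + j):(m + j)]
      ok <- ok & cj < 4L
      fwd <- fwd * 4 + ifelse(cj < 4L, cj, 0)
    }
    rcodes <- 3L - rev(codes)
    rc <- numeric(m)
    for (j in 0:(k - 1L)) {
      cj <- rcodes[(1L + j):(m + j)]
      rc <- rc * 4 + ifelse(cj >= 0L & cj < 4L, cj, 0)
    }
    rc <- rev(rc)  # rc[i] = hash of revcomp of window i
    canon <- pmin(fwd, rc)[ok]
    acc[[length(acc) + 1L]] <- unique(canon)
  }
  unique(unlist(acc))
}

#' k-mer completeness of an assembly against a reference
#'
#' Fraction of distinct canonical reference k-mers (min of forward and
#' reverse-complement encoding) that occur anywhere in the assembly. k-mers
#' containing N are excluded on both sides.
#'
#' @param reference,assembly named character vectors of sequences.
#' @param k k-mer size (default 21; must be between 1 and 26).
#' @return fraction in \[0, 1\].
#' @export
kmer_completeness <- function(reference, assembly, k = 21L) {
  if (k < 1) stop("k must be >= 1")
  if (k > 26) stop("k must be <= 26 (exact double packing)")
  refset <- kmer_hash_set(reference, k)
  if (length(refset) == 0) stop("reference has no valid k-mers at k = ", k)
  asmset <- kmer_hash_set(assembly, k)
  sum(refset %in% asmset) / length(refset)
}
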