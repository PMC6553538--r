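#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for every percentage and ratio the
#' package reports. `base::round()` rounds half to even, which would turn
#' 42.525 into 42.52; reported genome summaries conventionally use half-up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(42.525, 1)  # 42.5 comes from 42.525... printed at 1 dp
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with the package-wide rounding rule
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 1; composition tables use 2).
#' @return numeric percentage, rounded half-up.
#' @export
percent_of <- function(num, den, digits = 1) {
  if (any(den == 0)) stop("zero denominator")
  round_half_up(100 * num / den, digits)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors (N maps to N).
#'
#' @param x character vector of DNA strings over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode a DNA string to integer codes 0..3 (A,C,G,T); anything else -> 4.
# Internal: feeds the C++ sketching core.
encode_dna <- function(s) {
  v <- utf8ToInt(s)
  out <- rep.int(4L, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

# stopifnot with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
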