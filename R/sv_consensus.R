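#' Merge two structural-variant callsets into a consensus set
#'
#' Greedy 1-to-1 matching: a pair of calls (one per callset) may merge when
#' the SV types match (if `require_type_match`) and both breakpoints lie
#' within `max_breakpoint_dist` (inclusive); candidate pairs are processed in
#' ascending total breakpoint distance, ties broken by (chrom, start, caller
#' tag). A merged record takes the mean of the two breakpoint pairs and lists
#' both supporting callers; unmatched calls are retained with support 1, so
#' the "common" set is the `support == 2` subset.
#'
#' @param set_a,set_b SV data.frames: chrom, start, end (0-based half-open),
#'   svtype (DEL/DUP/INV/INS/TRA), size, caller; TRA records may carry a
#'   `chrom2` column for the second breakend (both loci must then match
#'   within the distance bound).
#' @param max_breakpoint_dist maximum per-breakpoint distance (default 1000).
#' @param require_type_match only merge same-type calls (default TRUE).
#' @return consensus data.frame with `support` and `callers` columns.
#' @export
merge_callsets <- function(set_a, set_b, max_breakpoint_dist = 1000L,
                           require_type_match = TRUE) {
  a <- set_a; b <- set_b
  chr2 <- function(d) if (!is.null(d$chrom2)) d$chrom2 else d$chrom
  pairs <- NULL
  if (nrow(a) && nrow(b)) {
    idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    ok <- a$chrom[idx$i] == b$chrom[idx$j] &
      chr2(a)[idx$i] == chr2(b)[idx$j]
    if (require_type_match) ok <- ok & a$svtype[idx$i] == b$svtype[idx$j]
    idx <- idx[ok, , drop = FALSE]
    ds <- abs(a$start[idx$i] - b$start[idx$j])
    de <- abs(a$end[idx$i] - b$end[idx$j])
    ok <- ds <= max_breakpoint_dist & de <= max_breakpoint_dist
    idx <- idx[ok, , drop = FALSE]
    if (nrow(idx)) {
      idx$dist <- ds[ok] + de[ok]
      idx <- idx[order(idx$dist, a$chrom[idx$i], a$start[idx$i],
                       a$caller[idx$i], b$caller[idx$j]), , drop = FALSE]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      keep <- logical(nrow(idx))
      for (r in seq_len(nrow(idx))) {
        i <- idx$i[r]; j <- idx$j[r]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        keep[r] <- TRUE
      }
      pairs <- idx[keep, , drop = FALSE]
    }
  }
  rows <- list()
  matched_a <- if (!is.null(pairs)) pairs$i else integer(0)
  matched_b <- if (!is.null(pairs)) pairs$j else integer(0)
  if (!is.null(pairs) && nrow(pairs)) {
    i <- pairs$i; j <- pairs$j
    ms <- as.integer(round((a$start[i] + b$start[j]) / 2))
    me <- as.integer(round((a$end[i] + b$end[j]) / 2))
    sz <- ifelse(a$svtype[i] == "INS",
                 as.integer(round((a$size[i] + b$size[j]) / 2)),
                 pmax(1L, me - ms))
    rows[[1]] <- data.frame(chrom = a$chrom[i], start = ms, end = me,
                            svtype = a$svtype[i], size = sz, support = 2L,
                            callers = paste(a$caller[i], b$caller[j],
                                            sep = ","),
                            stringsAsFactors = FALSE)
  }
  solo <- function(d, matched) {
    d <- d[setdiff(seq_len(nrow(d)), matched), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               svtype = d$svtype, size = d$size, support = 1L,
               callers = d$caller, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- solo(a, matched_a)
  rows[[length(rows) + 1L]] <- solo(b, matched_b)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), svtype = character(),
                      size = integer(), support = integer(),
                      callers = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$svtype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# lower median: for even n, the lower of the two central order statistics
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[floor((n + 1) / 2)]
}

#' Per-class summary of a structural-variant set
#'
#' Counts, sizes (lower median, so an even-sized class reports an attained
#' size) and gene overlap (any overlap of at least 1 bp) per SV class.
#'
#' @param svs SV data.frame (chrom, start, end, svtype, size).
#' @param genes optional gene interval data.frame (chrom, start, end).
#' @return data.frame: svtype, n, median_size, n_gene_overlap (NA when no
#'   genes given).
#' @export
summarize_sv <- function(svs, genes = NULL) {
  classes <- c("DEL", "DUP", "INV", "INS", "TRA")
  present <- union(classes, unique(svs$svtype))
  gene_hit <- if (!is.null(genes) && nrow(svs))
    IRanges::overlapsAny(intervals_to_gr(svs),
                               intervals_to_gr(genes))
  else rep(NA, nrow(svs))
  out <- do.call(rbind, lapply(present, function(cl) {
    d <- svs[svs$svtype == cl, , drop = FALSE]
    data.frame(svtype = cl, n = nrow(d),
               median_size = lower_median(d$size),
               n_gene_overlap = if (is.null(genes)) NA_integer_
                                else sum(gene_hit[svs$svtype == cl]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read an SV callset from TSV or VCF
#'
#' TSV: columns chrom, start, end, svtype, size (header optional). VCF: uses
#' the SVTYPE, END and SVLEN INFO keys.
#'
#' @param path input path.
#' @param caller caller tag to attach.
#' @return SV data.frame (chrom, start, end, svtype, size, caller).
#' @export
read_sv_callset <- function(path, caller = "caller") {
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix)))
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    info_get <- function(info, key) {
      m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
    }
    info <- fix[, "INFO"]
    svtype <- info_get(info, "SVTYPE")
    endp <- as.integer(info_get(info, "END"))
    svlen <- suppressWarnings(as.integer(info_get(info, "SVLEN")))
    pos <- as.integer(fix[, "POS"])
    start <- pos - 1L
    end <- ifelse(is.na(endp), start + 1L, endp)
    size <- ifelse(!is.na(svlen), abs(svlen),
                   pmax(1L, end - start))
    out <- data.frame(chrom = fix[, "CHROM"], start = start, end = end,
                      svtype = svtype, size = as.integer(size),
                      caller = caller, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = grepl("chrom", first),
                            sep = "\t", stringsAsFactors = FALSE)
    colnames(df)[1:5] <- c("chrom", "start", "end", "svtype", "size")
    out <- df[, 1:5]
    out$caller <- caller
  }
  check_that(all(out$size > 0), "SV with non-positive size")
  out
}
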