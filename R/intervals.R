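#' @importFrom IRanges IRanges findOverlaps reduce coverage
#' @importFrom S4Vectors queryHits subjectHits runLength runValue
NULL

# All genomic coordinates in this package are 0-based half-open ([start, end)),
# i.e. the BED convention; GTF input is converted on read. IRanges is 1-based
# closed, so conversion happens at the boundary in .as_iranges().

#' Construct a table of genomic intervals
#'
#' The elementary coordinate record used throughout the package: 0-based
#' half-open intervals with a mandatory strand.
#'
#' @param chrom character vector of chromosome/contig names.
#' @param start,end integer vectors; `0 <= start < end`, end exclusive.
#' @param strand character vector of `"+"` or `"-"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 100, 150, "+")
#' @export
genomic_intervals <- function(chrom, start, end, strand) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must not be NA")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start (half-open)")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(df)
}

# 0-based half-open -> IRanges (1-based closed)
.as_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Overlap query between two interval tables
#'
#' Finds all pairs of intervals that overlap by at least one nucleotide on the
#' same chromosome; strand is matched only when both tables carry it and
#' `same_strand = TRUE`.
#'
#' @param query,subject data.frames with `chrom`, `start`, `end` (and `strand`).
#' @param same_strand require matching strand (default TRUE).
#' @return data.frame with columns `query`, `subject` (row indices).
#' @export
overlap_pairs <- function(query, subject, same_strand = TRUE) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer()))
  qkey <- if (same_strand) paste(query$chrom, query$strand) else query$chrom
  skey <- if (same_strand) paste(subject$chrom, subject$strand) else subject$chrom
  out <- vector("list", 0L)
  for (key in intersect(unique(qkey), unique(skey))) {
    qi <- which(qkey == key)
    si <- which(skey == key)
    hits <- IRanges::findOverlaps(.as_iranges(query$start[qi], query$end[qi]),
                                  .as_iranges(subject$start[si], subject$end[si]))
    out[[length(out) + 1L]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                                          subject = si[S4Vectors::subjectHits(hits)])
  }
  if (length(out) == 0) return(data.frame(query = integer(), subject = integer()))
  res <- do.call(rbind, out)
  res[order(res$query, res$subject), , drop = FALSE]
}

# Intersect a set of disjoint sorted intervals (start/end vectors) with [lo, hi)
.clip_intervals <- function(start, end, lo, hi) {
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}
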