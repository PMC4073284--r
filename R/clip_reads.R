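# CLIP read layout: reads start with a fixed-length replicate index and a
# degenerate barcode, followed by the insert and an enzymatically added polyA
# tail. The degenerate barcode distinguishes unique cDNA clones from PCR
# duplicates; the index multiplexes replicates.

#' Describe the CLIP read layout
#'
#' @param indices named character vector: known index sequences, names are
#'   replicate ids (e.g. `c(rep1 = "ACGTAC", rep2 = "TTGCAA")`).
#' @param index_len,barcode_len hexamer lengths by default (6 + 6).
#' @param order order of the two elements at the read start.
#' @param max_mismatch tolerated index mismatches (default 0: 6-nt indices
#'   leave little edit-distance margin).
#' @param min_insert minimum insert length after trimming (default 18 nt).
#' @param polya_min minimum trailing polyA run to trim (default 6 nt).
#' @param polya_frac minimum A content of the trimmed tail (default 0.9;
#'   enzymatic tailing produces long but imperfect tails).
#' @return a `clip_layout` list.
#' @export
clip_layout <- function(indices, index_len = 6L, barcode_len = 6L,
                        order = c("index", "barcode"), max_mismatch = 0L,
                        min_insert = 18L, polya_min = 6L, polya_frac = 0.9) {
  stopifnot(length(indices) >= 1, !is.null(names(indices)),
            all(nchar(indices) == index_len),
            all(sort(order) == c("barcode", "index")))
  structure(list(indices = indices, index_len = as.integer(index_len),
                 barcode_len = as.integer(barcode_len), order = order,
                 max_mismatch = as.integer(max_mismatch),
                 min_insert = as.integer(min_insert),
                 polya_min = as.integer(polya_min), polya_frac = polya_frac),
            class = "clip_layout")
}

.hamming <- function(x, pattern) {
  n <- nchar(pattern)
  xm <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
               ncol = n, byrow = TRUE)
  pm <- strsplit(pattern, "", fixed = TRUE)[[1]]
  rowSums(xm != matrix(pm, nrow = nrow(xm), ncol = n, byrow = TRUE))
}

# Longest trailing run with >= polya_frac A content, minimum polya_min nt.
.polya_trim_len <- function(seq, polya_min, polya_frac) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < polya_min) return(0L)
  is_a <- rev(chars) == "A"
  frac <- cumsum(is_a) / seq_len(n)
  # a run must begin with A: never trim a non-A boundary base into the tail
  ok <- which(frac >= polya_frac & seq_len(n) >= polya_min & is_a)
  if (length(ok) == 0) 0L else max(ok)
}

#' Demultiplex and trim raw CLIP reads
#'
#' Splits each read into index, degenerate barcode and insert per the layout,
#' routes reads to replicates by exact (or `max_mismatch`-tolerant) index
#' match, trims the trailing polyA run, and discards inserts shorter than the
#' minimum. Unknown indices are routed to an `"undetermined"` bucket and
#' counted, never silently dropped.
#'
#' @param reads named character vector of read sequences (names = read ids),
#'   e.g. from [read_fastq()].
#' @param layout a [clip_layout()].
#' @return data.frame: `read_id`, `replicate`, `barcode`, `insert`, with
#'   attribute `tallies` (named counts: per replicate, `undetermined`,
#'   `too_short`).
#' @export
demultiplex_and_trim <- function(reads, layout) {
  stopifnot(inherits(layout, "clip_layout"))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  head_len <- layout$index_len + layout$barcode_len
  long_enough <- nchar(reads) >= head_len + 1L
  idx_off <- if (layout$order[1] == "index") 0L else layout$barcode_len
  bc_off <- if (layout$order[1] == "index") layout$index_len else 0L
  index_seq <- substr(reads, idx_off + 1L, idx_off + layout$index_len)
  barcode <- substr(reads, bc_off + 1L, bc_off + layout$barcode_len)
  rest <- substr(reads, head_len + 1L, nchar(reads))

  replicate <- rep("undetermined", length(reads))
  dist <- matrix(Inf, length(reads), length(layout$indices))
  if (any(long_enough))
    dist[long_enough, ] <- vapply(unname(layout$indices), function(ix)
      .hamming(index_seq[long_enough], ix), numeric(sum(long_enough)))
  best <- apply(dist, 1, which.min)
  bestd <- dist[cbind(seq_along(best), best)]
  hit <- is.finite(bestd) & bestd <= layout$max_mismatch
  # ambiguous best matches (two indices equally close) stay undetermined
  if (any(hit)) {
    ties <- rowSums(dist[hit, , drop = FALSE] ==
                      bestd[hit]) > 1
    replicate[hit][!ties] <- names(layout$indices)[best[hit][!ties]]
  }

  trim <- vapply(rest, .polya_trim_len, integer(1),
                 polya_min = layout$polya_min, polya_frac = layout$polya_frac,
                 USE.NAMES = FALSE)
  insert <- substr(rest, 1L, nchar(rest) - trim)

  known <- replicate != "undetermined"
  too_short <- known & nchar(insert) < layout$min_insert
  keep <- known & !too_short
  out <- data.frame(read_id = names(reads)[keep], replicate = replicate[keep],
                    barcode = barcode[keep], insert = insert[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  tallies <- c(table(factor(out$replicate, levels = names(layout$indices))),
               undetermined = sum(!known), too_short = sum(too_short))
  attr(out, "tallies") <- tallies
  out
}

#' Collapse PCR duplicates into unique CLIP tags
#'
#' One tag per unique key `(replicate, chrom, start, strand, barcode)`: reads
#' sharing alignment start and degenerate barcode within a replicate derive
#' from one cDNA clone. The alignment start (not the full span) defines the
#' clone because reverse-transcription truncation lengths differ. The
#' representative read is the longest (ties broken lexicographically by
#' read_id); deletion offsets are merged as the union across duplicates,
#' preserving crosslink evidence.
#'
#' @param reads data.frame with `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `replicate`, `barcode` and list-column `deletions` (0-based offsets from
#'   the tag's genomic start; optional, defaults to none).
#' @return tag table: `tag_id`, `chrom`, `start`, `end`, `strand`,
#'   `replicate`, `barcode`, `collapsed_count`, list-column `deletions`.
#' @export
collapse_duplicates <- function(reads) {
  need <- c("chrom", "start", "end", "strand", "replicate", "barcode")
  miss <- setdiff(need, names(reads))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(reads$barcode)) || any(!nzchar(reads$barcode)))
    stop("missing barcode: cannot deduplicate")
  if (is.null(reads$deletions)) reads$deletions <- rep(list(integer()), nrow(reads))
  if (is.null(reads$read_id)) reads$read_id <- paste0("r", seq_len(nrow(reads)))
  if (nrow(reads)) {
    len <- reads$end - reads$start
    bad <- vapply(seq_len(nrow(reads)), function(i) {
      d <- reads$deletions[[i]]
      length(d) > 0 && (any(d < 0) || any(d >= len[i]))
    }, logical(1))
    if (any(bad))
      stop("deletion offset outside tag span for read ", reads$read_id[which(bad)[1]])
  }
  key <- paste(reads$replicate, reads$chrom, reads$start, reads$strand,
               reads$barcode, sep = "\r")
  sp <- split(seq_len(nrow(reads)), key)
  rows <- lapply(sp, function(i) {
    r <- reads[i, , drop = FALSE]
    len <- r$end - r$start
    rep_i <- i[order(-len, r$read_id)][1]
    rep_row <- reads[rep_i, , drop = FALSE]
    rep_len <- rep_row$end - rep_row$start
    dels <- sort(unique(unlist(r$deletions)))
    dels <- dels[dels < rep_len]
    rep_row$collapsed_count <- length(i)
    rep_row$deletions <- list(dels)
    rep_row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand, out$replicate, out$barcode), ,
             drop = FALSE]
  out$tag_id <- sprintf("tag%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("tag_id", "chrom", "start", "end", "strand", "replicate", "barcode",
          "collapsed_count", "deletions")]
}

#' Per-replicate tag totals and genic fraction
#'
#' @param tags a tag table.
#' @param ann a `transcript_annotation`; genic = overlapping any same-strand
#'   gene span (pre-mRNA extent).
#' @return list with `per_replicate` (data.frame: replicate, n_tags,
#'   genic_fraction; NA fraction for empty replicates), `total` and
#'   `genic_fraction` overall.
#' @export
count_unique_tags <- function(tags, ann) {
  spans <- gene_spans(ann)
  genic <- rep(FALSE, nrow(tags))
  hits <- overlap_pairs(tags, spans)
  genic[unique(hits$query)] <- TRUE
  reps <- sort(unique(tags$replicate))
  per <- do.call(rbind, lapply(reps, function(r) {
    i <- tags$replicate == r
    data.frame(replicate = r, n_tags = sum(i),
               genic_fraction = if (sum(i) == 0) NA_real_ else mean(genic[i]),
               stringsAsFactors = FALSE)
  }))
  list(per_replicate = per, total = nrow(tags),
       genic_fraction = if (nrow(tags) == 0) NA_real_ else mean(genic))
}
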