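#' Read a transcript annotation from a GTF file
#'
#' Parses `exon` and `CDS` features into per-transcript models. Coordinates are
#' converted from GTF's 1-based closed convention to the package-internal
#' 0-based half-open convention (start decremented on read). Exons are
#' normalized to genomic order per transcript, and transcripts are returned in
#' deterministic `(chrom, start, transcript_id)` order.
#'
#' @param path path to a GTF file.
#' @return An object of class `transcript_annotation`: a list with
#'   \describe{
#'     \item{transcripts}{data.frame: `transcript_id`, `gene_id`, `chrom`,
#'       `strand`, `tx_start`, `tx_end`, `cds_start`, `cds_end` (NA when the
#'       transcript has no CDS), `n_exons`.}
#'     \item{exons}{data.frame: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'       `start`, `end`, `exon_rank` (1 = 5'-most exon in transcript
#'       orientation, so genomically descending on the minus strand).}
#'   }
#' @details Malformed lines (wrong field count, non-numeric or inverted
#'   coordinates, missing transcript_id) raise an error naming the line number.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty GTF: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 lnum[which(nf != 9)[1]], nf[which(nf != 9)[1]]))
  m <- do.call(rbind, fields)
  feature <- m[, 3]
  use <- feature %in% c("exon", "CDS")
  if (!any(use)) stop("GTF contains no exon or CDS features: ", path)
  m <- m[use, , drop = FALSE]
  lnum <- lnum[use]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad))
    stop(sprintf("malformed GTF line %d: invalid coordinates '%s'-'%s'",
                 lnum[bad[1]], m[bad[1], 4], m[bad[1], 5]))
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("malformed GTF line %d: strand must be + or -", lnum[bad[1]]))
  attr_field <- m[, 9]
  tx_id <- .gtf_attr(attr_field, "transcript_id")
  gene_id <- .gtf_attr(attr_field, "gene_id")
  bad <- which(is.na(tx_id) | is.na(gene_id))
  if (length(bad))
    stop(sprintf("malformed GTF line %d: missing gene_id/transcript_id attribute",
                 lnum[bad[1]]))

  rec <- data.frame(chrom = m[, 1], feature = m[, 3], start = start1 - 1L,
                    end = end1, strand = strand, transcript_id = tx_id,
                    gene_id = gene_id, stringsAsFactors = FALSE)
  ex <- rec[rec$feature == "exon", , drop = FALSE]
  cds <- rec[rec$feature == "CDS", , drop = FALSE]
  if (nrow(ex) == 0) stop("GTF contains no exon features: ", path)

  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  tx_list <- lapply(names(sp), function(tid) {
    i <- sp[[tid]]
    e <- ex[i, , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tid)
    ci <- cds[cds$transcript_id == tid, , drop = FALSE]
    cs <- if (nrow(ci)) min(ci$start) else NA_integer_
    ce <- if (nrow(ci)) max(ci$end) else NA_integer_
    rank <- if (e$strand[1] == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
    data.frame(transcript_id = tid, gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1], tx_start = min(e$start), tx_end = max(e$end),
               cds_start = cs, cds_end = ce, n_exons = nrow(e),
               stringsAsFactors = FALSE) -> tr
    list(tr = tr,
         ex = data.frame(transcript_id = tid, gene_id = e$gene_id[1],
                         chrom = e$chrom, strand = e$strand, start = e$start,
                         end = e$end, exon_rank = rank, stringsAsFactors = FALSE))
  })
  transcripts <- do.call(rbind, lapply(tx_list, `[[`, "tr"))
  exons <- do.call(rbind, lapply(tx_list, `[[`, "ex"))
  o <- order(transcripts$chrom, transcripts$tx_start, transcripts$transcript_id)
  transcripts <- transcripts[o, , drop = FALSE]
  rownames(transcripts) <- NULL
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  ann <- list(transcripts = transcripts, exons = exons)
  class(ann) <- "transcript_annotation"
  ann
}

.gtf_attr <- function(x, key) {
  pat <- paste0(key, '[ =]+"([^"]*)"')
  m <- regmatches(x, regexec(pat, x))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, character(1))
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf("transcript_annotation: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

#' Derive functional regions of a transcript
#'
#' Splits a transcript into 5'UTR / CDS / 3'UTR / intron intervals from its CDS
#' bounds, respecting strand. Without a CDS all exonic sequence is labelled
#' `noncoding_exon`. Introns are the gaps between consecutive exons.
#'
#' @param ann a `transcript_annotation`.
#' @param transcript_id single transcript id; default derives regions for all.
#' @return data.frame: `transcript_id`, `gene_id`, `label`, `chrom`, `start`,
#'   `end`, `strand`. Returned intervals are pairwise disjoint and their exonic
#'   labels union to the exon union.
#' @export
derive_regions <- function(ann, transcript_id = NULL) {
  txs <- ann$transcripts
  if (!is.null(transcript_id)) {
    txs <- txs[txs$transcript_id %in% transcript_id, , drop = FALSE]
    if (nrow(txs) == 0) stop("unknown transcript_id")
  }
  out <- lapply(seq_len(nrow(txs)), function(i) {
    tr <- txs[i, ]
    e <- ann$exons[ann$exons$transcript_id == tr$transcript_id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    regs <- list()
    add <- function(label, start, end) {
      if (length(start))
        regs[[length(regs) + 1L]] <<- data.frame(
          transcript_id = tr$transcript_id, gene_id = tr$gene_id, label = label,
          chrom = tr$chrom, start = start, end = end, strand = tr$strand,
          stringsAsFactors = FALSE)
    }
    if (nrow(e) > 1)
      add("intron", e$end[-nrow(e)], e$start[-1])
    if (is.na(tr$cds_start)) {
      add("noncoding_exon", e$start, e$end)
    } else {
      left <- .clip_intervals(e$start, e$end, tr$tx_start, tr$cds_start)
      mid <- .clip_intervals(e$start, e$end, tr$cds_start, tr$cds_end)
      right <- .clip_intervals(e$start, e$end, tr$cds_end, tr$tx_end)
      if (tr$strand == "+") {
        add("5'UTR", left$start, left$end)
        add("3'UTR", right$start, right$end)
      } else {
        add("3'UTR", left$start, left$end)
        add("5'UTR", right$start, right$end)
      }
      add("CDS", mid$start, mid$end)
    }
    do.call(rbind, regs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene spans (pre-mRNA extent per gene)
#'
#' Gene definition used for per-gene statistics: the union span of all
#' transcripts sharing a `gene_id`, so intronic evidence counts toward the gene.
#'
#' @param ann a `transcript_annotation`.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`, `length`.
#' @export
gene_spans <- function(ann) {
  txs <- ann$transcripts
  sp <- split(seq_len(nrow(txs)), txs$gene_id)
  res <- do.call(rbind, lapply(names(sp), function(g) {
    t <- txs[sp[[g]], , drop = FALSE]
    data.frame(gene_id = g, chrom = t$chrom[1], start = min(t$tx_start),
               end = max(t$tx_end), strand = t$strand[1],
               stringsAsFactors = FALSE)
  }))
  res$length <- res$end - res$start
  res <- res[order(res$chrom, res$start, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Priority when one position is covered by several overlapping annotations.
# Exonic evidence outranks an overlapping intron of another isoform, and the
# two headline binding classes rank first.
REGION_PRIORITY <- c("3'UTR" = 1, "5'UTR" = 2, "CDS" = 3,
                     "noncoding_exon" = 4, "intron" = 5, "intergenic" = 6)

#' Assign a single region label to each interval
#'
#' Same-strand assignment against all transcript regions with the fixed
#' priority 3'UTR > 5'UTR > CDS > noncoding_exon > intron > intergenic; an
#' interval with no same-strand gene overlap is `intergenic`. Total: every
#' interval receives exactly one label.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `strand`.
#' @param ann a `transcript_annotation`.
#' @param regions optional precomputed `derive_regions(ann)` table (pass it
#'   when calling repeatedly).
#' @return character vector of labels, one per interval row.
#' @export
assign_region <- function(intervals, ann, regions = NULL) {
  if (is.null(regions)) regions <- derive_regions(ann)
  labels <- rep("intergenic", nrow(intervals))
  hits <- overlap_pairs(intervals, regions)
  if (nrow(hits)) {
    pr <- REGION_PRIORITY[regions$label[hits$subject]]
    best <- tapply(pr, hits$query, min)
    labels[as.integer(names(best))] <-
      names(REGION_PRIORITY)[as.integer(best)]
  }
  labels
}
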