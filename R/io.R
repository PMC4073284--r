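#' @importFrom Biostrings readDNAStringSet DNAStringSet writeXStringSet
#'   reverseComplement letterFrequency
#' @importFrom utils read.delim write.table
NULL

# Writers emit deterministic column order, UTF-8, newline-terminated files.

#' Write intervals as BED6(+) records
#'
#' Standard BED columns `chrom, start, end, name, score, strand` followed by
#' any extra columns named in `extra`. Coordinates are written as stored
#' (0-based half-open; BED native).
#'
#' @param df data.frame with at least `chrom`, `start`, `end`, `strand`.
#' @param path output path.
#' @param name,score column names (or NULL) supplying the BED name/score
#'   fields; defaults write `"."` / `0`.
#' @param extra character vector of additional column names to append.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL, extra = character()) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (is.null(name)) "." else df[[name]],
                    score = if (is.null(score)) 0L else df[[score]],
                    strand = df$strand, stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- df[[col]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read BED6(+) records
#'
#' @param path BED file path.
#' @param extra names for columns beyond the six standard ones (in order).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   and any `extra` columns. Errors on malformed lines name the line number.
#' @export
read_bed <- function(path, extra = character()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- 6L + length(extra)
  nf <- lengths(fields)
  if (any(nf < need))
    stop(sprintf("malformed BED line %d: expected >= %d fields, got %d",
                 which(nf < need)[1], need, nf[which(nf < need)[1]]))
  m <- t(vapply(fields, function(f) f[seq_len(need)], character(need)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("malformed BED line %d: invalid interval '%s'-'%s'",
                 bad[1], m[bad[1], 2], m[bad[1], 3]))
  df <- data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
                   score = suppressWarnings(as.numeric(m[, 5])), strand = m[, 6],
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop(sprintf("malformed BED line %d: strand must be + or -",
                 which(!df$strand %in% c("+", "-"))[1]))
  for (i in seq_along(extra)) df[[extra[i]]] <- m[, 6L + i]
  df
}

#' Write a TSV table with a header row
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path input path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write CLIP tags as BED6+ records
#'
#' Extra columns: `replicate`, `barcode`, `deletions` (comma-separated 0-based
#' offsets within the tag, `"."` when none), `collapsed_count`.
#' @param tags a tag table from [collapse_duplicates()].
#' @param path output path.
#' @export
write_tags_bed <- function(tags, path) {
  df <- tags
  df$deletions <- vapply(tags$deletions, function(d)
    if (length(d) == 0) "." else paste(d, collapse = ","), character(1))
  df$name <- tags$tag_id
  write_bed(df, path, name = "name", score = "collapsed_count",
            extra = c("replicate", "barcode", "deletions", "collapsed_count"))
}

#' Read CLIP tags from BED6+ records
#' @param path BED6+ file written by [write_tags_bed()] (or equivalent).
#' @return tag table with list-column `deletions`.
#' @export
read_tags_bed <- function(path) {
  df <- read_bed(path, extra = c("replicate", "barcode", "deletions",
                                 "collapsed_count"))
  names(df)[names(df) == "name"] <- "tag_id"
  df$collapsed_count <- as.integer(df$collapsed_count)
  df$deletions <- lapply(df$deletions, function(d)
    if (d == "." || !nzchar(d)) integer() else as.integer(strsplit(d, ",")[[1]]))
  df$score <- NULL
  df
}

#' Write annotation back to GTF (exon and CDS features)
#'
#' Inverse of [read_annotation()]: coordinates converted back to GTF 1-based
#' closed on write. Round-tripping reproduces the model bit-identically.
#' @param ann a `transcript_annotation`.
#' @param path output path.
#' @param source source field (column 2).
#' @export
write_annotation <- function(ann, path, source = "rbpreg") {
  lines <- character()
  for (i in seq_len(nrow(ann$transcripts))) {
    tr <- ann$transcripts[i, ]
    e <- ann$exons[ann$exons$transcript_id == tr$transcript_id, , drop = FALSE]
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s";', tr$gene_id,
                     tr$transcript_id)
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              e$chrom, source, e$start + 1L, e$end, e$strand,
                              attr9))
    if (!is.na(tr$cds_start)) {
      cds <- .clip_intervals(e$start, e$end, tr$cds_start, tr$cds_end)
      lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                tr$chrom, source, cds$start + 1L, cds$end,
                                tr$strand, attr9))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read FASTQ records
#' @param path FASTQ file.
#' @return named character vector of sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences as FASTQ (constant quality)
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fastq <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, format = "fastq")
  invisible(path)
}
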