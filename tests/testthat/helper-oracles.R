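# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no IRanges, no shared helpers): plain enumeration only.

# unique-key enumeration for PCR-duplicate collapse
oracle_dedup_keys <- function(reads) {
  unique(paste(reads$replicate, reads$chrom, reads$start, reads$strand,
               reads$barcode, sep = "|"))
}

# connected components over the pairwise-overlap graph (same chrom+strand)
oracle_components <- function(tags) {
  n <- nrow(tags)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    same <- tags$chrom[i] == tags$chrom[j] && tags$strand[i] == tags$strand[j]
    if (same && tags$start[i] < tags$end[j] && tags$start[j] < tags$end[i]) {
      ri <- find(i); rj <- find(j)
      comp[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# per-base pileup maximum by explicit tabulation
oracle_pileup_max <- function(start, end) {
  pos <- unlist(mapply(function(s, e) s:(e - 1), start, end, SIMPLIFY = FALSE))
  tab <- table(pos)
  peak <- max(tab)
  list(height = as.integer(peak),
       position = as.integer(names(tab)[which(tab == peak)[1]]))
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum probabilities of all tables with the observed margins whose point
# probability does not exceed the observed one
oracle_fisher_p <- function(tbl) {
  a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct median-of-ratios size factors (median rescaling applied separately)
oracle_size_factors <- function(counts) {
  pos <- apply(counts > 0, 1, all)
  geo <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    median(col / geo))
  sf / median(sf)
}

# uniform random tag table for property tests
random_tags <- function(n, seed, span = 2000L, chroms = c("c1", "c2"),
                        replicates = c("rep1", "rep2"), len_range = c(20, 60)) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  df <- data.frame(
    tag_id = sprintf("t%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    replicate = sample(replicates, n, replace = TRUE),
    barcode = replicate(n, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                 collapse = "")),
    collapsed_count = 1L, stringsAsFactors = FALSE)
  df$deletions <- rep(list(integer()), n)
  df
}

# tiny two-gene annotation used across tests
toy_annotation <- function() {
  gtf <- c(
    'chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\texon\t201\t300\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\tCDS\t51\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\tCDS\t201\t250\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ttest\texon\t401\t500\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr1\ttest\texon\t601\t700\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr1\ttest\tCDS\t451\t500\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr1\ttest\tCDS\t601\t650\t.\t-\t.\tgene_id "gB"; transcript_id "tB";')
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(gtf, path)
  read_annotation(path)
}
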