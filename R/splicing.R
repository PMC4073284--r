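# Cassette-exon analysis: a cassette (CA) exon sits between two constitutive
# flanking exons (5'CE, 3'CE). Junction-spanning reads provide three pieces of
# evidence per event and sample: inc_up (5'CE-CA), inc_down (CA-3'CE) and
# skip (5'CE-3'CE). Events are stored in genomic coordinates with exon1 <
# exon2 < exon3 left to right; on the minus strand exon3 is the 5'CE.

#' Construct a cassette-event table
#'
#' @param event_id,gene_id identifiers.
#' @param chrom,strand location.
#' @param e1_start,e1_end,e2_start,e2_end,e3_start,e3_end genomic 0-based
#'   half-open coordinates of the three exons, left to right (`e2` is the CA
#'   exon; `e1` is the 5'CE on `+`, the 3'CE on `-`).
#' @return data.frame of class `cassette_events`.
#' @export
cassette_events <- function(event_id, gene_id, chrom, strand,
                            e1_start, e1_end, e2_start, e2_end,
                            e3_start, e3_end) {
  df <- data.frame(event_id = as.character(event_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom), strand = as.character(strand),
                   e1_start = as.integer(e1_start), e1_end = as.integer(e1_end),
                   e2_start = as.integer(e2_start), e2_end = as.integer(e2_end),
                   e3_start = as.integer(e3_start), e3_end = as.integer(e3_end),
                   stringsAsFactors = FALSE)
  ok <- df$e1_start < df$e1_end & df$e1_end <= df$e2_start &
    df$e2_start < df$e2_end & df$e2_end <= df$e3_start & df$e3_start < df$e3_end
  if (!all(ok)) stop("malformed exon order in event ", df$event_id[which(!ok)[1]])
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  class(df) <- c("cassette_events", "data.frame")
  df
}

# genomic junction (left exon end, right exon start) per event and junction type
.event_junctions <- function(events) {
  plus <- events$strand == "+"
  ju <- function(type, jl, jr)
    data.frame(event_id = events$event_id, type = type, chrom = events$chrom,
               strand = events$strand, jl = jl, jr = jr,
               stringsAsFactors = FALSE)
  rbind(
    ju(ifelse(plus, "inc_up", "inc_down"), events$e1_end, events$e2_start),
    ju(ifelse(plus, "inc_down", "inc_up"), events$e2_end, events$e3_start),
    ju("skip", events$e1_end, events$e3_start))
}

#' Count junction reads per cassette event
#'
#' Matches junction evidence to each event's three junctions by exact genomic
#' coordinates (a junction off by even 1 nt is not counted); unmatched
#' junction records are tallied, not silently dropped.
#'
#' @param junctions data.frame: `sample`, `chrom`, `strand`, `jl` (end of the
#'   left exon, 0-based exclusive), `jr` (start of the right exon), `count`.
#' @param events a [cassette_events()] table.
#' @return data.frame: `event_id`, `sample`, `inc_up`, `inc_down`, `skip`
#'   (one row per event x sample present in `junctions`), with attribute
#'   `unmatched` (number of junction records matching no event junction).
#' @export
count_junction_reads <- function(junctions, events) {
  ej <- .event_junctions(events)
  jkey <- paste(junctions$chrom, junctions$strand, junctions$jl, junctions$jr,
                sep = "\r")
  ekey <- paste(ej$chrom, ej$strand, ej$jl, ej$jr, sep = "\r")
  m <- match(jkey, ekey)
  unmatched <- sum(is.na(m))
  samples <- sort(unique(junctions$sample))
  grid <- expand.grid(event_id = events$event_id, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$event_id, grid$sample, sep = "\r")
  hit <- which(!is.na(m))
  for (type in c("inc_up", "inc_down", "skip")) {
    grid[[type]] <- 0L
    i <- hit[ej$type[m[hit]] == type]
    if (length(i)) {
      sums <- tapply(as.integer(junctions$count[i]),
                     paste(ej$event_id[m[i]], junctions$sample[i], sep = "\r"),
                     sum)
      rows <- match(names(sums), gkey)
      grid[[type]][rows] <- as.integer(sums)
    }
  }
  attr(grid, "unmatched") <- unmatched
  grid
}

#' Inclusion rate from junction counts
#'
#' `I = (inc_up + inc_down) / 2` (averaging the two inclusion junctions avoids
#' double-counting inclusion evidence against the single skip junction);
#' `IR = I / (I + skip)`. All-zero counts give NA.
#'
#' @param inc_up,inc_down,skip non-negative counts (vectorized).
#' @return inclusion rate in \[0, 1\], NA where all three counts are zero.
#' @export
inclusion_rate <- function(inc_up, inc_down, skip) {
  if (any(c(inc_up, inc_down, skip) < 0)) stop("counts must be non-negative")
  i <- (inc_up + inc_down) / 2
  ifelse(i + skip == 0, NA_real_, i / (i + skip))
}

#' Condition-averaged inclusion change per event
#'
#' IR is averaged across replicates within each condition, and
#' `delta_i = mean IR(treatment) - mean IR(control)`; positive values indicate
#' factor-dependent inclusion. Averaging per cell type first identifies
#' reciprocal splicing changes while normalizing for RNA-stability changes.
#'
#' @param counts per-sample junction counts ([count_junction_reads()]).
#' @param design data.frame: `sample`, `condition`.
#' @param treatment,control condition labels.
#' @return data.frame: `event_id`, `ir_treatment`, `ir_control`, `delta_i`,
#'   `total_reads` (junction reads summed over all samples).
#' @export
delta_I <- function(counts, design, treatment = "treatment",
                    control = "control") {
  cond <- design$condition[match(counts$sample, design$sample)]
  if (any(is.na(cond))) stop("sample missing from design")
  if (!all(c(treatment, control) %in% design$condition))
    stop("missing condition: need both '", treatment, "' and '", control, "'")
  counts$ir <- inclusion_rate(counts$inc_up, counts$inc_down, counts$skip)
  counts$reads <- counts$inc_up + counts$inc_down + counts$skip
  res <- do.call(rbind, lapply(split(counts, counts$event_id), function(e) {
    ct <- design$condition[match(e$sample, design$sample)]
    data.frame(event_id = e$event_id[1],
               ir_treatment = mean(e$ir[ct == treatment], na.rm = TRUE),
               ir_control = mean(e$ir[ct == control], na.rm = TRUE),
               total_reads = sum(e$reads), stringsAsFactors = FALSE)
  }))
  res$ir_treatment[is.nan(res$ir_treatment)] <- NA_real_
  res$ir_control[is.nan(res$ir_control)] <- NA_real_
  res$delta_i <- res$ir_treatment - res$ir_control
  res <- res[match(unique(counts$event_id), res$event_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("event_id", "ir_treatment", "ir_control", "delta_i", "total_reads")]
}

#' Fisher exact test on pooled isoform evidence
#'
#' 2 x 2 table of pooled (isoform-1, isoform-2) x condition counts, where
#' isoform-1 evidence is `inc_up + inc_down` and isoform-2 is `skip`, pooled
#' over replicates per condition. Two-sided exact test; a zero margin gives
#' p = 1 by convention.
#'
#' @param counts,design,treatment,control as in [delta_I()].
#' @return data.frame: `event_id`, `fisher_p`.
#' @export
fisher_splice_test <- function(counts, design, treatment = "treatment",
                               control = "control") {
  cond <- design$condition[match(counts$sample, design$sample)]
  if (any(is.na(cond))) stop("sample missing from design")
  res <- do.call(rbind, lapply(split(seq_len(nrow(counts)), counts$event_id),
                               function(i) {
    ct <- cond[i]
    inc <- counts$inc_up[i] + counts$inc_down[i]
    skp <- counts$skip[i]
    tbl <- rbind(c(sum(inc[ct == treatment]), sum(skp[ct == treatment])),
                 c(sum(inc[ct == control]), sum(skp[ct == control])))
    p <- if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) 1
         else stats::fisher.test(tbl)$p.value
    data.frame(event_id = counts$event_id[i][1], fisher_p = p,
               stringsAsFactors = FALSE)
  }))
  res <- res[match(unique(counts$event_id), res$event_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call regulated cassette exons
#'
#' An event passes when total junction reads >= `min_reads` (summed over all
#' samples), `|delta_i| >= min_delta` and `fisher_p <= max_p`; the sign of
#' delta_i splits included (positive) from excluded (negative) events.
#'
#' @param stats data.frame with `event_id`, `delta_i`, `total_reads`,
#'   `fisher_p` (merge of [delta_I()] and [fisher_splice_test()]).
#' @param min_reads,min_delta,max_p thresholds (defaults 10, 0.2, 0.05).
#' @return `stats` with a `status` column in `{"included", "excluded", "ns"}`.
#' @export
call_regulated_exons <- function(stats, min_reads = 10L, min_delta = 0.2,
                                 max_p = 0.05) {
  pass <- !is.na(stats$delta_i) & stats$total_reads >= min_reads &
    abs(stats$delta_i) >= min_delta & stats$fisher_p <= max_p
  stats$status <- "ns"
  stats$status[pass & stats$delta_i > 0] <- "included"
  stats$status[pass & stats$delta_i < 0] <- "excluded"
  stats
}

#' Is a cassette exon bound?
#'
#' True when the summed tag count of qualifying clusters (BC >= `min_bc` and
#' total tags >= `min_cluster_tags`) overlapping the region from the start of
#' the event's leftmost exon to the end of its rightmost exon, on the event
#' strand, reaches `min_total` tags.
#'
#' @param events a [cassette_events()] table.
#' @param clusters annotated cluster table.
#' @param min_bc,min_cluster_tags,min_total thresholds (defaults 2, 5, 10).
#' @return logical vector, one per event.
#' @export
bound_exon <- function(events, clusters, min_bc = 2L, min_cluster_tags = 5L,
                       min_total = 10L) {
  keep <- clusters$bc >= min_bc & clusters$total_tags >= min_cluster_tags
  cl <- clusters[keep, , drop = FALSE]
  span <- data.frame(chrom = events$chrom, start = events$e1_start,
                     end = events$e3_end, strand = events$strand,
                     stringsAsFactors = FALSE)
  out <- rep(FALSE, nrow(events))
  if (nrow(cl) == 0) return(out)
  hits <- overlap_pairs(span, cl)
  if (nrow(hits)) {
    tot <- tapply(cl$total_tags[hits$subject], hits$query, sum)
    out[as.integer(names(tot))] <- tot >= min_total
  }
  out
}

#' Normalized splicing complexity map
#'
#' For each of the four exon-intron boundaries of the composite cassette
#' transcript (5'CE donor, CA acceptor, CA donor, 3'CE acceptor) and each
#' offset (a fixed exonic margin into the exon, up to `window` nt into the
#' intron, truncated at the actual intron midpoint for short introns), the
#' profile value is the fraction of events in the class with >= 1 tag covering
#' that position. Values are therefore bounded in \[0, 1\].
#'
#' @param events a [cassette_events()] table.
#' @param status character vector per event (`"included"` / `"excluded"` /
#'   other); profiles are built for the included and excluded classes.
#' @param tags tag table.
#' @param window maximum intronic extent in nt (default 1000).
#' @param exon_margin exonic extent in nt (default 50).
#' @return data.frame: `class`, `boundary` (one of `ce5_donor`, `ca_acceptor`,
#'   `ca_donor`, `ce3_acceptor`), `offset` (negative = exonic side, 0 = first
#'   intronic base, in transcript orientation), `fraction`, `n_events`.
#' @export
complexity_map <- function(events, status, tags, window = 1000L,
                           exon_margin = 50L) {
  stopifnot(length(status) == nrow(events))
  classes <- intersect(c("included", "excluded"), unique(status))
  out <- list()
  for (cls in classes) {
    ev <- events[status == cls, , drop = FALSE]
    acc <- list()  # boundary -> matrix [event, offset] of coverage
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      covered <- .event_coverage(e, tags, window)
      intron5 <- c(e$e1_end, e$e2_start)  # genomic left intron
      intron3 <- c(e$e2_end, e$e3_start)  # genomic right intron
      if (e$strand == "+") {
        b <- list(ce5_donor = list(edge = e$e1_end, dir = +1, intron = intron5),
                  ca_acceptor = list(edge = e$e2_start, dir = -1, intron = intron5),
                  ca_donor = list(edge = e$e2_end, dir = +1, intron = intron3),
                  ce3_acceptor = list(edge = e$e3_start, dir = -1, intron = intron3))
      } else {
        b <- list(ce5_donor = list(edge = e$e3_start, dir = -1, intron = intron3),
                  ca_acceptor = list(edge = e$e2_end, dir = +1, intron = intron3),
                  ca_donor = list(edge = e$e2_start, dir = -1, intron = intron5),
                  ce3_acceptor = list(edge = e$e1_end, dir = +1, intron = intron5))
      }
      for (bn in names(b)) {
        spec <- b[[bn]]
        mid <- floor((spec$intron[1] + spec$intron[2]) / 2)
        # offsets in transcript orientation: -exon_margin .. -1 exonic,
        # 0 .. window-1 intronic (truncated at the intron midpoint)
        offs <- seq.int(-exon_margin, window - 1L)
        if (spec$dir == +1) {  # intron extends genomically rightward
          gpos <- spec$edge + offs
          ok_intron <- offs < 0 | gpos < mid
        } else {               # intron extends genomically leftward
          gpos <- spec$edge - 1L - offs
          ok_intron <- offs < 0 | gpos >= mid
        }
        vals <- rep(NA, length(offs))
        inb <- gpos >= covered$lo & gpos < covered$hi & ok_intron
        vals[inb] <- covered$cov[gpos[inb] - covered$lo + 1L] > 0
        acc[[bn]] <- rbind(acc[[bn]], vals)
      }
    }
    for (bn in names(acc)) {
      m <- acc[[bn]]
      frac <- colMeans(m, na.rm = TRUE)
      frac[is.nan(frac)] <- 0
      out[[length(out) + 1L]] <- data.frame(
        class = cls, boundary = bn,
        offset = seq.int(-exon_margin, window - 1L),
        fraction = frac, n_events = nrow(ev), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(class = character(), boundary = character(),
                      offset = integer(), fraction = numeric(),
                      n_events = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-event coverage vector over [lo, hi) from same-strand tags
.event_coverage <- function(e, tags, window) {
  lo <- max(e$e1_start - window, 0L)
  hi <- e$e3_end + window
  sel <- tags$chrom == e$chrom & tags$strand == e$strand &
    tags$end > lo & tags$start < hi
  cov <- integer(hi - lo)
  if (any(sel)) {
    s <- pmax(tags$start[sel], lo) - lo
    en <- pmin(tags$end[sel], hi) - lo
    covr <- IRanges::coverage(.as_iranges(s, en), width = hi - lo)
    cov <- as.integer(covr)
  }
  list(lo = lo, hi = hi, cov = cov)
}
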