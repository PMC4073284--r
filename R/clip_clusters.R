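# Tag clustering and the stringency-tier filters: biological complexity (BC,
# number of replicates contributing >= 1 tag), total tags, peak height with a
# gene-level Poisson significance model, and a replicate-reproducibility
# chi-squared score. The peak-significance and reproducibility contracts are
# this package's own reconstructions of thresholds the field cites from prior
# work; the raw height cutoff is kept alongside so the tiers stay
# interpretable either way.

#' Merge overlapping tags into clusters
#'
#' Clusters are maximal runs of same-strand tags where consecutive tags
#' overlap by >= 1 nt (merge gap 0, the most conservative choice). Every tag
#' belongs to exactly one cluster; the cluster interval is the union span of
#' its members.
#'
#' @param tags a tag table (see [collapse_duplicates()]).
#' @param replicates character vector of replicate ids defining the BC
#'   denominator; defaults to the replicates present in `tags`.
#' @return list with `clusters` (data.frame: `cluster_id`, `chrom`, `start`,
#'   `end`, `strand`, `total_tags`, `bc`, one `n_<replicate>` count column per
#'   replicate) and `tags` (the input with a `cluster_id` column).
#' @export
build_clusters <- function(tags, replicates = NULL) {
  if (is.null(replicates)) replicates <- sort(unique(tags$replicate))
  tags$cluster_id <- NA_character_
  if (nrow(tags) == 0) {
    cl <- data.frame(cluster_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     total_tags = integer(), bc = integer())
    return(list(clusters = cl, tags = tags))
  }
  key <- paste(tags$chrom, tags$strand)
  parts <- split(seq_len(nrow(tags)), key)
  rows <- list()
  for (idx in parts) {
    ir <- .as_iranges(tags$start[idx], tags$end[idx])
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    hits <- IRanges::findOverlaps(ir, merged)
    memb <- integer(length(idx))
    memb[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    for (j in seq_along(merged)) {
      i <- idx[memb == j]
      cnt <- table(factor(tags$replicate[i], levels = replicates))
      row <- data.frame(chrom = tags$chrom[i][1],
                        start = min(tags$start[i]), end = max(tags$end[i]),
                        strand = tags$strand[i][1], total_tags = length(i),
                        bc = sum(cnt > 0), stringsAsFactors = FALSE)
      for (r in replicates) row[[paste0("n_", r)]] <- as.integer(cnt[[r]])
      row$.members <- list(i)
      rows[[length(rows) + 1L]] <- row
    }
  }
  cl <- do.call(rbind, rows)
  o <- order(cl$chrom, cl$start, cl$strand)
  cl <- cl[o, , drop = FALSE]
  cl$cluster_id <- sprintf("cl%06d", seq_len(nrow(cl)))
  for (j in seq_len(nrow(cl))) tags$cluster_id[cl$.members[[j]]] <- cl$cluster_id[j]
  cl$.members <- NULL
  rownames(cl) <- NULL
  first <- c("cluster_id", "chrom", "start", "end", "strand", "total_tags", "bc")
  cl <- cl[, c(first, setdiff(names(cl), first))]
  list(clusters = cl, tags = tags)
}

#' Peak height of a cluster
#'
#' Maximum per-base tag depth over the cluster interval; on ties the leftmost
#' maximal position is reported.
#'
#' @param start,end member-tag coordinates (0-based half-open).
#' @return list `height`, `position` (0-based genomic position of the peak).
#' @export
peak_height <- function(start, end) {
  cov <- IRanges::coverage(.as_iranges(start, end))
  h <- max(S4Vectors::runValue(cov))
  ends <- cumsum(S4Vectors::runLength(cov))
  first_run <- which(S4Vectors::runValue(cov) == h)[1]
  pos1 <- if (first_run == 1) 1L else ends[first_run - 1L] + 1L
  list(height = as.integer(h), position = as.integer(pos1 - 1L))
}

#' Gene-level Poisson significance of a peak
#'
#' Under a null of tags scattered uniformly over the gene, per-base depth is
#' approximately Poisson with rate `gene_tag_total * mean_tag_length /
#' gene_length`; the upper-tail probability of the observed peak is
#' Bonferroni-corrected for the `gene_length` positions scanned.
#'
#' @param peak observed peak height (integer >= 1).
#' @param gene_tag_total total tags in the gene.
#' @param gene_length gene span length in nt (> 0).
#' @param mean_tag_length mean tag length in nt.
#' @return p-value clamped to \[0, 1\].
#' @export
peak_significance <- function(peak, gene_tag_total, gene_length,
                              mean_tag_length) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  lambda <- gene_tag_total * mean_tag_length / gene_length
  p <- gene_length * stats::ppois(peak - 1, lambda, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Replicate-reproducibility chi-squared score for a cluster
#'
#' Tests whether the cluster's tags are split across replicates in the same
#' proportions as the rest of the gene's tags (R x 2 table: tags in cluster vs
#' gene tags outside it, per replicate; df = R - 1). A low p flags a
#' replicate-skewed (irreproducible) cluster; the retention rule keeps
#' clusters whose per-replicate proportions do not differ at the threshold.
#' When any expected cell is below 1 the exact test is used instead.
#'
#' @param cluster_counts integer vector: tags in the cluster per replicate.
#' @param gene_totals integer vector: the gene's tags per replicate (same
#'   order; must be >= cluster_counts).
#' @return list `chi2`, `p`.
#' @export
reproducibility_score <- function(cluster_counts, gene_totals) {
  if (length(cluster_counts) < 2) stop("needs >= 2 replicates")
  if (length(gene_totals) != length(cluster_counts))
    stop("gene_totals and cluster_counts must align")
  outside <- gene_totals - cluster_counts
  if (any(outside < 0)) stop("gene totals smaller than cluster counts")
  tbl <- cbind(inside = cluster_counts, outside = outside)
  if (sum(outside) == 0 || sum(cluster_counts) == 0)
    return(list(chi2 = 0, p = 1))  # degenerate margin: nothing to compare
  cs <- suppressWarnings(stats::chisq.test(tbl, correct = FALSE))
  if (any(cs$expected < 1)) {
    p <- stats::fisher.test(tbl)$p.value
    return(list(chi2 = unname(cs$statistic), p = p))
  }
  list(chi2 = unname(cs$statistic), p = unname(cs$p.value))
}

#' Annotate clusters with gene assignment, peak and reproducibility statistics
#'
#' Assigns each cluster to the same-strand gene span with the largest overlap
#' (ties by gene_id), then computes peak height/position, the gene-level
#' Poisson peak p-value and the reproducibility score. Clusters outside any
#' gene get NA gene statistics.
#'
#' @param built result of [build_clusters()].
#' @param ann a `transcript_annotation`.
#' @return the cluster table with added columns `gene_id`, `peak_height`,
#'   `peak_pos`, `peak_p`, `repro_chi2`, `repro_p`.
#' @export
annotate_clusters <- function(built, ann) {
  cl <- built$clusters
  tags <- built$tags
  replicates <- sub("^n_", "", grep("^n_", names(cl), value = TRUE))
  spans <- gene_spans(ann)

  # gene assignment by maximal overlap
  cl$gene_id <- NA_character_
  hits <- overlap_pairs(cl, spans)
  if (nrow(hits)) {
    ov <- pmin(cl$end[hits$query], spans$end[hits$subject]) -
      pmax(cl$start[hits$query], spans$start[hits$subject])
    hits <- hits[order(hits$query, -ov, spans$gene_id[hits$subject]), ]
    first <- !duplicated(hits$query)
    cl$gene_id[hits$query[first]] <- spans$gene_id[hits$subject[first]]
  }

  # per-gene tag totals (all tags in the gene span, per replicate)
  tag_hits <- overlap_pairs(tags, spans)
  gene_rep <- matrix(0L, nrow(spans), length(replicates),
                     dimnames = list(spans$gene_id, replicates))
  if (nrow(tag_hits)) {
    tt <- table(factor(spans$gene_id[tag_hits$subject], levels = spans$gene_id),
                factor(tags$replicate[tag_hits$query], levels = replicates))
    gene_rep[] <- as.integer(tt)
  }
  gene_len <- stats::setNames(spans$length, spans$gene_id)
  mean_tag_len <- if (nrow(tags)) mean(tags$end - tags$start) else 0

  cl$peak_height <- NA_integer_
  cl$peak_pos <- NA_integer_
  cl$peak_p <- NA_real_
  cl$repro_chi2 <- NA_real_
  cl$repro_p <- NA_real_
  memb <- split(seq_len(nrow(tags)), tags$cluster_id)
  for (j in seq_len(nrow(cl))) {
    i <- memb[[cl$cluster_id[j]]]
    pk <- peak_height(tags$start[i], tags$end[i])
    cl$peak_height[j] <- pk$height
    cl$peak_pos[j] <- pk$position
    g <- cl$gene_id[j]
    if (!is.na(g)) {
      cl$peak_p[j] <- peak_significance(pk$height, sum(gene_rep[g, ]),
                                        gene_len[[g]], mean_tag_len)
      if (length(replicates) >= 2) {
        counts <- vapply(replicates, function(r) cl[[paste0("n_", r)]][j],
                         integer(1))
        rs <- reproducibility_score(counts, gene_rep[g, ])
        cl$repro_chi2[j] <- rs$chi2
        cl$repro_p[j] <- rs$p
      }
    }
  }
  cl
}

#' Apply the nested stringency tiers
#'
#' Four nested binding-site tiers: T1 = BC >= `min_bc` and total tags >= 2;
#' T2 = BC filter and total tags >= 10; T3 = T2 and peak height >= 10 and
#' peak p <= `peak_alpha`; T4 = T3 and reproducibility retained (BC equal to
#' the replicate count and repro p > `repro_alpha`). Tier sizes are monotone
#' non-increasing by construction.
#'
#' @param clusters annotated cluster table ([annotate_clusters()]).
#' @param n_replicates number of CLIP replicates.
#' @param min_bc biological-complexity threshold (default 2).
#' @param min_tags_t2 tag threshold of the second tier (default 10).
#' @param min_peak peak-height threshold (default 10).
#' @param peak_alpha significance level for the peak p-value (default 0.01).
#' @param repro_alpha level below which a cluster is flagged replicate-skewed
#'   (default 0.01).
#' @return `clusters` with logical columns `tier1`..`tier4`.
#' @export
apply_stringency_tiers <- function(clusters, n_replicates, min_bc = 2L,
                                   min_tags_t2 = 10L, min_peak = 10L,
                                   peak_alpha = 0.01, repro_alpha = 0.01) {
  bc_ok <- clusters$bc >= min_bc
  clusters$tier1 <- bc_ok & clusters$total_tags >= 2L
  clusters$tier2 <- bc_ok & clusters$total_tags >= min_tags_t2
  clusters$tier3 <- clusters$tier2 & clusters$peak_height >= min_peak &
    !is.na(clusters$peak_p) & clusters$peak_p <= peak_alpha
  retained <- clusters$bc == n_replicates & !is.na(clusters$repro_p) &
    clusters$repro_p > repro_alpha
  clusters$tier4 <- clusters$tier3 & retained
  clusters
}

#' Region distribution of clusters per stringency tier
#'
#' @param clusters tiered cluster table.
#' @param ann a `transcript_annotation`.
#' @param regions optional precomputed `derive_regions(ann)`.
#' @return list with `proportions` (data.frame: tier, label, n, proportion;
#'   proportions sum to 1 within each non-empty tier) and `tag_counts`
#'   (data.frame: tier, label, total_tags per cluster) for per-region
#'   tags-per-cluster histograms.
#' @export
region_distribution <- function(clusters, ann, regions = NULL) {
  if (is.null(regions)) regions <- derive_regions(ann)
  clusters$region <- assign_region(clusters, ann, regions)
  tiers <- grep("^tier", names(clusters), value = TRUE)
  labs <- names(REGION_PRIORITY)
  props <- list()
  counts <- list()
  for (t in tiers) {
    sub <- clusters[clusters[[t]], , drop = FALSE]
    if (nrow(sub) == 0) next
    tab <- table(factor(sub$region, levels = labs))
    props[[t]] <- data.frame(tier = t, label = labs, n = as.integer(tab),
                             proportion = as.numeric(tab) / nrow(sub),
                             stringsAsFactors = FALSE)
    counts[[t]] <- data.frame(tier = t, label = sub$region,
                              total_tags = sub$total_tags,
                              stringsAsFactors = FALSE)
  }
  list(proportions = if (length(props)) do.call(rbind, props) else
         data.frame(tier = character(), label = character(), n = integer(),
                    proportion = numeric()),
       tag_counts = if (length(counts)) do.call(rbind, counts) else
         data.frame(tier = character(), label = character(),
                    total_tags = integer()))
}

#' Per-gene tag totals over filtered clusters
#'
#' Sums cluster tag counts per gene over clusters passing a BC / tag-count
#' filter (default: BC >= 2 and total tags >= 10, the strong-binder
#' definition); genes are then classifiable by the > `strong_cutoff` rule.
#'
#' @param clusters annotated cluster table.
#' @param min_bc,min_tags cluster filter (defaults 2 and 10).
#' @param strong_cutoff per-gene tag total above which a gene counts as a
#'   strong binding partner (default 100).
#' @return data.frame: `gene_id`, `tag_total`, `strong_binder` (logical).
#'   Genes with no passing cluster are absent (tag total 0 by convention).
#' @export
tags_per_transcript <- function(clusters, min_bc = 2L, min_tags = 10L,
                                strong_cutoff = 100L) {
  keep <- clusters$bc >= min_bc & clusters$total_tags >= min_tags &
    !is.na(clusters$gene_id)
  sub <- clusters[keep, , drop = FALSE]
  if (nrow(sub) == 0)
    return(data.frame(gene_id = character(), tag_total = integer(),
                      strong_binder = logical()))
  agg <- stats::aggregate(list(tag_total = sub$total_tags),
                          by = list(gene_id = sub$gene_id), FUN = sum)
  agg$strong_binder <- agg$tag_total > strong_cutoff
  agg[order(agg$gene_id), , drop = FALSE]
}
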