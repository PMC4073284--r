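# Dose-response direct-target screen: two wild-type inducible clones and one
# loss-of-function mutant clone, each assayed across an inducer dose series.
# A direct target must respond in both wild-type clones already at the lowest
# dose and not respond in the mutant.

#' Median-of-ratios size-factor normalization
#'
#' Per-sample size factor = median over genes with all-positive counts of the
#' ratio of the gene's count to its geometric mean across samples. Factors are
#' rescaled so their median is 1 (a data-driven, reproducible reference
#' scale); the normalized matrix is counts divided by factors.
#'
#' @param counts non-negative numeric matrix, genes x samples.
#' @return list: `normalized` (matrix), `size_factors` (named vector).
#' @export
size_factor_normalize <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene with positive counts in all samples; ",
         "consider a pseudo-reference fallback")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2, function(col) stats::median(col / geo))
  sf <- sf / stats::median(sf)
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Per-gene dose correlation within each clone
#'
#' Pearson correlation of normalized expression against inducer dose across a
#' clone's samples, with the two-sided p-value from the t-distribution
#' transform. Constant-expression genes get r = NA, p = 1 by convention.
#'
#' @param expr normalized expression matrix, genes x samples.
#' @param design data.frame: `sample`, `clone`, `dose` (sample names must
#'   match `colnames(expr)`). Each clone needs >= 3 samples over >= 3
#'   distinct doses including 0.
#' @param dose_transform optional function applied to dose before correlating
#'   (e.g. `function(d) log1p(d)`); default identity (the dose axis itself).
#' @return data.frame: `gene_id`, `clone`, `r`, `p`.
#' @export
dose_correlation <- function(expr, design, dose_transform = identity) {
  if (!all(design$sample %in% colnames(expr)))
    stop("design samples missing from expression matrix")
  out <- list()
  for (cl in unique(design$clone)) {
    d <- design[design$clone == cl, , drop = FALSE]
    if (nrow(d) < 3) stop("clone ", cl, " has < 3 samples")
    if (length(unique(d$dose)) < 3) stop("clone ", cl, " has < 3 dose levels")
    x <- dose_transform(d$dose)
    sub <- expr[, d$sample, drop = FALSE]
    n <- length(x)
    sdy <- apply(sub, 1, stats::sd)
    r <- rep(NA_real_, nrow(sub))
    ok <- sdy > 0
    if (any(ok)) r[ok] <- as.numeric(stats::cor(t(sub[ok, , drop = FALSE]), x))
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[!ok] <- 1
    out[[cl]] <- data.frame(gene_id = rownames(sub), clone = cl, r = r, p = p,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log2 fold change at the lowest nonzero dose
#'
#' Per gene and clone: log2 of mean normalized expression at the lowest
#' nonzero dose over mean expression at dose 0 (pseudocount 0.5 on both means
#' guards against zeros).
#'
#' @param expr normalized expression matrix.
#' @param design as in [dose_correlation()].
#' @param pseudocount added to both means (default 0.5).
#' @return data.frame: `gene_id`, `clone`, `lfc_lowest`.
#' @export
lowest_dose_log2fc <- function(expr, design, pseudocount = 0.5) {
  out <- list()
  for (cl in unique(design$clone)) {
    d <- design[design$clone == cl, , drop = FALSE]
    doses <- sort(unique(d$dose))
    if (doses[1] != 0) stop("clone ", cl, " lacks a dose-0 baseline")
    low <- doses[doses > 0][1]
    m0 <- rowMeans(expr[, d$sample[d$dose == 0], drop = FALSE])
    m1 <- rowMeans(expr[, d$sample[d$dose == low], drop = FALSE])
    out[[cl]] <- data.frame(gene_id = rownames(expr), clone = cl,
                            lfc_lowest = log2((m1 + pseudocount) /
                                                (m0 + pseudocount)),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Three-criterion direct-target screen
#'
#' A gene is UP when (i) the dose correlation has p < `p_wt` with r > 0 in
#' both wild-type clones, (ii) its expression change is detectable already at
#' the lowest nonzero dose in both wild-type clones (|log2 fold change| >=
#' `min_lfc` with consistent positive sign), and (iii) it shows no
#' significant correlation in the mutant clone (p > `p_mut`). DOWN is
#' symmetric with negative r and fold change. The raw p cutoffs are used as
#' stated; `adjust = "BH"` optionally applies Benjamini-Hochberg within each
#' clone first.
#'
#' @param cor_results output of [dose_correlation()] covering both wild-type
#'   clones and the mutant clone.
#' @param lfc_results output of [lowest_dose_log2fc()].
#' @param wt_clones character(2): the wild-type clone ids.
#' @param mut_clone the mutant clone id.
#' @param p_wt,p_mut,min_lfc thresholds (defaults 0.01, 0.05 and 0.585,
#'   i.e. 1.5-fold).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `gene_id`, `classification` in `{UP, DOWN, none}` plus
#'   the per-clone r/p/lfc columns used.
#' @export
screen_targets <- function(cor_results, lfc_results, wt_clones, mut_clone,
                           p_wt = 0.01, p_mut = 0.05, min_lfc = 0.585,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  clones <- c(wt_clones, mut_clone)
  if (!all(clones %in% cor_results$clone))
    stop("missing clone in correlation results: ",
         paste(setdiff(clones, cor_results$clone), collapse = ", "))
  if (adjust == "BH")
    cor_results$p <- stats::ave(cor_results$p, cor_results$clone,
                                FUN = function(p) stats::p.adjust(p, "BH"))
  genes <- unique(cor_results$gene_id)
  wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cl in clones) {
    sub <- cor_results[cor_results$clone == cl, ]
    wide[[paste0("r_", cl)]] <- sub$r[match(genes, sub$gene_id)]
    wide[[paste0("p_", cl)]] <- sub$p[match(genes, sub$gene_id)]
  }
  for (cl in wt_clones) {
    sub <- lfc_results[lfc_results$clone == cl, ]
    wide[[paste0("lfc_", cl)]] <- sub$lfc_lowest[match(genes, sub$gene_id)]
  }
  w1 <- wt_clones[1]; w2 <- wt_clones[2]
  sig_wt <- function(sign) {
    ok <- wide[[paste0("p_", w1)]] < p_wt & wide[[paste0("p_", w2)]] < p_wt &
      sign * wide[[paste0("r_", w1)]] > 0 & sign * wide[[paste0("r_", w2)]] > 0 &
      sign * wide[[paste0("lfc_", w1)]] >= min_lfc &
      sign * wide[[paste0("lfc_", w2)]] >= min_lfc &
      wide[[paste0("p_", mut_clone)]] > p_mut
    ok & !is.na(ok)
  }
  up <- sig_wt(+1)
  down <- sig_wt(-1)
  wide$classification <- ifelse(up, "UP", ifelse(down, "DOWN", "none"))
  wide
}

#' Binding-strength integration of screen results
#'
#' For each target set, the count and fraction of genes whose per-gene CLIP
#' tag total exceeds `strong_cutoff`, plus a two-sided Fisher exact test for a
#' binding preference between the UP and DOWN sets.
#'
#' @param screen output of [screen_targets()].
#' @param tag_totals data.frame from [tags_per_transcript()] (`gene_id`,
#'   `tag_total`). Genes absent from it count as 0 tags.
#' @param strong_cutoff tag threshold (default 100).
#' @return list: `summary` (data.frame per set: n, n_bound, fraction_bound),
#'   `fisher_p`.
#' @export
integrate_binding <- function(screen, tag_totals, strong_cutoff = 100L) {
  tt <- tag_totals$tag_total[match(screen$gene_id, tag_totals$gene_id)]
  tt[is.na(tt)] <- 0L
  bound <- tt > strong_cutoff
  sets <- c("UP", "DOWN")
  summary <- do.call(rbind, lapply(sets, function(s) {
    i <- screen$classification == s
    data.frame(set = s, n = sum(i), n_bound = sum(bound & i),
               fraction_bound = if (sum(i)) mean(bound[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tbl <- rbind(c(summary$n_bound[1], summary$n[1] - summary$n_bound[1]),
               c(summary$n_bound[2], summary$n[2] - summary$n_bound[2]))
  p <- if (any(rowSums(tbl) == 0)) 1 else stats::fisher.test(tbl)$p.value
  list(summary = summary, fisher_p = p)
}

#' Gene-set signature score
#'
#' Per-sample sum of z-scores over a gene set (e.g. a curated pathway
#' signature); genes missing from the matrix are dropped with a warning.
#'
#' @param zmat z-score matrix, genes x samples.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(zmat, gene_set) {
  present <- intersect(gene_set, rownames(zmat))
  if (length(present) == 0) stop("no gene of the set present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present), " gene(s) of the set missing")
  colSums(zmat[present, , drop = FALSE])
}
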