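# Crosslink-induced mutation sites (CIMS): reverse transcription through the
# crosslinked residue leaves deletions in CLIP tags; positions where deletions
# recur beyond what random placement explains pinpoint the contact nucleotide.
# Only deletions are modeled here.

#' Collect candidate deletion sites
#'
#' For every genomic position carrying at least one deletion: `k` = number of
#' tags with a deletion there, `m` = number of tags covering the position.
#'
#' @param tags tag table with list-column `deletions` (0-based offsets from
#'   the tag's genomic start).
#' @return data.frame: `chrom`, `pos` (0-based), `strand`, `k`, `m`, sorted by
#'   (chrom, pos, strand). Positions with no deletion are omitted.
#' @export
collect_deletion_sites <- function(tags) {
  empty <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      k = integer(), m = integer())
  if (nrow(tags) == 0) return(empty)
  len <- tags$end - tags$start
  ndel <- lengths(tags$deletions)
  if (sum(ndel) == 0) return(empty)
  tag_i <- rep(seq_len(nrow(tags)), ndel)
  off <- unlist(tags$deletions)
  if (any(off < 0) || any(off >= len[tag_i]))
    stop("deletion offset outside tag span")
  # k counts tags, not deletion events: one vote per (tag, position)
  keep <- !duplicated(paste(tag_i, off, sep = "\r"))
  tag_i <- tag_i[keep]
  off <- off[keep]
  del <- data.frame(chrom = tags$chrom[tag_i], pos = tags$start[tag_i] + off,
                    strand = tags$strand[tag_i], stringsAsFactors = FALSE)
  key <- paste(del$chrom, del$pos, del$strand, sep = "\r")
  tab <- table(key)
  uniq <- !duplicated(key)
  sites <- del[uniq, , drop = FALSE]
  sites$k <- as.integer(tab[key[uniq]])
  # coverage m per site from the tag pileup
  sites$m <- 0L
  hits <- overlap_pairs(
    data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
               strand = sites$strand, stringsAsFactors = FALSE), tags)
  if (nrow(hits)) {
    cnt <- table(factor(hits$query, levels = seq_len(nrow(sites))))
    sites$m <- as.integer(cnt)
  }
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# count, per (stratum, k >= threshold), of sites: returns matrix strata x k
.site_exceedance <- function(sites, strata_levels, k_max) {
  out <- matrix(0, length(strata_levels), k_max,
                dimnames = list(strata_levels, NULL))
  if (nrow(sites) == 0) return(out)
  s <- as.character(pmin(sites$m, attr(strata_levels, "pool")))
  for (k in seq_len(k_max))
    out[, k] <- as.integer(table(factor(s[sites$k >= k],
                                        levels = strata_levels)))
  out
}

#' Permutation FDR for deletion sites
#'
#' In each permutation round every deletion is repositioned uniformly at
#' random within its own tag (per-tag deletion counts, and therefore the
#' total, are conserved). Within each coverage stratum (exact `m`, pooling
#' `m > pool_m` into one stratum) the FDR at deletion count `k` is the mean
#' permuted number of positions with coverage in the stratum and deletion
#' count >= k, divided by the observed number, clamped to \[0, 1\] and
#' monotonized so that fdr is non-increasing in `k`.
#'
#' @param tags tag table with list-column `deletions`.
#' @param n_permutations number of permutation rounds (>= 20; default 100).
#' @param seed mandatory RNG seed for reproducibility.
#' @param min_k,max_fdr thresholds defining the reproducible set (defaults
#'   k >= 5 and fdr <= 0.01).
#' @param pool_m coverage above which strata are pooled (default 100).
#' @return the candidate site table with an `fdr` column and a logical
#'   `reproducible` column (`k >= min_k & fdr <= max_fdr`).
#' @export
cims_fdr <- function(tags, n_permutations = 100L, seed, min_k = 5L,
                     max_fdr = 0.01, pool_m = 100L) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_permutations < 20) stop("n_permutations must be >= 20")
  observed <- collect_deletion_sites(tags)
  if (nrow(observed) == 0) {
    observed$fdr <- numeric()
    observed$reproducible <- logical()
    return(observed)
  }
  strata_levels <- as.character(sort(unique(pmin(observed$m, pool_m))))
  attr(strata_levels, "pool") <- pool_m
  k_max <- max(observed$k)
  obs_counts <- .site_exceedance(observed, strata_levels, k_max)

  len <- tags$end - tags$start
  ndel <- lengths(tags$deletions)
  perm_tags <- tags
  old_seed <- .preserve_seed()
  on.exit(.restore_seed(old_seed))
  set.seed(seed)
  perm_sum <- matrix(0, length(strata_levels), k_max,
                     dimnames = dimnames(obs_counts))
  for (b in seq_len(n_permutations)) {
    tag_i <- rep(seq_len(nrow(tags)), ndel)
    off <- floor(stats::runif(length(tag_i)) * len[tag_i])
    perm_tags$deletions <- unname(split(as.integer(off),
                                        factor(tag_i, levels = seq_len(nrow(tags)))))
    psites <- collect_deletion_sites(perm_tags)
    perm_sum <- perm_sum + .site_exceedance(psites, strata_levels, k_max)
  }
  fdr_tab <- perm_sum / n_permutations / pmax(obs_counts, 1)
  fdr_tab[obs_counts == 0] <- NA
  fdr_tab <- pmin(fdr_tab, 1)
  # conservative monotonization: fdr non-increasing in k within a stratum
  for (s in seq_len(nrow(fdr_tab))) {
    v <- fdr_tab[s, ]
    ok <- !is.na(v)
    if (any(ok)) v[ok] <- rev(cummax(rev(v[ok])))
    fdr_tab[s, ] <- v
  }
  srow <- match(as.character(pmin(observed$m, pool_m)), strata_levels)
  observed$fdr <- fdr_tab[cbind(srow, observed$k)]
  observed$reproducible <- observed$k >= min_k & observed$fdr <= max_fdr
  observed
}

.preserve_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract footprint sequence windows around CIMS
#'
#' Windows of length `2 * halfwidth + 1` centered on each site, in transcript
#' orientation (minus-strand windows are reverse-complemented). Windows
#' extending past a sequence end are clipped and flagged.
#'
#' @param sites site table (`chrom`, `pos`, `strand`).
#' @param seqs named `DNAStringSet` (or named character vector) of reference
#'   sequences keyed by `chrom`.
#' @param halfwidth window half-width in nt (default 10).
#' @return data.frame: `chrom`, `pos`, `strand`, `seq`, `clipped`.
#' @export
extract_footprints <- function(sites, seqs, halfwidth = 10L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  out <- sites[, c("chrom", "pos", "strand"), drop = FALSE]
  out$seq <- NA_character_
  out$clipped <- FALSE
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    if (!chrom %in% names(seqs)) stop("no sequence for ", chrom)
    slen <- Biostrings::width(seqs[chrom])
    lo <- sites$pos[i] - halfwidth
    hi <- sites$pos[i] + halfwidth + 1L
    clipped <- lo < 0 || hi > slen
    lo <- max(lo, 0L)
    hi <- min(hi, slen)
    w <- Biostrings::subseq(seqs[[chrom]], start = lo + 1L, end = hi)
    if (sites$strand[i] == "-") w <- Biostrings::reverseComplement(w)
    out$seq[i] <- as.character(w)
    out$clipped[i] <- clipped
  }
  rownames(out) <- NULL
  out
}

#' Base-composition enrichment of footprint windows
#'
#' Compares the per-window fraction of a base (default U, i.e. T in DNA
#' space) between foreground and background windows with a one-sided
#' Mann-Whitney test (foreground greater), and counts windows containing a
#' run of >= `min_run` of that base.
#'
#' @param fg,bg character vectors of window sequences (>= 1 each; background
#'   should be drawn from matched transcript regions).
#' @param base the base of interest (`"U"` is treated as `"T"`).
#' @param min_run run length for the run-count statistic (default 4).
#' @return list: `fraction_fg`, `fraction_bg` (mean per-window fractions),
#'   `p` (one-sided Mann-Whitney), `run_count_fg`, `run_count_bg`.
#' @export
base_composition_enrichment <- function(fg, bg, base = "U", min_run = 4L) {
  if (length(fg) == 0 || length(bg) == 0) stop("empty window group")
  base <- toupper(base)
  if (base == "U") base <- "T"
  frac <- function(x) {
    ss <- Biostrings::DNAStringSet(x)
    as.numeric(Biostrings::letterFrequency(ss, base)) / Biostrings::width(ss)
  }
  ffg <- frac(fg)
  fbg <- frac(bg)
  run <- strrep(base, min_run)
  list(fraction_fg = mean(ffg), fraction_bg = mean(fbg),
       p = stats::wilcox.test(ffg, fbg, alternative = "greater",
                              exact = FALSE)$p.value,
       run_count_fg = sum(grepl(run, fg, fixed = TRUE)),
       run_count_bg = sum(grepl(run, bg, fixed = TRUE)))
}
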