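# Synthetic-data generators: every input the pipeline consumes can be built
# with known ground truth, so each stage is testable without external data.
# All generators take a mandatory seed and restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  old <- .preserve_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a deterministic toy genome
#'
#' Genes are laid head to tail on one chromosome with intergenic gaps; every
#' transcript has >= 3 exons (so cassette events are representable), a CDS
#' from mid first exon to mid last exon (hence 5'UTR and 3'UTR on both
#' flanks) and >= 1 intron. Identical seeds give identical output.
#'
#' @param n_genes number of genes (default 30).
#' @param seed RNG seed (mandatory).
#' @param n_exons_range,exon_len_range,intron_len_range,gap_range integer
#'   ranges sampled uniformly per gene/feature.
#' @param chrom chromosome name (default `"chrS"`).
#' @return list of class `sim_genome`: `ann` (a `transcript_annotation`),
#'   `seq` (`DNAStringSet`), `chrom`.
#' @export
make_genome <- function(n_genes = 30L, seed,
                        n_exons_range = c(3L, 5L),
                        exon_len_range = c(80L, 300L),
                        intron_len_range = c(200L, 1500L),
                        gap_range = c(500L, 2000L), chrom = "chrS") {
  if (missing(seed)) stop("seed is mandatory")
  if (n_exons_range[1] < 2) stop("transcripts need >= 2 exons")
  .with_seed(seed, {
    pos <- sample(gap_range[1]:gap_range[2], 1)
    tx_rows <- list(); ex_rows <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      tid <- sprintf("tx%03d", g)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(n_exons_range[1]:n_exons_range[2], 1)
      elen <- sample(exon_len_range[1]:exon_len_range[2], n_ex, replace = TRUE)
      ilen <- sample(intron_len_range[1]:intron_len_range[2],
                     max(n_ex - 1, 1), replace = TRUE)
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- pos
      for (j in seq_len(n_ex)) {
        starts[j] <- p; ends[j] <- p + elen[j]
        p <- ends[j] + if (j < n_ex) ilen[j] else 0L
      }
      cds_start <- starts[1] + floor(elen[1] / 2)
      cds_end <- starts[n_ex] + floor(elen[n_ex] / 2)
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      tx_rows[[g]] <- data.frame(transcript_id = tid, gene_id = gid,
                                 chrom = chrom, strand = strand,
                                 tx_start = starts[1], tx_end = ends[n_ex],
                                 cds_start = cds_start, cds_end = cds_end,
                                 n_exons = n_ex, stringsAsFactors = FALSE)
      ex_rows[[g]] <- data.frame(transcript_id = tid, gene_id = gid,
                                 chrom = chrom, strand = strand,
                                 start = starts, end = ends, exon_rank = rank,
                                 stringsAsFactors = FALSE)
      pos <- ends[n_ex] + sample(gap_range[1]:gap_range[2], 1)
    }
    transcripts <- do.call(rbind, tx_rows)
    exons <- do.call(rbind, ex_rows)
    ann <- list(transcripts = transcripts, exons = exons)
    class(ann) <- "transcript_annotation"
    total_len <- max(transcripts$tx_end) + 500L
    seqs <- Biostrings::DNAStringSet(.random_dna(total_len))
    names(seqs) <- chrom
    structure(list(ann = ann, seq = seqs, chrom = chrom), class = "sim_genome")
  })
}

#' Simulate aligned CLIP reads with planted binding sites
#'
#' Plants one binding site per selected gene in a chosen region class, then
#' draws site tags (Poisson per replicate, each covering the site center,
#' with a crosslink deletion at the center with probability `deletion_prob`)
#' and uniform background tags per gene. Each unique tag is expanded into a
#' geometric number of PCR duplicates sharing start and degenerate barcode.
#' A T-run is written into the genome sequence at each site center so
#' footprint composition tests have signal to find.
#'
#' @param genome a [make_genome()] result.
#' @param seed RNG seed (mandatory).
#' @param n_replicates CLIP replicates (default 2).
#' @param sites_per_gene planted sites per selected gene (default 1).
#' @param site_region region labels eligible to host sites
#'   (default `c("3'UTR", "intron")`).
#' @param site_rate site tags per replicate: either a single Poisson mean or
#'   a length-2 range from which per-site means are drawn log-uniformly
#'   (default 5-80, emulating the orders-of-magnitude spread of binding
#'   strength across transcripts).
#' @param background_rate mean background tags per gene per replicate
#'   (default 5).
#' @param intergenic_fraction expected fraction of tags falling outside gene
#'   spans (default 0.25, so about three quarters of tags are genic).
#' @param tag_len_range tag length range in nt (default 30-50).
#' @param deletion_prob probability a site tag carries a deletion at the site
#'   center (default 0.3).
#' @param background_deletion_prob probability a background tag carries one
#'   deletion placed uniformly within the tag (default 0; raise it for null
#'   CIMS calibrations).
#' @param dup_mean mean PCR copies per unique tag (geometric; default 3).
#' @param polyu_len length of the T-run planted at site centers (default 9;
#'   0 disables sequence editing).
#' @return list: `reads` (aligned duplicated reads: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `replicate`, `barcode`, list-column
#'   `deletions`), `truth` (list: `sites` data.frame, `unique_tags` the
#'   pre-duplication tag table, `n_unique` per replicate), `seq` (the genome
#'   sequence with planted T-runs).
#' @export
simulate_clip <- function(genome, seed, n_replicates = 2L, sites_per_gene = 1L,
                          site_region = c("3'UTR", "intron"),
                          site_rate = c(5, 80), background_rate = 5,
                          intergenic_fraction = 0.25,
                          tag_len_range = c(30L, 50L),
                          deletion_prob = 0.3, background_deletion_prob = 0,
                          dup_mean = 3, polyu_len = 9L) {
  if (missing(seed)) stop("seed is mandatory")
  ann <- genome$ann
  regions <- derive_regions(ann)
  spans <- gene_spans(ann)
  reps <- paste0("rep", seq_len(n_replicates))
  .with_seed(seed, {
    # choose site positions
    cand <- regions[regions$label %in% site_region &
                      (regions$end - regions$start) >= 60, , drop = FALSE]
    sites <- list()
    for (g in unique(cand$gene_id)) {
      rg <- cand[cand$gene_id == g, , drop = FALSE]
      for (s in seq_len(min(sites_per_gene, nrow(rg)))) {
        r <- rg[sample(nrow(rg), 1), , drop = FALSE]
        center <- r$start + sample(25:(r$end - r$start - 25), 1)
        sites[[length(sites) + 1L]] <- data.frame(
          site_id = sprintf("site%03d", length(sites) + 1L), gene_id = g,
          chrom = r$chrom, center = center, strand = r$strand,
          region = r$label, stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, sites)
    sites$rate <- if (length(site_rate) == 2)
      exp(stats::runif(nrow(sites), log(site_rate[1]), log(site_rate[2])))
    else rep(site_rate, nrow(sites))

    # intergenic gaps available for non-genic background
    gaps_lo <- c(0L, spans$end)
    gaps_hi <- c(spans$start, max(spans$end) + 400L)
    keep_gap <- gaps_hi - gaps_lo > 100L
    gaps_lo <- gaps_lo[keep_gap]; gaps_hi <- gaps_hi[keep_gap]

    tag_rows <- list()
    new_tag <- function(chrom, start, len, strand, rep_id, dels) {
      data.frame(chrom = chrom, start = start, end = start + len,
                 strand = strand, replicate = rep_id,
                 barcode = .random_dna(6), stringsAsFactors = FALSE) -> d
      d$deletions <- list(as.integer(dels))
      d
    }
    for (rep_id in reps) {
      for (i in seq_len(nrow(sites))) {
        n <- stats::rpois(1, sites$rate[i])
        if (n == 0) next
        for (k in seq_len(n)) {
          len <- sample(tag_len_range[1]:tag_len_range[2], 1)
          d <- sample(5:(len - 5), 1)   # tag covers the center
          start <- sites$center[i] - d
          dels <- if (stats::runif(1) < deletion_prob) d else integer()
          tag_rows[[length(tag_rows) + 1L]] <-
            new_tag(sites$chrom[i], start, len, sites$strand[i], rep_id, dels)
        }
      }
      for (gi in seq_len(nrow(spans))) {
        n <- stats::rpois(1, background_rate)
        if (n == 0) next
        for (k in seq_len(n)) {
          len <- sample(tag_len_range[1]:tag_len_range[2], 1)
          start <- spans$start[gi] +
            sample(0:max(spans$length[gi] - len, 1), 1)
          dels <- if (stats::runif(1) < background_deletion_prob)
            sample(0:(len - 1), 1) else integer()
          tag_rows[[length(tag_rows) + 1L]] <-
            new_tag(spans$chrom[gi], start, len, spans$strand[gi], rep_id, dels)
        }
      }
      # intergenic background at the configured overall fraction
      n_genic <- sum(vapply(tag_rows, function(x)
        x$replicate == rep_id, logical(1)))
      n_inter <- stats::rpois(1, intergenic_fraction /
                                   max(1 - intergenic_fraction, 1e-6) * n_genic)
      for (k in seq_len(n_inter)) {
        len <- sample(tag_len_range[1]:tag_len_range[2], 1)
        gp <- sample(length(gaps_lo), 1, prob = gaps_hi - gaps_lo)
        start <- gaps_lo[gp] + sample(0:max(gaps_hi[gp] - gaps_lo[gp] - len, 1), 1)
        tag_rows[[length(tag_rows) + 1L]] <-
          new_tag(spans$chrom[1], start, len, sample(c("+", "-"), 1), rep_id,
                  integer())
      }
    }
    unique_tags <- do.call(rbind, tag_rows)
    unique_tags$read_id <- sprintf("u%06d", seq_len(nrow(unique_tags)))

    # PCR duplication: geometric number of copies per unique tag
    copies <- 1L + stats::rgeom(nrow(unique_tags), prob = 1 / dup_mean)
    idx <- rep(seq_len(nrow(unique_tags)), copies)
    reads <- unique_tags[idx, , drop = FALSE]
    reads$read_id <- sprintf("read%06d", seq_along(idx))
    reads <- reads[sample(nrow(reads)), , drop = FALSE]  # shuffle input order
    rownames(reads) <- NULL

    seqs <- genome$seq
    if (polyu_len > 0) {
      for (i in seq_len(nrow(sites))) {
        lo <- sites$center[i] - floor(polyu_len / 2)
        # a U-run in transcript orientation is an A-run on the genome for
        # minus-strand sites
        base <- if (sites$strand[i] == "+") "T" else "A"
        Biostrings::subseq(seqs[[sites$chrom[i]]], start = lo + 1L,
                           width = polyu_len) <-
          Biostrings::DNAString(strrep(base, polyu_len))
      }
    }
    n_unique <- table(factor(unique_tags$replicate, levels = reps))
    list(reads = reads,
         truth = list(sites = sites, unique_tags = unique_tags,
                      n_unique = as.integer(n_unique), replicates = reps),
         seq = seqs)
  })
}

#' Simulate raw barcoded FASTQ-like CLIP reads
#'
#' Builds reads as `[index][degenerate barcode][insert][polyA tail]` per the
#' layout, for testing demultiplexing and trimming against generator truth.
#'
#' @param layout a [clip_layout()].
#' @param n_per_replicate named integer vector (names = replicate ids present
#'   in the layout).
#' @param seed RNG seed.
#' @param insert_len_range insert lengths (default 25-45).
#' @param polya_len tail length (default 10).
#' @param n_undetermined reads given a random unknown index (default 0).
#' @return list: `reads` (named character vector), `truth` (data.frame:
#'   `read_id`, `replicate`, `barcode`, `insert`).
#' @export
simulate_clip_fastq <- function(layout, n_per_replicate, seed,
                                insert_len_range = c(25L, 45L),
                                polya_len = 10L, n_undetermined = 0L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(names(n_per_replicate) %in% names(layout$indices)))
  .with_seed(seed, {
    # the last 4 insert bases avoid A so the insert boundary can never blend
    # into the (imperfect-run tolerant) polyA trim
    non_a_tail <- function(s) {
      n <- nchar(s)
      paste0(substr(s, 1, n - 4),
             paste(sample(c("C", "G", "T"), 4, TRUE), collapse = ""))
    }
    rows <- list()
    for (rep_id in names(n_per_replicate)) {
      for (k in seq_len(n_per_replicate[[rep_id]])) {
        ins_len <- sample(insert_len_range[1]:insert_len_range[2], 1)
        insert <- non_a_tail(.random_dna(ins_len))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_id, index = unname(layout$indices[[rep_id]]),
          barcode = .random_dna(layout$barcode_len), insert = insert,
          stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(n_undetermined)) {
      repeat {
        ix <- .random_dna(layout$index_len)
        if (!ix %in% layout$indices) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = "undetermined", index = ix,
        barcode = .random_dna(layout$barcode_len),
        insert = non_a_tail(.random_dna(30)), stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[sample(nrow(truth)), , drop = FALSE]
    truth$read_id <- sprintf("raw%05d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
    head2 <- if (layout$order[1] == "index")
      paste0(truth$index, truth$barcode) else paste0(truth$barcode, truth$index)
    reads <- paste0(head2, truth$insert, strrep("A", polya_len))
    names(reads) <- truth$read_id
    list(reads = reads,
         truth = truth[, c("read_id", "replicate", "barcode", "insert")])
  })
}

#' Simulate cassette-exon junction reads at set inclusion rates
#'
#' Events are laid out on a dedicated chromosome; per event, condition and
#' replicate, `inc_up` and `inc_down` are independent Binomial(depth, IR)
#' draws and `skip` is Binomial(depth, 1 - IR).
#'
#' @param n_events number of cassette events.
#' @param delta_i planted inclusion change per event (recycled; treatment IR
#'   = control IR + delta_i, clamped to \[0, 1\]).
#' @param seed RNG seed.
#' @param ir_control control-condition IR per event (recycled; default 0.5).
#' @param depth junction-read depth parameter per replicate (default 200).
#' @param n_reps replicates per condition (default 3, the usual triplicate
#'   design).
#' @param chrom chromosome name for the synthetic events.
#' @return list: `events` ([cassette_events()]), `junctions` (data.frame:
#'   `sample`, `chrom`, `strand`, `jl`, `jr`, `count`), `design` (`sample`,
#'   `condition`), `truth` (per-event IRs and delta).
#' @export
simulate_junction_reads <- function(n_events, delta_i, seed, ir_control = 0.5,
                                    depth = 200L, n_reps = 3L,
                                    chrom = "chrE") {
  if (missing(seed)) stop("seed is mandatory")
  delta_i <- rep_len(delta_i, n_events)
  ir_control <- rep_len(ir_control, n_events)
  ir_treatment <- pmin(pmax(ir_control + delta_i, 0), 1)
  base <- 2000L * (seq_len(n_events) - 1L)
  events <- cassette_events(
    event_id = sprintf("ev%04d", seq_len(n_events)),
    gene_id = sprintf("evgene%04d", seq_len(n_events)),
    chrom = chrom, strand = rep(c("+", "-"), length.out = n_events),
    e1_start = base, e1_end = base + 150L,
    e2_start = base + 550L, e2_end = base + 670L,
    e3_start = base + 1070L, e3_end = base + 1220L)
  design <- data.frame(
    sample = c(paste0("ctrl_", seq_len(n_reps)), paste0("trt_", seq_len(n_reps))),
    condition = rep(c("control", "treatment"), each = n_reps),
    stringsAsFactors = FALSE)
  ej <- .event_junctions(events)
  .with_seed(seed, {
    rows <- list()
    for (s in seq_len(nrow(design))) {
      ir <- if (design$condition[s] == "treatment") ir_treatment else ir_control
      for (type in c("inc_up", "inc_down", "skip")) {
        p <- if (type == "skip") 1 - ir else ir
        cnt <- stats::rbinom(n_events, depth, p)
        j <- ej[ej$type == type, , drop = FALSE]
        j <- j[match(events$event_id, j$event_id), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = design$sample[s], chrom = j$chrom, strand = j$strand,
          jl = j$jl, jr = j$jr, count = cnt, stringsAsFactors = FALSE)
      }
    }
    junctions <- do.call(rbind, rows)
    rownames(junctions) <- NULL
    list(events = events, junctions = junctions, design = design,
         truth = data.frame(event_id = events$event_id,
                            ir_control = ir_control,
                            ir_treatment = ir_treatment,
                            delta_i = ir_treatment - ir_control,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate dose-responsive count matrices for three clones
#'
#' Two wild-type clones carry planted UP/DOWN genes whose log2 effect rises
#' log-linearly in log2(dose) from `lfc_low` at the lowest nonzero dose to
#' `lfc_high` at the highest; the mutant clone carries no effect for any
#' gene. Counts are negative binomial; library sizes are varied to exercise
#' normalization.
#'
#' @param seed RNG seed.
#' @param n_genes,n_up,n_down gene counts (defaults 2000, 40, 30).
#' @param doses inducer concentrations, must include 0
#'   (default 0, 1, 2.5, 5, 10, 25 ng/ml).
#' @param reps_per_dose replicates per clone and dose (default 3, the usual
#'   triplicate design).
#' @param clones clone ids; the last is the mutant (default WT6, WT10, MUT3).
#' @param dispersion NB dispersion (default 0.1).
#' @param lfc_low,lfc_high planted effect at lowest/highest nonzero dose in
#'   log2 units (defaults 1.5 and 3, so planted effects clear the
#'   lowest-dose detectability criterion at the default dispersion).
#' @param mu_range base-mean range, sampled log-uniformly (default 50-2000).
#' @param libsize_range per-sample library scale factors (default 0.6-1.4).
#' @return list: `counts` (genes x samples), `design` (`sample`, `clone`,
#'   `dose`), `truth` (list: `up_genes`, `down_genes`).
#' @export
simulate_dose_counts <- function(seed, n_genes = 2000L, n_up = 40L,
                                 n_down = 30L,
                                 doses = c(0, 1, 2.5, 5, 10, 25),
                                 reps_per_dose = 3L,
                                 clones = c("WT6", "WT10", "MUT3"),
                                 dispersion = 0.1, lfc_low = 1.5, lfc_high = 3,
                                 mu_range = c(50, 2000),
                                 libsize_range = c(0.6, 1.4)) {
  if (missing(seed)) stop("seed is mandatory")
  if (!0 %in% doses) stop("doses must include 0")
  .with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    up <- sample(genes, n_up)
    down <- sample(setdiff(genes, up), n_down)
    sign <- stats::setNames(rep(0, n_genes), genes)
    sign[up] <- 1; sign[down] <- -1
    mu0 <- exp(stats::runif(n_genes, log(mu_range[1]), log(mu_range[2])))
    nz <- sort(doses[doses > 0])
    lfc_of_dose <- function(d) {
      if (d == 0) return(0)
      if (length(nz) == 1) return(lfc_high)
      lfc_low + (lfc_high - lfc_low) *
        (log2(d / nz[1]) / log2(nz[length(nz)] / nz[1]))
    }
    design <- expand.grid(rep = seq_len(reps_per_dose), dose = sort(doses),
                          clone = clones, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_d%g_r%d", design$clone, design$dose,
                             design$rep)
    counts <- matrix(0L, n_genes, nrow(design),
                     dimnames = list(genes, design$sample))
    mut <- clones[length(clones)]
    for (j in seq_len(nrow(design))) {
      lib <- stats::runif(1, libsize_range[1], libsize_range[2])
      eff <- if (design$clone[j] == mut) 0 else lfc_of_dose(design$dose[j])
      mu <- mu0 * 2^(sign * eff) * lib
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts,
         design = design[, c("sample", "clone", "dose")],
         truth = list(up_genes = sort(up), down_genes = sort(down)))
  })
}

#' Simulate a transcription-shutoff decay time course
#'
#' Exponential decay at the given half-life with multiplicative lognormal
#' noise; time-0 rows are fixed at exactly 1 (the series is t0-normalized by
#' definition).
#'
#' @param t_half true half-life in hours.
#' @param seed RNG seed.
#' @param times sampling times in hours, starting at 0
#'   (default 0, 1, 2, 4, 8).
#' @param n_reps replicates (default 3).
#' @param noise_sd standard deviation of the lognormal noise on the log scale
#'   (default 0.05).
#' @return data.frame: `time`, `value`, `replicate`.
#' @export
simulate_decay <- function(t_half, seed, times = c(0, 1, 2, 4, 8),
                           n_reps = 3L, noise_sd = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  if (t_half <= 0) stop("t_half must be positive")
  if (times[1] != 0) stop("times must start at 0")
  .with_seed(seed, {
    out <- expand.grid(time = times, replicate = seq_len(n_reps),
                       KEEP.OUT.ATTRS = FALSE)
    mu <- 2^(-out$time / t_half)
    noise <- exp(stats::rnorm(nrow(out), 0, noise_sd))
    out$value <- ifelse(out$time == 0, 1, mu * noise)
    out[, c("time", "value", "replicate")]
  })
}
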