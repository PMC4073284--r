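#' rbpreg: transcriptome-wide analysis of an RNA-binding protein's regulatory
#' program
#'
#' See the package vignette for the underlying models and the design of each
#' stage: CLIP tag processing ([demultiplex_and_trim()],
#' [collapse_duplicates()]), cluster calling and stringency tiers
#' ([build_clusters()], [apply_stringency_tiers()]), crosslink-site detection
#' ([cims_fdr()]), cassette-exon statistics ([delta_I()],
#' [call_regulated_exons()], [complexity_map()]), the dose-response target
#' screen ([screen_targets()]) and half-life estimation
#' ([estimate_half_life()]).
#'
#' @keywords internal
"_PACKAGE"

# Default analysis thresholds, bundled so the pipeline and the docs agree:
# BC = 2, cluster tags >= 10, peak height >= 10, reproducibility p <= 0.01,
# CIMS k >= 5 at FDR <= 0.01, splicing |dI| >= 0.2 / p <= 0.05 / >= 10
# junction reads, bound = tags >= 10 in BC2 tags >= 5 clusters, screen
# p < 0.01 with mutant p > 0.05, strong binder > 100 tags per transcript.
default_thresholds <- function() {
  list(min_bc = 2L, min_tags_t2 = 10L, min_peak = 10L, peak_alpha = 0.01,
       repro_alpha = 0.01, cims_min_k = 5L, cims_max_fdr = 0.01,
       splice_min_reads = 10L, splice_min_delta = 0.2, splice_max_p = 0.05,
       bound_min_cluster_tags = 5L, bound_min_total = 10L,
       screen_p_wt = 0.01, screen_p_mut = 0.05, screen_min_lfc = 0.585,
       strong_cutoff = 100L)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a synthetic bundle (genome, CLIP reads, junction reads, dose
#' counts, decay courses) from one seed, runs every analysis stage with the
#' default thresholds (any override via `params` is recorded in the
#' manifest), and writes stage outputs plus a JSON run manifest to `out_dir`.
#' Identical seeds give byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param params named list of threshold overrides (see
#'   `rbpreg:::default_thresholds()`).
#' @param scale list of problem sizes: `n_genes`, `n_events`, `dose_genes`
#'   (defaults 30, 60, 600) to keep smoke runs fast.
#' @return invisibly, a list of the in-memory stage results plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(out_dir, seed, params = list(), scale = list()) {
  th <- utils::modifyList(default_thresholds(), params)
  sc <- utils::modifyList(list(n_genes = 30L, n_events = 60L,
                               dose_genes = 600L), scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  genome <- make_genome(n_genes = sc$n_genes, seed = seed + 1L)
  write_annotation(genome$ann, p("genome.gtf"))

  clip <- simulate_clip(genome, seed = seed + 2L)
  tags <- collapse_duplicates(clip$reads)
  write_tags_bed(tags, p("tags.bed"))

  built <- build_clusters(tags)
  clusters <- annotate_clusters(built, genome$ann)
  clusters <- apply_stringency_tiers(clusters, n_replicates = 2L,
                                     min_bc = th$min_bc,
                                     min_tags_t2 = th$min_tags_t2,
                                     min_peak = th$min_peak,
                                     peak_alpha = th$peak_alpha,
                                     repro_alpha = th$repro_alpha)
  write_tsv(clusters, p("clusters.tsv"))

  sites <- cims_fdr(tags, n_permutations = 100L, seed = seed + 3L,
                    min_k = th$cims_min_k, max_fdr = th$cims_max_fdr)
  write_tsv(sites, p("cims.tsv"))

  jr <- simulate_junction_reads(n_events = sc$n_events,
                                delta_i = rep(c(0.4, -0.4, 0),
                                              length.out = sc$n_events),
                                seed = seed + 4L)
  counts <- count_junction_reads(jr$junctions, jr$events)
  sstats <- merge(delta_I(counts, jr$design), fisher_splice_test(counts, jr$design),
                  by = "event_id", sort = FALSE)
  sstats <- call_regulated_exons(sstats, min_reads = th$splice_min_reads,
                                 min_delta = th$splice_min_delta,
                                 max_p = th$splice_max_p)
  sstats$bound <- bound_exon(jr$events, clusters,
                             min_bc = th$min_bc,
                             min_cluster_tags = th$bound_min_cluster_tags,
                             min_total = th$bound_min_total)
  write_tsv(sstats, p("splicing.tsv"))
  cmap <- complexity_map(jr$events, sstats$status, tags)
  write_tsv(cmap, p("complexity_map.tsv"))

  dose <- simulate_dose_counts(seed = seed + 5L, n_genes = sc$dose_genes,
                               n_up = max(4L, sc$dose_genes %/% 50L),
                               n_down = max(3L, sc$dose_genes %/% 60L))
  norm <- size_factor_normalize(dose$counts)
  # log dose axis: tet-on induction is log-linear in dose, so the log axis is
  # the coherent Pearson pairing
  cors <- dose_correlation(norm$normalized, dose$design, dose_transform = log1p)
  lfcs <- lowest_dose_log2fc(norm$normalized, dose$design)
  screen <- screen_targets(cors, lfcs, wt_clones = c("WT6", "WT10"),
                           mut_clone = "MUT3", p_wt = th$screen_p_wt,
                           p_mut = th$screen_p_mut,
                           min_lfc = th$screen_min_lfc)
  write_tsv(screen, p("dose_screen.tsv"))
  binding <- integrate_binding(screen, tags_per_transcript(clusters),
                               strong_cutoff = th$strong_cutoff)
  write_tsv(binding$summary, p("binding_integration.tsv"))

  decay_truth <- data.frame(series = c("ctrl", "induced"),
                            t_half = c(2.3, 9.8), stringsAsFactors = FALSE)
  dc <- lapply(seq_len(nrow(decay_truth)), function(i)
    simulate_decay(decay_truth$t_half[i], seed = seed + 6L + i))
  hl <- do.call(rbind, lapply(seq_along(dc), function(i) {
    est <- estimate_half_life(dc[[i]]$time, dc[[i]]$value)
    data.frame(series = decay_truth$series[i], t_half = est$t_half,
               rate = est$rate, r2 = est$r2, stringsAsFactors = FALSE)
  }))
  write_tsv(hl, p("half_lives.tsv"))

  manifest <- list(seed = seed, thresholds = th, scale = sc,
                   package_version = as.character(utils::packageVersion("rbpreg")),
                   outputs = c("genome.gtf", "tags.bed", "clusters.tsv",
                               "cims.tsv", "splicing.tsv", "complexity_map.tsv",
                               "dose_screen.tsv", "binding_integration.tsv",
                               "half_lives.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(clusters = clusters, cims = sites, splicing = sstats,
                 complexity_map = cmap, screen = screen, binding = binding,
                 half_lives = hl, manifest_path = p("manifest.json")))
}
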