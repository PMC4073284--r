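simple_tags <- function(start, end, replicate = "rep1", chrom = "c1",
                        strand = "+") {
  n <- length(start)
  df <- data.frame(tag_id = sprintf("t%03d", seq_len(n)), chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand,
                   replicate = rep_len(replicate, n), barcode = "AAAAAA",
                   collapsed_count = 1L, stringsAsFactors = FALSE)
  df$deletions <- rep(list(integer()), n)
  df
}

test_that("clustering merges overlapping tags but not abutting ones", {
  b <- build_clusters(simple_tags(c(100, 120), c(130, 150)))
  expect_equal(nrow(b$clusters), 1)
  expect_equal(b$clusters$start, 100L)
  expect_equal(b$clusters$end, 150L)
  expect_equal(b$clusters$total_tags, 2L)
  # half-open intervals: [100,130) and [130,160) share no base
  b2 <- build_clusters(simple_tags(c(100, 130), c(130, 160)))
  expect_equal(nrow(b2$clusters), 2)
})

test_that("cluster membership equals the connected-components oracle", {
  for (seed in c(3, 4)) {
    tags <- random_tags(120, seed = seed, span = 1500)
    b <- build_clusters(tags)
    comp <- oracle_components(tags)
    # identical partitions: same label <=> same cluster
    expect_equal(length(unique(comp)), nrow(b$clusters))
    cross <- table(comp, b$tags$cluster_id)
    expect_true(all(rowSums(cross > 0) == 1))
    expect_true(all(colSums(cross > 0) == 1))
    # every tag in exactly one cluster
    expect_true(all(!is.na(b$tags$cluster_id)))
  }
})

test_that("peak height equals the brute-force pileup maximum", {
  # ten tags stacked over one base
  p <- peak_height(rep(995L, 10), rep(1005L, 10))
  expect_equal(p$height, 10L)
  # two stacks of depth 4 and 7
  p2 <- peak_height(c(rep(0L, 4), rep(100L, 7)), c(rep(30L, 4), rep(130L, 7)))
  expect_equal(p2$height, 7L)
  for (seed in c(7, 8)) {
    set.seed(seed)
    s <- sample.int(300, 60, replace = TRUE)
    e <- s + sample(10:40, 60, replace = TRUE)
    ours <- peak_height(s, e)
    brute <- oracle_pileup_max(s, e)
    expect_equal(ours$height, brute$height)
    expect_equal(ours$position, brute$position)
  }
})

test_that("peak significance behaves like a corrected Poisson tail", {
  # strong peak over a quiet gene: lambda = 0.1
  p <- peak_significance(10, gene_tag_total = 10, gene_length = 3000,
                         mean_tag_length = 30)
  expect_lt(p, 1e-6)
  # depth-1 peak at lambda 1 is not enrichment
  expect_equal(peak_significance(1, 100, 3000, 30), 1)
  # monotone in background: p shrinks as lambda -> 0
  ps <- vapply(c(100, 30, 10, 3), function(tt)
    peak_significance(5, tt, 3000, 30), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(peak_significance(5, 10, 0, 30), "gene_length")
})

test_that("reproducibility score flags replicate-skewed clusters", {
  bal <- reproducibility_score(c(10, 10), c(100, 100))
  expect_equal(bal$chi2, 0)
  expect_gt(bal$p, 0.99)
  skew <- reproducibility_score(c(20, 0), c(100, 100))
  expect_lt(skew$p, 0.01)
  # oracle: the statistic is the standard two-sample chi-squared
  tbl <- rbind(c(20, 80), c(0, 100))
  expect_equal(skew$chi2,
               unname(suppressWarnings(chisq.test(tbl, correct = FALSE))$statistic))
  expect_error(reproducibility_score(c(5), c(10)), "2 replicates")
})

test_that("stringency tiers are nested and require biological complexity", {
  g <- make_genome(n_genes = 10, seed = 13)
  clip <- simulate_clip(g, seed = 14)
  tags <- collapse_duplicates(clip$reads)
  cl <- annotate_clusters(build_clusters(tags), g$ann)
  cl <- apply_stringency_tiers(cl, n_replicates = 2)
  sizes <- colSums(cl[, paste0("tier", 1:4)])
  expect_true(all(diff(sizes) <= 0))
  # a BC1 cluster never enters any tier, however many tags it has
  one_rep <- cl[cl$bc == 1, ]
  if (nrow(one_rep))
    expect_true(all(!one_rep$tier1))
  # invariants on the cluster statistics
  expect_true(all(cl$bc >= 1 & cl$bc <= 2))
  expect_true(all(cl$peak_height >= 1 & cl$peak_height <= cl$total_tags))
  ok <- !is.na(cl$peak_p)
  expect_true(all(cl$peak_p[ok] >= 0 & cl$peak_p[ok] <= 1))
})

test_that("few balanced clusters are flagged irreproducible under the null", {
  # both replicates drawn from the same clumped distribution over one gene:
  # tags pile up around shared hotspots, so clusters stay separate
  set.seed(99)
  centers <- sort(sample.int(195000, 60))
  n_per <- sample(12:30, 60, replace = TRUE)
  start <- unlist(mapply(function(c, k) pmax(round(rnorm(k, c, 12)), 0),
                         centers, n_per))
  n <- length(start)
  tags <- simple_tags(start, start + 30,
                      replicate = sample(c("rep1", "rep2"), n, TRUE))
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines('c1\tt\texon\t1\t200000\t.\t+\t.\tgene_id "g"; transcript_id "t";',
             path)
  ann <- read_annotation(path)
  cl <- annotate_clusters(build_clusters(tags), ann)
  big <- cl[cl$bc == 2 & cl$total_tags >= 10, ]
  expect_gt(nrow(big), 20)
  expect_lte(mean(big$repro_p <= 0.01), 0.03)
})

test_that("region distributions normalize within each tier", {
  g <- make_genome(n_genes = 10, seed = 23)
  clip <- simulate_clip(g, seed = 24)
  tags <- collapse_duplicates(clip$reads)
  cl <- apply_stringency_tiers(annotate_clusters(build_clusters(tags), g$ann),
                               n_replicates = 2)
  rd <- region_distribution(cl, g$ann)
  for (t in unique(rd$proportions$tier))
    expect_equal(sum(rd$proportions$proportion[rd$proportions$tier == t]), 1,
                 tolerance = 1e-12)
})

test_that("per-gene tag totals follow the strong-binder filter", {
  cl <- data.frame(cluster_id = c("a", "b", "c"), gene_id = "g1",
                   bc = c(2L, 2L, 1L), total_tags = c(60L, 50L, 500L),
                   stringsAsFactors = FALSE)
  tt <- tags_per_transcript(cl)
  expect_equal(tt$tag_total, 110L)  # BC1 cluster contributes nothing
  expect_true(tt$strong_binder)    # 110 > 100
  cl2 <- cl; cl2$bc <- 1L
  expect_equal(nrow(tags_per_transcript(cl2)), 0)
  # random clusters match a brute-force per-gene sum
  set.seed(6)
  cl3 <- data.frame(cluster_id = sprintf("c%d", 1:200),
                    gene_id = sample(sprintf("g%d", 1:20), 200, TRUE),
                    bc = sample(1:2, 200, TRUE),
                    total_tags = sample(1:60, 200, TRUE),
                    stringsAsFactors = FALSE)
  tt3 <- tags_per_transcript(cl3)
  keep <- cl3$bc >= 2 & cl3$total_tags >= 10
  brute <- tapply(cl3$total_tags[keep], cl3$gene_id[keep], sum)
  expect_equal(tt3$tag_total, as.integer(brute[tt3$gene_id]),
               ignore_attr = TRUE)
})
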