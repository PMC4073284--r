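one_event <- function(strand = "+") {
  cassette_events(event_id = "ev1", gene_id = "g1", chrom = "c1",
                  strand = strand, e1_start = 0L, e1_end = 150L,
                  e2_start = 550L, e2_end = 670L,
                  e3_start = 1070L, e3_end = 1220L)
}

test_that("junction matching is exact-coordinate with an unmatched tally", {
  ev <- one_event()
  j <- data.frame(sample = "s1", chrom = "c1", strand = "+",
                  jl = c(150L, 670L, 150L, 151L),
                  jr = c(550L, 1070L, 1070L, 550L),
                  count = c(20L, 40L, 10L, 99L))
  cnt <- count_junction_reads(j, ev)
  expect_equal(cnt$inc_up, 20L)
  expect_equal(cnt$inc_down, 40L)
  expect_equal(cnt$skip, 10L)
  expect_equal(attr(cnt, "unmatched"), 1L)  # the off-by-1 junction
  # on the minus strand the genomically-right junction is inc_up
  evm <- one_event("-")
  jm <- data.frame(sample = "s1", chrom = "c1", strand = "-",
                   jl = 670L, jr = 1070L, count = 7L)
  cm <- count_junction_reads(jm, evm)
  expect_equal(cm$inc_up, 7L)
  expect_equal(cm$inc_down, 0L)
})

test_that("inclusion rate averages the two inclusion junctions", {
  expect_equal(inclusion_rate(20, 40, 10), 0.75)  # I = 30, 30/(30+10)
  expect_equal(inclusion_rate(5, 7, 0), 1)
  expect_equal(inclusion_rate(0, 0, 12), 0)
  expect_true(is.na(inclusion_rate(0, 0, 0)))
  # scale invariance
  expect_equal(inclusion_rate(200, 400, 100), inclusion_rate(2, 4, 1))
})

test_that("delta_I averages IR within condition and subtracts", {
  counts <- data.frame(
    event_id = "e", sample = paste0("s", 1:6),
    inc_up = c(90, 88, 92, 50, 52, 48), inc_down = c(90, 88, 92, 50, 52, 48),
    skip = c(10, 12, 8, 50, 48, 52))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("treatment", "control"), each = 3))
  d <- delta_I(counts, design)
  expect_equal(d$delta_i, mean(c(.9, 88 / 100, .92)) - mean(c(.5, .52, .48)),
               tolerance = 1e-12)
  # identical conditions give exactly zero
  d0 <- delta_I(counts[c(4:6, 4:6), ] |>
                  transform(sample = paste0("s", 1:6)), design)
  expect_equal(d0$delta_i, 0)
  # antisymmetry under condition swap
  design_sw <- transform(design,
                         condition = ifelse(condition == "control",
                                            "treatment", "control"))
  expect_equal(delta_I(counts, design_sw)$delta_i, -d$delta_i)
  expect_error(delta_I(counts, transform(design, condition = "control")),
               "missing condition")
})

test_that("Fisher splice p equals exhaustive hypergeometric enumeration", {
  design <- data.frame(sample = c("t1", "c1"),
                       condition = c("treatment", "control"))
  mk <- function(inc_t, skip_t, inc_c, skip_c)
    data.frame(event_id = "e", sample = c("t1", "c1"),
               inc_up = c(inc_t, inc_c), inc_down = 0L,
               skip = c(skip_t, skip_c))
  expect_equal(fisher_splice_test(mk(10, 10, 10, 10), design)$fisher_p, 1)
  p <- fisher_splice_test(mk(10, 0, 0, 10), design)$fisher_p
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-9)
  # zero margin convention
  expect_equal(fisher_splice_test(mk(0, 0, 5, 5), design)$fisher_p, 1)
  # random small tables against the enumeration oracle
  set.seed(14)
  for (i in 1:60) {
    tb <- matrix(sample(0:15, 4, TRUE), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    ours <- fisher_splice_test(mk(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                               design)$fisher_p
    expect_equal(ours, oracle_fisher_p(tb), tolerance = 1e-9)
  }
})

test_that("regulated-exon calls apply the read, effect and p thresholds", {
  st <- data.frame(event_id = c("a", "b", "c", "d"),
                   delta_i = c(0.4, 0.15, -0.5, 0.4),
                   total_reads = c(60L, 500L, 40L, 8L),
                   fisher_p = c(0.001, 1e-4, 0.01, 1e-6))
  out <- call_regulated_exons(st)
  expect_equal(out$status, c("included", "ns", "excluded", "ns"))
})

test_that("bound-exon rule sums qualifying clusters over the event span", {
  ev <- one_event()
  cl <- function(start, end, bc, tags)
    data.frame(cluster_id = "x", chrom = "c1", start = start, end = end,
               strand = "+", bc = bc, total_tags = tags)
  expect_true(bound_exon(ev, cl(200L, 260L, 2L, 12L)))        # 12 in 5'FI
  expect_true(bound_exon(ev, rbind(cl(200L, 260L, 2L, 5L),
                                   cl(700L, 760L, 2L, 5L))))  # 5 + 5
  expect_false(bound_exon(ev, cl(200L, 260L, 1L, 100L)))      # BC1
  expect_false(bound_exon(ev, cl(5000L, 5100L, 2L, 100L)))    # outside span
})

test_that("complexity map is an event fraction bounded in [0, 1]", {
  ev <- one_event()
  # tags tiling the whole 5' flanking intron
  starts <- seq(150L, 520L, by = 10L)
  tags <- data.frame(tag_id = sprintf("t%d", seq_along(starts)), chrom = "c1",
                     start = starts, end = starts + 30L, strand = "+",
                     replicate = "rep1", barcode = "A", collapsed_count = 1L)
  tags$deletions <- rep(list(integer()), nrow(tags))
  cm <- complexity_map(ev, "included", tags, window = 300, exon_margin = 20)
  don <- cm[cm$boundary == "ce5_donor" & cm$offset >= 0, ]
  expect_true(all(don$fraction[don$offset < 190] == 1))
  expect_true(all(cm$fraction >= 0 & cm$fraction <= 1))
  # no tags at all: flat zero profile
  cm0 <- complexity_map(ev, "included", tags[0, ], window = 300)
  expect_true(all(cm0$fraction == 0))
  # brute-force check at the CA acceptor: fraction = coverage indicator
  cm_acc <- cm[cm$boundary == "ca_acceptor", ]
  for (off in c(-5L, 0L, 10L, 100L)) {
    gpos <- 550L - 1L - off  # intron extends genomically left of the acceptor
    if (off < 0) gpos <- 550L + (-off - 1L)
    covered <- any(tags$start <= gpos & tags$end > gpos)
    expect_equal(cm_acc$fraction[cm_acc$offset == off] == 1, covered)
  }
})

test_that("planted reciprocal events are recovered with correct signs", {
  sim <- simulate_junction_reads(40, delta_i = rep(c(0.4, -0.4), 20),
                                 seed = 31)
  cnt <- count_junction_reads(sim$junctions, sim$events)
  st <- merge(delta_I(cnt, sim$design), fisher_splice_test(cnt, sim$design),
              by = "event_id", sort = FALSE)
  st <- call_regulated_exons(st)
  truth_sign <- sign(sim$truth$delta_i[match(st$event_id,
                                             sim$truth$event_id)])
  called <- st$status != "ns"
  expect_gte(mean(called), 0.95)
  expect_true(all(sign(st$delta_i[called]) == truth_sign[called]))
})
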