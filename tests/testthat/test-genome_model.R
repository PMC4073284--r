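test_that("GTF parsing builds normalized transcript models", {
  ann <- toy_annotation()
  expect_s3_class(ann, "transcript_annotation")
  expect_equal(nrow(ann$transcripts), 2)
  tA <- ann$transcripts[ann$transcripts$transcript_id == "tA", ]
  # 1-based GTF converted to 0-based half-open
  expect_equal(tA$tx_start, 0L)
  expect_equal(tA$tx_end, 300L)
  expect_equal(tA$cds_start, 50L)
  expect_equal(tA$cds_end, 250L)
  # minus-strand transcript: exon rank 1 is the genomically rightmost exon
  eB <- ann$exons[ann$exons$transcript_id == "tB", ]
  expect_equal(eB$exon_rank[order(eB$start)], c(2L, 1L))
})

test_that("malformed GTF lines raise errors naming the line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1\tbroken line"), path)
  expect_error(read_annotation(path), "line 2")
  writeLines(c(
    'chr1\tt\texon\t100\t1\t.\t+\t.\tgene_id "g"; transcript_id "t";'), path)
  expect_error(read_annotation(path), "line 1")
})

test_that("region derivation follows CDS bounds and strand", {
  ann <- toy_annotation()
  # plus strand, exons [0,100) [200,300), CDS 50-250
  rA <- derive_regions(ann, "tA")
  get <- function(lab) rA[rA$label == lab, c("start", "end")]
  expect_equal(get("5'UTR"), data.frame(start = 0L, end = 50L),
               ignore_attr = TRUE)
  expect_equal(get("3'UTR"), data.frame(start = 250L, end = 300L),
               ignore_attr = TRUE)
  expect_equal(get("intron"), data.frame(start = 100L, end = 200L),
               ignore_attr = TRUE)
  # same layout on the minus strand swaps the UTR labels
  rB <- derive_regions(ann, "tB")
  expect_equal(rB[rB$label == "3'UTR", "start"], 400L)
  expect_equal(rB[rB$label == "5'UTR", "start"], 650L)
})

test_that("regions are disjoint and reconstruct the transcript span", {
  g <- make_genome(n_genes = 12, seed = 31)
  regs <- derive_regions(g$ann)
  for (tid in g$ann$transcripts$transcript_id) {
    r <- regs[regs$transcript_id == tid, ]
    r <- r[order(r$start), ]
    # pairwise disjoint
    expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    # union covers the span exactly
    expect_true(all(r$start[-1] == r$end[-nrow(r)]))
    tr <- g$ann$transcripts[g$ann$transcripts$transcript_id == tid, ]
    expect_equal(min(r$start), tr$tx_start)
    expect_equal(max(r$end), tr$tx_end)
  }
})

test_that("transcripts without CDS yield noncoding exons and no UTRs", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";'), path)
  r <- derive_regions(read_annotation(path))
  expect_equal(r$label, "noncoding_exon")
  expect_equal(nrow(r[r$label == "intron", ]), 0)  # single exon, no intron
})

test_that("region assignment is total and obeys the priority rule", {
  ann <- toy_annotation()
  q <- data.frame(chrom = "chr1",
                  start = c(260L, 120L, 5000L, 420L),
                  end = c(280L, 140L, 5050L, 440L),
                  strand = c("+", "+", "+", "+"))
  labs <- assign_region(q, ann)
  expect_equal(labs, c("3'UTR", "intron", "intergenic", "intergenic"))
  # same position on the matching strand is genic: strandedness matters
  q$strand <- "-"
  expect_equal(assign_region(q, ann)[4], "3'UTR")

  # ambiguity: intron of one gene vs 3'UTR of another, same strand
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id "gX"; transcript_id "tX";',
    'chr1\tt\texon\t901\t1000\t.\t+\t.\tgene_id "gX"; transcript_id "tX";',
    'chr1\tt\texon\t301\t600\t.\t+\t.\tgene_id "gY"; transcript_id "tY";',
    'chr1\tt\tCDS\t301\t400\t.\t+\t.\tgene_id "gY"; transcript_id "tY";'),
    path)
  ann2 <- read_annotation(path)
  # query sits in gX's intron and gY's 3'UTR simultaneously
  lab <- assign_region(data.frame(chrom = "chr1", start = 450L, end = 470L,
                                  strand = "+"), ann2)
  # brute-force enumeration of overlapping labels confirms both are present
  regs <- derive_regions(ann2)
  over <- regs[regs$start < 470 & regs$end > 450, "label"]
  expect_setequal(over, c("intron", "3'UTR"))
  expect_equal(lab, "3'UTR")
})

test_that("annotation and BED round-trips are lossless", {
  g <- make_genome(n_genes = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(g$ann, path)
  back <- read_annotation(path)
  expect_equal(back$transcripts, g$ann$transcripts)
  expect_equal(back$exons, g$ann$exons)

  tags <- random_tags(40, seed = 8)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tags_bed(tags, bed)
  back_tags <- read_tags_bed(bed)
  expect_equal(back_tags$start, tags$start)
  expect_equal(back_tags$barcode, tags$barcode)
  expect_equal(back_tags$deletions, tags$deletions)
})

test_that("GTF parse agrees with rtracklayer on coordinates", {
  library(rtracklayer)
  g <- make_genome(n_genes = 5, seed = 77)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(g$ann, path)
  gr <- rtracklayer::import(path)
  ex <- gr[gr$type == "exon"]
  ours <- g$ann$exons[order(g$ann$exons$start), ]
  theirs <- as.data.frame(ex)[order(GenomicRanges::start(ex)), ]
  expect_equal(ours$start, theirs$start - 1L)
  expect_equal(ours$end, theirs$end)
  expect_equal(sort(unique(theirs$transcript_id)),
               sort(unique(ours$transcript_id)))
})
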