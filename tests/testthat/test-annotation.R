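mk_aln <- function(tag, start, end, chrom = "chr1", strand = "+") {
  data.frame(tag = tag, chrom = chrom, start = start, end = end,
             strand = strand, mismatches = 0L, stringsAsFactors = FALSE)
}

test_that("category priority resolves multi-feature overlaps", {
  feats <- feature_set(data.frame(
    chrom = "chr1", start = c(0, 0, 500), end = c(100, 100, 600),
    strand = "+", class = c("exon", "rRNA", "intron")))
  # known miRNA beats exon overlap
  aln <- mk_aln("TAGA", 10, 32)
  res <- annotate_tags(aln, feats, known_tags = "TAGA")
  expect_equal(as.character(res$category), "known_miRNA")
  # rRNA beats exon at the same interval
  res2 <- annotate_tags(mk_aln("TAGB", 10, 32), feats)
  expect_equal(as.character(res2$category), "rRNA")
  # mapped, no overlap: unannotated
  res3 <- annotate_tags(mk_aln("TAGC", 200, 222), feats)
  expect_equal(as.character(res3$category), "unannotated")
})

test_that("adding a lower-priority overlap never changes an assignment", {
  base <- feature_set(data.frame(chrom = "chr1", start = 0, end = 100,
                                 strand = "+", class = "tRNA"))
  more <- feature_set(data.frame(
    chrom = "chr1", start = c(0, 0), end = c(100, 100), strand = "+",
    class = c("tRNA", "intron")))
  aln <- mk_aln("TAGX", 10, 32)
  expect_equal(as.character(annotate_tags(aln, base)$category),
               as.character(annotate_tags(aln, more)$category))
})

test_that("every tag receives exactly one category and counts are conserved", {
  set.seed(31)
  feats <- feature_set(data.frame(
    chrom = "chr1", start = seq(0, 900, 100), end = seq(60, 960, 100),
    strand = "+",
    class = sample(c("rRNA", "tRNA", "repeat", "exon"), 10, TRUE)))
  tags <- data.frame(sequence = sprintf("TAG%02d", 1:30),
                     count = sample(1:100, 30), stringsAsFactors = FALSE)
  starts <- sample(0:950, 30)
  aln <- mk_aln(tags$sequence, start = starts, end = starts + 22)
  res <- annotate_tags(aln, feats)
  expect_equal(nrow(res), 30)
  expect_false(any(is.na(res$category)))
  summ <- summarize_categories(res, tags)
  expect_equal(sum(summ$total_reads), sum(tags$count))
  expect_equal(sum(summ$unique_tags), 30)
})

test_that("single-tag and empty summaries behave", {
  res <- annotate_tags(mk_aln("T1", 0, 22), NULL)
  summ <- summarize_categories(res, data.frame(sequence = "T1", count = 5L))
  expect_equal(summ$pct_reads[summ$category == "unannotated"], 100)
  no_aln <- data.frame(tag = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), mismatches = integer(0))
  empty <- summarize_categories(
    annotate_tags(no_aln, NULL),
    data.frame(sequence = character(0), count = integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("feature files round-trip through BED", {
  df <- data.frame(chrom = "chr1", start = c(10L, 200L), end = c(80L, 260L),
                   strand = c("+", "-"), class = c("rRNA", "repeat"))
  bed <- tempfile(fileext = ".bed")
  write.table(data.frame(df$chrom, df$start, df$end, df$class, 0L, df$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gr <- read_features(bed)
  expect_equal(gr$feature_class, df$class)
  expect_equal(BiocGenerics::start(gr) - 1L, df$start)
  expect_equal(BiocGenerics::end(gr), df$end)
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t1\t5\tplasmid\t0\t+", bad)
  expect_error(read_features(bad), "unknown feature class")
})
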