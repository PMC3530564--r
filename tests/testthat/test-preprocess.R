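ad3 <- "TCGTATGCCGTCTTCTGCTTG"
ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
mk_read <- function(ins, len = 36L) substr(paste0(ins, ad3), 1, len)

test_that("reads are classified into the fixed category hierarchy", {
  ins22 <- "ACGTGCATCAGTTCAGCTACGA"
  r <- classify_read(mk_read(ins22), ad3, ad5)
  expect_equal(r$category, "clean")
  expect_equal(r$insert, ins22)

  # no adapter prefix anywhere
  expect_equal(classify_read(strrep("AC", 18), ad3, ad5)$category,
               "adapter3_null")
  # adapter at position 1: empty insert
  expect_equal(classify_read(substr(paste0(ad3, ad3), 1, 36), ad3,
                             ad5)$category, "insert_null")
  # insert starting with the 5' adapter tail
  tail5 <- substr(ad5, nchar(ad5) - 7, nchar(ad5))
  expect_equal(classify_read(mk_read(paste0(tail5, "ACGTGCATCAGTTC")), ad3,
                             ad5)$category, "adapter5_contaminant")
  # polyA insert
  expect_equal(classify_read(mk_read(strrep("A", 20)), ad3, ad5)$category,
               "polyA")
  # 16-nt insert is below the 18-nt minimum
  expect_equal(classify_read(mk_read("ACGTGCATCAGTTCAG"), ad3, ad5)$category,
               "too_short")
  # N anywhere wins over everything
  expect_equal(classify_read(mk_read("ACGTGCATCANTTCAGCTACGA"), ad3,
                             ad5)$category, "low_quality")
  expect_error(classify_reads("", ad3, ad5), "empty")
})

test_that("already-trimmed inserts are not trimmed again", {
  # a bare insert carries no adapter, so it must land in adapter3_null
  # rather than being re-trimmed to something shorter
  expect_equal(classify_read("ACGTGCATCAGTTCAGCTACGA", ad3, ad5)$category,
               "adapter3_null")
})

test_that("cleaning conserves counts and collapses tags correctly", {
  set.seed(42)
  inserts <- replicate(200, paste(
    sample(c("A", "C", "G", "T"), sample(18:30, 1), replace = TRUE),
    collapse = ""))
  inserts <- inserts[!grepl("^(AAAAAAAA)", inserts)]
  reads <- c(mk_read(inserts[sample.int(length(inserts), 500, replace = TRUE)]),
             replicate(30, paste(sample(c("A", "C"), 36, TRUE), collapse = "")))
  res <- clean_library(reads, ad3, ad5)
  rep <- res$report
  counts <- setNames(rep$reads, rep$category)
  # raw = low quality + all filter classes + clean
  expect_equal(counts[["raw_reads"]],
               (counts[["raw_reads"]] - counts[["high_quality"]]) +
                 counts[["adapter3_null"]] + counts[["insert_null"]] +
                 counts[["adapter5_contaminant"]] +
                 counts[["shorter_than_18"]] + counts[["polyA"]] +
                 counts[["clean_reads"]])
  # collapse conserves reads and matches a brute-force dictionary count
  expect_equal(sum(res$tags$count), counts[["clean_reads"]])
  cls <- classify_reads(reads, ad3, ad5)
  dict <- table(cls$insert[cls$category == "clean"])
  expect_equal(sort(setNames(res$tags$count, res$tags$sequence)),
               sort(setNames(as.integer(dict), names(dict))))
})

test_that("an empty library yields an all-zero report", {
  res <- clean_library(character(0), ad3, ad5)
  expect_equal(nrow(res$tags), 0)
  expect_true(all(res$report$reads == 0))
})

test_that("the published accounting reproduces its printed percentages", {
  qc <- mammary_qc_counts()
  d <- qc[qc$library == "dry", ]
  rep <- qc_report(raw_reads = d$raw_reads, high_quality = d$high_quality,
                   adapter3_null = d$adapter3_null,
                   insert_null = d$insert_null,
                   adapter5_contaminant = d$adapter5_contaminant,
                   shorter_than_18 = d$shorter_than_18, polyA = d$polyA,
                   clean_reads = d$clean_reads)
  expect_equal(rep$pct[rep$category == "clean_reads"], 94.55)
  expect_equal(rep$pct[rep$category == "high_quality"], 99.53)
})

test_that("length histograms conserve reads and find the 22-nt mode", {
  one <- data.frame(sequence = strrep("A", 22), count = 7L)
  h <- length_distribution(one)
  expect_equal(h$reads[h$length == 22], 7)
  expect_equal(sum(h$reads), 7)
  expect_equal(sum(h$proportion), 1)

  set.seed(5)
  lens <- sample(18:30, 400, replace = TRUE,
                 prob = c(2, 3, 5, 8, 14, 8, 5, 3, 2, 1.5, 1, 0.8, 0.5))
  tags <- data.frame(sequence = vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
    character(1)), count = sample(1:50, 400, TRUE))
  tags <- tags[!duplicated(tags$sequence), ]
  h <- length_distribution(tags)
  expect_equal(h$length[which.max(h$reads)], 22)
})
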