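# a small hand-built reference: one precursor with both arms named
ref_fixture <- function() {
  mat <- "TGAGGTAGTAGGTTGTATAGTT"            # 5' arm, positions 1-22
  loop <- "GGGAAACCC"
  star <- revcomp("TGAGGTAGTAGGTTGTATACTT")  # imperfect complement arm
  prec <- paste0(mat, loop, star)
  read_mirbase(
    mature_fa = c("sim-let-7a" = mat,
                  "sim-let-7a*" = star),
    hairpin_fa = c("sim-let-7a" = prec))
}

test_that("matures are located inside their precursors on loading", {
  ref <- ref_fixture()
  m <- ref$matures
  expect_equal(nrow(m), 2)
  for (i in 1:2) {
    expect_equal(substr(ref$precursors[[m$precursor[i]]], m$start[i], m$end[i]),
                 m$sequence[i])
  }
})

test_that("tags match matures exactly and within the end-shift tolerance", {
  ref <- ref_fixture()
  mat <- ref$matures$sequence[ref$matures$name == "sim-let-7a"]
  hit <- match_conserved(mat, ref)
  expect_equal(hit$mirna, "sim-let-7a")
  expect_equal(hit$shift, 0L)
  expect_equal(hit$mismatches, 0L)

  # 3' end extended 2 nt into the precursor: still a match, shift 2
  prec <- ref$precursors[[1]]
  ext <- substr(prec, 1, nchar(mat) + 2)
  hit2 <- match_conserved(ext, ref)
  expect_equal(hit2$mirna, "sim-let-7a")
  expect_equal(hit2$shift, 2L)

  # 3 nt beyond the tolerance: no match
  ext3 <- substr(prec, 1, nchar(mat) + 3)
  expect_null(match_conserved(ext3, ref))

  # a tag sitting across the loop only: no match
  loop_tag <- substr(prec, nchar(mat) + 4, nchar(mat) + 4 + 17)
  expect_null(match_conserved(loop_tag, ref))
})

test_that("arm labels follow the reference naming conventions", {
  expect_equal(assign_arm("miR-126*"), "miRNA*")
  expect_equal(assign_arm("let-7a"), "miRNA")
  expect_equal(assign_arm("miR-199a-3p"), "miRNA-3p")
  expect_equal(assign_arm("miR-26-5p"), "miRNA-5p")
})

test_that("count tables tally unique tags and total reads", {
  ref <- ref_fixture()
  prec <- ref$precursors[[1]]
  mat <- ref$matures$sequence[ref$matures$name == "sim-let-7a"]
  shifted <- substr(prec, 1, nchar(mat) + 1)
  matches <- match_conserved_all(c(mat, shifted), ref)
  tags <- data.frame(sequence = c(mat, shifted), count = c(3L, 5L))
  ct <- count_table(matches, tags)
  expect_equal(ct$unique_tags, 2L)
  expect_equal(ct$total_reads, 8L)
  s <- attr(ct, "summary")
  expect_equal(s$detected_mirnas, 1L)
  expect_equal(s$total_reads_matched, 8L)

  empty <- count_table(match_conserved_all(character(0), ref), tags)
  expect_equal(nrow(empty), 0)
})

test_that("synthetic known-miRNA reads all return to their source entries", {
  cfg <- small_sim_config(seed = 301L)
  built <- build_toy_genome(cfg)
  man <- built$manifest
  ref <- read_mirbase(man$reference$mature, man$reference$hairpin)
  known <- man$loci[man$loci$class == "known_mirna", ]
  for (i in seq_len(nrow(known))) {
    hit <- match_conserved(known$mature_seq[i], ref)
    expect_equal(hit$mirna, known$mature_name[i])
    hit_s <- match_conserved(known$star_seq[i], ref)
    expect_equal(hit_s$mirna, known$star_name[i])
  }
})
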