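# hand-built structure: 25-bp perfect stem, 4-nt loop
perfect_stem_structure <- function() {
  stem <- paste(sample(c("G", "C"), 25, TRUE), collapse = "")
  seq <- paste0(stem, "AAAA", chartr("GC", "CG",
                                     paste(rev(strsplit(stem, "")[[1]]),
                                           collapse = "")))
  pairs <- cbind(1:25, 54:30)
  db <- paste0(strrep("(", 25), "....", strrep(")", 25))
  structure(list(sequence = chartr("T", "U", seq), dot_bracket = db,
                 mfe = -40, pairs = pairs), class = "hairpin_structure")
}

test_that("features of a perfect stem-loop are read off exactly", {
  set.seed(41)
  st <- perfect_stem_structure()
  f <- extract_features(st, c(2, 23))
  expect_equal(f$n_stem_pairs, 25L)
  expect_equal(f$loop_length, 4L)
  expect_equal(f$max_bulge, 0L)
  expect_equal(f$hairpin_length, 54L)
  expect_equal(f$mature_in_stem_pct, 100)
})

test_that("the let-7a mature is 63.6 percent A+U", {
  st <- list(sequence = chartr("T", "U",
                               normalize_dna(chartr("u", "t",
                                 "ugagguaguagguuguauaguu"))),
             dot_bracket = strrep(".", 22), mfe = 0,
             pairs = matrix(integer(0), ncol = 2))
  class(st) <- "hairpin_structure"
  f <- extract_features(st, c(1, 22))
  expect_equal(f$mature_AU_pct, 100 * 14 / 22, tolerance = 1e-9)
})

test_that("a mature crossing the loop falls below the in-stem threshold", {
  st <- perfect_stem_structure()
  f <- extract_features(st, c(16, 37))  # 10 stem + 4 loop + 8 stem
  expect_lt(f$mature_in_stem_pct, 100)
  expect_equal(f$mature_in_stem_pct, 100 * 18 / 22, tolerance = 1e-9)
})

test_that("each criterion gates at its published boundary", {
  f <- list(n_stem_pairs = 25L, loop_length = 4L, max_bulge = 0L,
            hairpin_length = 54L, mature_in_stem_pct = 100,
            mature_AU_pct = 50, mfe = -40)
  class(f) <- "hairpin_features"
  expect_true(apply_criteria(f)$overall)

  short <- f; short$hairpin_length <- 52L
  v <- apply_criteria(short)
  expect_false(v$c5); expect_false(v$overall)
  expect_true(all(unlist(v[c("c1", "c2", "c3", "c4", "c6", "c7")])))

  border <- f; border$mfe <- -20
  expect_false(apply_criteria(border)$c3)  # "under -20" is strict

  au <- f; au$mature_AU_pct <- 25
  expect_false(apply_criteria(au)$c7)
  au$mature_AU_pct <- 30
  expect_true(apply_criteria(au)$c7)  # inclusive range ends

  none <- f; none$n_stem_pairs <- 0L; none$loop_length <- NA_integer_
  none$hairpin_length <- NA_integer_; none$max_bulge <- NA_integer_
  v0 <- apply_criteria(none)
  expect_false(v0$overall)
})

test_that("strengthening a stem never flips c1 or c5 from pass to fail", {
  set.seed(43)
  for (i in 1:20) {
    npairs <- sample(18:30, 1)
    loop <- sample(4:20, 1)
    len <- 2 * npairs + loop
    f <- list(n_stem_pairs = npairs, loop_length = loop, max_bulge = 0L,
              hairpin_length = len, mature_in_stem_pct = 100,
              mature_AU_pct = 50, mfe = -30)
    class(f) <- "hairpin_features"
    v <- apply_criteria(f)
    g <- f
    g$n_stem_pairs <- g$n_stem_pairs + 1L   # one more terminal pair
    g$hairpin_length <- g$hairpin_length + 2L
    w <- apply_criteria(g)
    expect_true(!v$c1 || w$c1)
    expect_true(!v$c5 || w$c5)
  }
})

test_that("candidate extraction enforces abundance, uniqueness and annotation", {
  set.seed(44)
  g <- random_dna(2000)
  tagA <- substr(g, 301, 322)   # unique, count 20 -> kept
  tagB <- substr(g, 601, 622)   # count 4 -> dropped
  dup <- substr(g, 901, 922)
  g2 <- paste0(g, dup)          # tagC maps twice -> dropped
  idx <- build_index(c(chr1 = g2))
  tags <- data.frame(sequence = c(tagA, tagB, dup),
                     count = c(20L, 4L, 50L), stringsAsFactors = FALSE)
  aln <- map_tags(tags$sequence, idx)
  ann <- data.frame(tag = tags$sequence,
                    category = factor("unannotated",
                                      levels = annotation_categories()))
  cand <- extract_candidates(tags, aln, ann, idx)
  expect_setequal(unique(cand$tag), tagA)
  expect_equal(nrow(cand), 2)       # two windows
  expect_true(all(grepl(tagA, cand$win_seq, fixed = TRUE)))
  # windows carry the tag at the stated position
  for (r in 1:2) {
    expect_equal(substr(cand$win_seq[r], cand$mature_start[r],
                        cand$mature_end[r]), tagA)
  }
})

test_that("freshly constructed hairpins always pass the seven criteria", {
  set.seed(45)
  cfg <- simulation_config()
  for (i in 1:100) {
    hp <- construct_passing_hairpin(22, cfg)
    ev <- caprimir:::evaluate_candidate_window(hp$seq, c(1, 22))
    expect_true(ev$verdict$overall)
  }
  expect_error(construct_passing_hairpin(19, cfg), "between 20 and 24")
})

test_that("prediction keeps the lower-MFE window and orders ids by count", {
  set.seed(46)
  cfg <- small_sim_config(seed = 401L)
  built <- build_toy_genome(cfg)
  idx <- build_index(built$genome)
  man <- built$manifest
  nov <- man$loci[man$loci$class == "novel_hairpin", ]
  tags <- data.frame(sequence = nov$mature_seq,
                     count = seq(10L, by = 10L, length.out = nrow(nov)))
  aln <- map_tags(tags$sequence, idx)
  ann <- data.frame(tag = tags$sequence,
                    category = factor("unannotated",
                                      levels = annotation_categories()))
  cand <- extract_candidates(tags, aln, ann, idx)
  res <- predict_novel(cand)
  expect_equal(nrow(res), nrow(nov))
  expect_equal(res$id, sprintf("novel_miR_%d", seq_len(nrow(res))))
  expect_true(all(diff(res$count) <= 0))
  expect_true(all(res$mfe < -20))
  expect_equal(nrow(predict_novel(cand[0, ])), 0)
})
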