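test_that("identical configuration and seed give identical outputs", {
  cfg <- small_sim_config(seed = 601L)
  b1 <- build_toy_genome(cfg)
  b2 <- build_toy_genome(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$manifest$loci, b2$manifest$loci)
  s1 <- simulate_library(b1$genome, b1$manifest, "D")
  s2 <- simulate_library(b2$genome, b2$manifest, "D")
  expect_identical(s1$reads, s2$reads)
})

test_that("over-full genomes raise a capacity error", {
  cfg <- small_sim_config(seed = 602L)
  cfg$genome_length <- 2000L
  expect_error(build_toy_genome(cfg), "capacity")
})

test_that("artifact fractions are validated", {
  expect_error(simulation_config(frac_short = 0.7, frac_low_quality = 0.4),
               "sum below 1")
  expect_error(simulation_config(star_fraction = 0), "star_fraction")
})

test_that("planted hairpins pass and decoys fail their named criterion", {
  cfg <- small_sim_config(seed = 603L)
  built <- build_toy_genome(cfg)
  man <- built$manifest
  genome <- built$genome[["chr1"]]
  hp <- man$loci[man$loci$class %in% c("novel_hairpin", "decoy_hairpin"), ]
  for (i in seq_len(nrow(hp))) {
    sp <- if (hp$strand[i] == "+") {
      c(hp$start[i] + hp$mature_start[i] - 1L,
        hp$start[i] + hp$mature_end[i])
    } else {
      c(hp$end[i] - hp$mature_end[i], hp$end[i] - hp$mature_start[i] + 1L)
    }
    ws <- caprimir:::planted_windows(genome, sp[1], sp[2], hp$strand[i])
    evs <- lapply(ws, function(w)
      caprimir:::evaluate_candidate_window(w$seq, w$mature))
    if (hp$class[i] == "novel_hairpin") {
      expect_true(evs$tag5p$verdict$overall, label = hp$id[i])
    } else {
      named <- hp$violated[i]
      for (ev in evs) {
        expect_false(ev$verdict$overall, label = hp$id[i])
        expect_false(ev$verdict[[named]],
                     label = paste(hp$id[i], "criterion", named))
      }
    }
  }
})

test_that("category counts conserve the library total exactly", {
  cfg <- small_sim_config(seed = 604L)
  built <- build_toy_genome(cfg)
  for (cond in c("D", "P")) {
    sim <- simulate_library(built$genome, built$manifest, cond)
    expect_equal(sum(sim$qc_truth), cfg$reads_per_library)
    expect_equal(sum(sim$locus_truth$count), sim$qc_truth[["clean"]])
    expect_equal(nrow(sim$reads), cfg$reads_per_library)
  }
})

test_that("artifact and star rates land within binomial sampling error", {
  cfg <- small_sim_config(seed = 605L)
  cfg$frac_polyA <- 0.01
  built <- build_toy_genome(cfg)
  sim <- simulate_library(built$genome, built$manifest, "D")
  n <- cfg$reads_per_library
  expect_lt(abs(sim$qc_truth[["polyA"]] - n * 0.01),
            4 * sqrt(n * 0.01 * 0.99))
  lt <- sim$locus_truth[sim$locus_truth$class %in%
                          c("known_mirna", "novel_hairpin"), ]
  tot <- sum(lt$count)
  expect_lt(abs(sum(lt$star_count) - tot * cfg$star_fraction),
            4 * sqrt(tot * cfg$star_fraction * (1 - cfg$star_fraction)))
})

test_that("per-locus counts track their recorded expectations", {
  cfg <- small_sim_config(seed = 606L)
  built <- build_toy_genome(cfg)
  simD <- simulate_library(built$genome, built$manifest, "D")
  simP <- simulate_library(built$genome, built$manifest, "P")
  for (lt in list(simD$locus_truth, simP$locus_truth)) {
    big <- lt$expected >= 50
    z <- (lt$count[big] - lt$expected[big]) / sqrt(lt$expected[big])
    expect_lt(max(abs(z)), 5)
  }
  # planted fold changes shift the peak expectations in the right
  # direction (the multinomial design compresses, but preserves sign)
  fc <- built$manifest$loci$log2fc
  ratio <- simP$locus_truth$expected / simD$locus_truth$expected
  expect_true(all(ratio[fc > 0] > 1.9))
  expect_true(all(ratio[fc < 0] < 1 / 1.9))
  expect_lt(max(abs(log2(ratio[fc == 0]))), 1)
})

test_that("every emitted clean read classifies to its intended category", {
  cfg <- small_sim_config(seed = 607L)
  built <- build_toy_genome(cfg)
  sim <- simulate_library(built$genome, built$manifest, "D")
  cls <- classify_reads(sim$reads$sequence, cfg$adapter_3p, cfg$adapter_5p)
  lab <- vapply(strsplit(sim$reads$id, "|", fixed = TRUE), function(p) {
    if (p[[2]] == "artifact") p[[3]] else "clean"
  }, character(1))
  expect_equal(as.character(cls$category), lab)
})
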