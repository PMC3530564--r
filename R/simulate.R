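#' Configuration for the synthetic small-RNA study
#'
#' Defines the study conditions the generator emulates: a toy genome with
#' planted miRNA hairpins, decoy hairpins, structural non-coding RNA and
#' background loci, and two sequencing libraries (dry period "D" and peak
#' lactation "P") whose artifact rates mirror those reported for real
#' two-library small RNA sequencing runs (per-library defaults: ~0.5% low
#' quality, ~0.1% missing 3' adapter, ~0.1% missing insert, ~0.5% 5'
#' adapter contamination, ~4.3% sub-18-nt inserts, ~0.0025% polyA).
#'
#' @param seed integer seed; the same configuration and seed give
#'   byte-identical outputs.
#' @param genome_length toy genome length in nt.
#' @param n_known_mirnas,n_novel_hairpins,n_decoy_hairpins planted hairpin
#'   locus counts; decoys violate at least one named stem-loop criterion.
#' @param n_ncrna_loci loci per structural/feature class (rRNA, tRNA,
#'   snRNA, snoRNA, scRNA, srpRNA, repeat, exon, intron).
#' @param n_background_loci unannotated background loci (each emits one
#'   distinct tag).
#' @param reads_per_library reads simulated per library.
#' @param read_length sequencing read length in nt.
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param frac_low_quality,frac_no_adapter,frac_insert_null,frac_5p_contaminant,frac_polyA,frac_short
#'   artifact fractions of raw reads, each in [0, 1], summing below 1.
#' @param planted_log2fc named numeric vector of true log2 fold changes
#'   (peak over dry) keyed by locus id; NULL plants +2 on three known and
#'   two novel loci and -2 on three known and two novel loci.
#' @param star_fraction fraction of a hairpin locus' reads drawn from the
#'   passenger (star) arm.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 100000L,
                              n_known_mirnas = 30L, n_novel_hairpins = 10L,
                              n_decoy_hairpins = 10L, n_ncrna_loci = 3L,
                              n_background_loci = 400L,
                              reads_per_library = 200000L, read_length = 36L,
                              adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                              adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                              frac_low_quality = 0.005,
                              frac_no_adapter = 0.001,
                              frac_insert_null = 0.001,
                              frac_5p_contaminant = 0.005,
                              frac_polyA = 2.5e-5, frac_short = 0.043,
                              planted_log2fc = NULL, star_fraction = 0.05) {
  fr <- c(frac_low_quality, frac_no_adapter, frac_insert_null,
          frac_5p_contaminant, frac_polyA, frac_short)
  if (any(fr < 0 | fr > 1) || sum(fr) >= 1)
    stop("artifact fractions must lie in [0,1] and sum below 1")
  if (star_fraction <= 0 || star_fraction >= 1)
    stop("star_fraction must be in (0,1)")
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_hairpins = as.integer(n_novel_hairpins),
              n_decoy_hairpins = as.integer(n_decoy_hairpins),
              n_ncrna_loci = as.integer(n_ncrna_loci),
              n_background_loci = as.integer(n_background_loci),
              reads_per_library = as.integer(reads_per_library),
              read_length = as.integer(read_length),
              adapter_3p = adapter_3p, adapter_5p = adapter_5p,
              frac_low_quality = frac_low_quality,
              frac_no_adapter = frac_no_adapter,
              frac_insert_null = frac_insert_null,
              frac_5p_contaminant = frac_5p_contaminant,
              frac_polyA = frac_polyA, frac_short = frac_short,
              planted_log2fc = planted_log2fc,
              star_fraction = star_fraction)
  class(cfg) <- "sim_config"
  cfg
}

# length distribution of emitted inserts; mode 22 nt as in mammalian
# Dicer-product libraries
insert_length_probs <- function() {
  len <- 18:30
  p <- c(2, 3, 5, 8, 14, 8, 5, 3, 2, 1.5, 1, 0.8, 0.5)
  setNames(p / sum(p), len)
}

mature_length_probs <- function() {
  setNames(c(0.1, 0.2, 0.4, 0.2, 0.1), 20:24)
}

# is this insert safe to emit as a clean read?  It must trim back to
# itself and classify clean under the preprocessing rules.
insert_ok <- function(ins, cfg) {
  if (nchar(ins) < 18 || nchar(ins) > 30) return(FALSE)
  read <- substr(paste0(ins, cfg$adapter_3p), 1, cfg$read_length)
  cls <- classify_reads(read, cfg$adapter_3p, cfg$adapter_5p)
  cls$category[1] == "clean" && !is.na(cls$insert[1]) && cls$insert[1] == ins
}

# passenger arm: reverse complement of the mature with n_sub substitutions
# at interior positions.  Real miRNA/miRNA* duplexes carry mismatches; the
# substitutions also keep the mature from mapping to the star arm within
# the one-mismatch tolerance, so planted tags stay single-locus.
imperfect_star <- function(mature, n_sub = 2L) {
  star <- strsplit(revcomp(mature), "")[[1]]
  pos <- sample(3:(length(star) - 2L), n_sub)
  for (p in pos) {
    star[p] <- sample(setdiff(c("A", "C", "G", "T"), star[p]), 1)
  }
  paste(star, collapse = "")
}

random_clean_insert <- function(len, cfg, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (insert_ok(s, cfg)) return(s)
  }
  stop("could not draw a clean insert; adapter configuration too permissive")
}

#' Construct a hairpin precursor guaranteed to pass the seven criteria
#'
#' Builds mature + loop + reverse-complement star precursors and verifies
#' them with the prediction machinery itself ([fold_mfe()],
#' [extract_features()], [apply_criteria()]), retrying until the verdict
#' is all-pass.  The mature arm sits at the 5' end; its A+U content is
#' constrained to 35-65% so criterion 7 holds with margin.
#'
#' @param mature_length mature length in nt, between 20 and 24.
#' @param cfg a `sim_config` (adapters are needed to guarantee the mature
#'   and star arms survive read cleaning intact).
#' @param max_tries bounded retries before giving up.
#' @return list with `seq`, `mature`, `star`, `mature_start`,
#'   `mature_end`, `star_start`, `star_end` (1-based within `seq`).
#' @export
construct_passing_hairpin <- function(mature_length,
                                      cfg = simulation_config(),
                                      max_tries = 200L) {
  if (mature_length < 20 || mature_length > 24)
    stop("mature_length must be between 20 and 24 nt")
  m <- as.integer(mature_length)
  for (i in seq_len(max_tries)) {
    mat <- random_dna(m)
    au <- au_percent(mat)
    if (au < 35 || au > 65) next
    if (!insert_ok(mat, cfg)) next
    star <- imperfect_star(mat)
    if (!insert_ok(star, cfg)) next
    loop_len <- sample(max(9L, 55L - 2L * m):16L, 1)
    hp <- paste0(mat, random_dna(loop_len), star)
    ev <- evaluate_candidate_window(hp, c(1L, m))
    if (!ev$verdict$overall) next
    return(list(seq = hp, mature = mat, star = star,
                mature_start = 1L, mature_end = m,
                star_start = m + loop_len + 1L,
                star_end = 2L * m + loop_len))
  }
  stop("failed to construct a passing hairpin within retry budget")
}

# decoy hairpins: "au" violates criterion 7 by composition (mature A+U
# ~80%); "weak" has no complementary star arm, so no stable stem forms
# and criterion 3 fails
construct_decoy_hairpin <- function(type = c("au", "weak"),
                                    cfg = simulation_config(),
                                    max_tries = 200L) {
  type <- match.arg(type)
  for (i in seq_len(max_tries)) {
    m <- sample(20:24, 1)
    if (type == "au") {
      mat <- paste(sample(c("A", "T", "G", "C"), m, replace = TRUE,
                          prob = c(0.42, 0.42, 0.08, 0.08)), collapse = "")
      if (au_percent(mat) < 78) next
      if (!insert_ok(mat, cfg)) next
      loop_len <- sample(12:16, 1)
      hp <- paste0(mat, random_dna(loop_len), imperfect_star(mat))
      return(list(seq = hp, mature = mat, mature_start = 1L, mature_end = m,
                  violated = "c7"))
    } else {
      mat <- random_dna(m)
      au <- au_percent(mat)
      if (au < 35 || au > 65) next
      if (!insert_ok(mat, cfg)) next
      hp <- paste0(mat, random_dna(m + 14L))
      return(list(seq = hp, mature = mat, mature_start = 1L, mature_end = m,
                  violated = "c3"))
    }
  }
  stop("failed to construct a decoy hairpin within retry budget")
}

# the two candidate windows the prediction stage will excise for a tag
# planted at genome[start, end) on `strand` (0-based half-open)
planted_windows <- function(genome, start, end, strand, flank = 70L) {
  n <- nchar(genome)
  len <- end - start
  wins <- list()
  for (w in c("tag5p", "tag3p")) {
    downstream <- (w == "tag5p") == (strand == "+")
    if (downstream) {
      gs <- start; ge <- min(end + flank, n)
    } else {
      gs <- max(start - flank, 0L); ge <- end
    }
    seq <- substr(genome, gs + 1L, ge)
    if (strand == "-") seq <- revcomp(seq)
    if (w == "tag5p") { ms <- 1L; me <- len } else {
      me <- nchar(seq); ms <- me - len + 1L
    }
    wins[[w]] <- list(seq = seq, mature = c(ms, me), gs = gs, ge = ge)
  }
  wins
}

#' Build the toy genome and its ground-truth manifest
#'
#' Plants all configured loci at non-overlapping positions (random strand,
#' at least 80 nt apart so candidate windows never cross loci) in an
#' i.i.d. uniform background, then certifies the construction against the
#' pipeline itself: planted novel hairpins must pass the seven criteria in
#' the window the prediction stage will excise, decoys must fail both
#' windows including their named criterion (failing flanks are
#' regenerated), and every emitted insert must survive read cleaning
#' unchanged.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `genome` (named character, one chromosome `chr1`) and
#'   `manifest` (class `sim_manifest`): `loci` data.frame, `fragments`
#'   data.frame, `reference` (mature/hairpin named vectors), `features`
#'   data.frame, `log2fc` named vector, and the `config`.
#' @export
build_toy_genome <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  loci <- list()
  add_locus <- function(id, class, seq, mature = NA, star = NA,
                        mstart = NA, mend = NA, sstart = NA, send = NA,
                        mature_name = NA, star_name = NA, violated = NA) {
    loci[[length(loci) + 1L]] <<- data.frame(
      id = id, class = class, sequence = seq, length = nchar(seq),
      mature_seq = mature, star_seq = star,
      mature_start = mstart, mature_end = mend,
      star_start = sstart, star_end = send,
      mature_name = mature_name, star_name = star_name,
      violated = violated, stringsAsFactors = FALSE)
  }

  mature_ref <- character(0)
  for (i in seq_len(cfg$n_known_mirnas)) {
    m <- as.integer(sample(names(mature_length_probs()), 1,
                           prob = mature_length_probs()))
    hp <- construct_passing_hairpin(m, cfg)
    if (i <= ceiling(cfg$n_known_mirnas / 2)) {
      mname <- sprintf("sim-miR-%d", i)
      sname <- sprintf("sim-miR-%d*", i)
    } else {
      mname <- sprintf("sim-miR-%d-5p", i)
      sname <- sprintf("sim-miR-%d-3p", i)
    }
    add_locus(sprintf("kmir_%02d", i), "known_mirna", hp$seq, hp$mature,
              hp$star, hp$mature_start, hp$mature_end, hp$star_start,
              hp$star_end, mname, sname)
    mature_ref[mname] <- hp$mature
    mature_ref[sname] <- hp$star
  }
  for (i in seq_len(cfg$n_novel_hairpins)) {
    m <- as.integer(sample(names(mature_length_probs()), 1,
                           prob = mature_length_probs()))
    hp <- construct_passing_hairpin(m, cfg)
    add_locus(sprintf("novel_%02d", i), "novel_hairpin", hp$seq, hp$mature,
              hp$star, hp$mature_start, hp$mature_end, hp$star_start,
              hp$star_end)
  }
  for (i in seq_len(cfg$n_decoy_hairpins)) {
    type <- if (i %% 2 == 1) "au" else "weak"
    dc <- construct_decoy_hairpin(type, cfg)
    add_locus(sprintf("decoy_%02d", i), "decoy_hairpin", dc$seq, dc$mature,
              NA, dc$mature_start, dc$mature_end, violated = dc$violated)
  }
  frag_rows <- list()
  for (cls in feature_classes()) {
    for (i in seq_len(cfg$n_ncrna_loci)) {
      len <- sample(120:250, 1)
      seq <- random_dna(len)
      id <- sprintf("%s_%02d", cls, i)
      add_locus(id, cls, seq)
      lens <- as.integer(sample(names(insert_length_probs()), 8, replace = TRUE,
                                prob = insert_length_probs()))
      for (fl in lens) {
        for (tries in 1:50) {
          off <- sample.int(len - fl + 1L, 1)
          frag <- substr(seq, off, off + fl - 1L)
          if (insert_ok(frag, cfg)) break
          frag <- NA
        }
        if (is.na(frag)) frag <- random_clean_insert(fl, cfg)
        frag_rows[[length(frag_rows) + 1L]] <-
          data.frame(locus_id = id, sequence = frag, stringsAsFactors = FALSE)
      }
    }
  }
  bg_lens <- as.integer(sample(names(insert_length_probs()),
                               cfg$n_background_loci, replace = TRUE,
                               prob = insert_length_probs()))
  for (i in seq_len(cfg$n_background_loci)) {
    add_locus(sprintf("bg_%03d", i), "background",
              random_clean_insert(bg_lens[i], cfg))
  }

  loci <- do.call(rbind, loci)
  gap <- 80L
  need <- sum(loci$length) + gap * (nrow(loci) + 1L)
  if (need > cfg$genome_length)
    stop("planted loci exceed genome capacity (need ", need, " nt)")

  ord <- sample.int(nrow(loci))
  loci <- loci[ord, , drop = FALSE]
  extra <- cfg$genome_length - need
  bonus <- as.integer(rmultinom(1, extra, rep(1, nrow(loci) + 1L)))
  gaps <- gap + bonus
  loci$strand <- sample(c("+", "-"), nrow(loci), replace = TRUE)
  pieces <- character(2L * nrow(loci) + 1L)
  starts <- integer(nrow(loci))
  pos <- 0L
  for (i in seq_len(nrow(loci))) {
    pieces[2L * i - 1L] <- random_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos
    emb <- loci$sequence[i]
    if (loci$strand[i] == "-") emb <- revcomp(emb)
    pieces[2L * i] <- emb
    pos <- pos + loci$length[i]
  }
  pieces[2L * nrow(loci) + 1L] <- random_dna(gaps[nrow(loci) + 1L])
  genome <- paste(pieces, collapse = "")
  loci$start <- starts
  loci$end <- starts + loci$length

  # certify hairpin loci against the prediction machinery; regenerate
  # flanks when the surrounding background spoils the intended verdict
  redraw_flank <- function(genome, gs, ge) {
    before <- substr(genome, 1, gs)
    after <- substr(genome, ge + 1L, nchar(genome))
    paste0(before, random_dna(ge - gs), after)
  }
  tag_span <- function(i) {
    # genomic span of the mature tag within locus i
    if (loci$strand[i] == "+") {
      c(loci$start[i] + loci$mature_start[i] - 1L,
        loci$start[i] + loci$mature_end[i])
    } else {
      c(loci$end[i] - loci$mature_end[i], loci$end[i] - loci$mature_start[i] + 1L)
    }
  }
  for (i in which(loci$class == "novel_hairpin")) {
    sp <- tag_span(i)
    for (tries in 1:60) {
      w <- planted_windows(genome, sp[1], sp[2], loci$strand[i])$tag5p
      ev <- evaluate_candidate_window(w$seq, w$mature)
      if (ev$verdict$overall) break
      genome <- redraw_flank(genome,
                             max(w$gs, loci$end[i]),
                             min(w$ge, nchar(genome)))
      if (tries == 60) stop("could not certify a planted novel hairpin")
    }
  }
  for (i in which(loci$class == "decoy_hairpin")) {
    sp <- tag_span(i)
    for (tries in 1:60) {
      ws <- planted_windows(genome, sp[1], sp[2], loci$strand[i])
      evs <- lapply(ws, function(w) evaluate_candidate_window(w$seq, w$mature))
      named <- loci$violated[i]
      ok <- all(vapply(evs, function(e) !e$verdict$overall, logical(1))) &&
        all(vapply(evs, function(e) !e$verdict[[named]], logical(1)))
      if (ok) break
      # regenerate everything the windows see except the mature itself
      # (the decoy tail is never emitted as reads, so it may change)
      for (w in ws) {
        fs <- if (w$gs < sp[1]) c(w$gs, sp[1]) else c(sp[2], w$ge)
        if (fs[2] > fs[1]) genome <- redraw_flank(genome, fs[1], fs[2])
      }
      if (tries == 60) stop("could not certify a planted decoy hairpin")
    }
    emb <- substr(genome, loci$start[i] + 1L, loci$end[i])
    loci$sequence[i] <- if (loci$strand[i] == "-") revcomp(emb) else emb
  }

  # planted hairpin tags must be single-locus under the mapping tolerance
  index_chk <- build_index(c(chr1 = genome))
  for (i in which(loci$class %in% c("novel_hairpin", "decoy_hairpin"))) {
    for (s in c(loci$mature_seq[i], loci$star_seq[i])) {
      if (is.na(s)) next
      if (classify_mapping(map_tag(s, index_chk))$status != "unique")
        stop("planted hairpin tag is not single-locus; change the seed")
    }
  }

  # per-locus base abundance weights, shared by both conditions
  w <- numeric(nrow(loci))
  w[loci$class == "known_mirna"] <- rlnorm(sum(loci$class == "known_mirna"),
                                           log(2000), 0.6)
  w[loci$class %in% feature_classes()] <-
    rlnorm(sum(loci$class %in% feature_classes()), log(1400), 0.5)
  w[loci$class == "novel_hairpin"] <- rlnorm(sum(loci$class == "novel_hairpin"),
                                             log(120), 0.3)
  w[loci$class == "decoy_hairpin"] <- rlnorm(sum(loci$class == "decoy_hairpin"),
                                             log(80), 0.3)
  w[loci$class == "background"] <- rlnorm(sum(loci$class == "background"),
                                          log(70), 1.0)
  loci$base_weight <- w

  lfc <- cfg$planted_log2fc
  if (is.null(lfc)) {
    up <- c(loci$id[loci$class == "known_mirna"][1:3],
            loci$id[loci$class == "novel_hairpin"][1:2])
    dn <- c(loci$id[loci$class == "known_mirna"][4:6],
            loci$id[loci$class == "novel_hairpin"][3:4])
    lfc <- setNames(c(rep(2, length(up)), rep(-2, length(dn))), c(up, dn))
  }
  loci$log2fc <- ifelse(is.na(match(loci$id, names(lfc))), 0,
                        lfc[match(loci$id, names(lfc))])

  fragments <- do.call(rbind, frag_rows)
  hp_idx <- loci$class == "known_mirna"
  reference <- list(
    mature = mature_ref,
    hairpin = setNames(loci$sequence[hp_idx],
                       sub("-miR-", "-mir-",
                           sub("(-5p|\\*)$", "", loci$mature_name[hp_idx]))))
  fclass <- loci$class %in% feature_classes()
  features <- data.frame(chrom = "chr1", start = loci$start[fclass],
                         end = loci$end[fclass], strand = loci$strand[fclass],
                         class = loci$class[fclass], name = loci$id[fclass],
                         stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  manifest <- structure(
    list(loci = loci, fragments = fragments, reference = reference,
         features = features, log2fc = lfc, config = cfg),
    class = "sim_manifest")
  list(genome = c(chr1 = genome), manifest = manifest)
}

#' Simulate one sequencing library from the toy genome
#'
#' Read counts follow a multinomial over artifact classes and planted loci
#' (the conditional of independent Poisson locus counts given the library
#' total, so per-category counts sum exactly to `reads_per_library`).
#' Hairpin loci split their reads between the mature and star arms at
#' `star_fraction`; condition "P" scales each locus weight by
#' `2^log2fc`.  Every read is emitted as insert + 3' adapter truncated to
#' the read length; artifact reads are constructed so the cleaning stage
#' recovers the intended category deterministically.
#'
#' @param genome named character vector from [build_toy_genome()].
#' @param manifest the matching `sim_manifest`.
#' @param condition "D" (dry, baseline weights) or "P" (peak,
#'   fold-change-scaled weights).
#' @param config optional override of the manifest's `sim_config`.
#' @return list with `reads` (data.frame `id`, `sequence`), `qc_truth`
#'   (named counts per cleaning category), `locus_truth` (data.frame
#'   `locus_id`, `class`, `count`, `star_count`).
#' @export
simulate_library <- function(genome, manifest, condition = c("D", "P"),
                             config = manifest$config) {
  condition <- match.arg(condition)
  cfg <- config
  set.seed(cfg$seed * 13L + ifelse(condition == "D", 1L, 2L))
  loci <- manifest$loci
  n <- cfg$reads_per_library
  art_p <- c(low_quality = cfg$frac_low_quality,
             adapter3_null = cfg$frac_no_adapter,
             insert_null = cfg$frac_insert_null,
             adapter5_contaminant = cfg$frac_5p_contaminant,
             polyA = cfg$frac_polyA, too_short = cfg$frac_short)
  wt <- loci$base_weight
  if (condition == "P") wt <- wt * 2^loci$log2fc
  p <- c(art_p, (1 - sum(art_p)) * wt / sum(wt))
  counts <- as.integer(rmultinom(1, n, p))
  art_counts <- setNames(counts[seq_along(art_p)], names(art_p))
  locus_counts <- counts[-seq_along(art_p)]

  is_hp <- loci$class %in% c("known_mirna", "novel_hairpin")
  star_counts <- integer(nrow(loci))
  star_counts[is_hp] <- rbinom(sum(is_hp), locus_counts[is_hp],
                               cfg$star_fraction)

  inserts <- character(0)
  src <- character(0)
  for (i in seq_len(nrow(loci))) {
    ci <- locus_counts[i]
    if (ci == 0) next
    si <- star_counts[i]
    cls <- loci$class[i]
    if (cls %in% c("known_mirna", "novel_hairpin", "decoy_hairpin")) {
      ins <- c(rep(loci$mature_seq[i], ci - si), rep(loci$star_seq[i], si))
      arm <- c(rep("mature", ci - si), rep("star", si))
    } else if (cls == "background") {
      ins <- rep(loci$sequence[i], ci)
      arm <- rep("na", ci)
    } else {
      frags <- manifest$fragments$sequence[manifest$fragments$locus_id ==
                                             loci$id[i]]
      ins <- sample(frags, ci, replace = TRUE)
      arm <- rep("na", ci)
    }
    inserts <- c(inserts, ins)
    src <- c(src, paste0(loci$id[i], "|", cls, "|", arm))
  }

  make_read <- function(ins) substr(paste0(ins, cfg$adapter_3p), 1,
                                    cfg$read_length)
  reads <- make_read(inserts)

  tail5 <- substr(cfg$adapter_5p, nchar(cfg$adapter_5p) - 7L,
                  nchar(cfg$adapter_5p))
  gen_artifact <- function(class, k) {
    if (k == 0) return(character(0))
    out <- character(k)
    for (j in seq_len(k)) {
      for (tries in 1:100) {
        r <- switch(class,
          low_quality = {
            ins <- random_clean_insert(22L, cfg)
            r0 <- make_read(ins)
            pos <- sample.int(nchar(r0), 1)
            paste0(substr(r0, 1, pos - 1L), "N",
                   substr(r0, pos + 1L, nchar(r0)))
          },
          adapter3_null = random_dna(cfg$read_length),
          insert_null = substr(paste0(cfg$adapter_3p,
                                      random_dna(cfg$read_length)), 1,
                               cfg$read_length),
          adapter5_contaminant = make_read(paste0(tail5, random_dna(14L))),
          polyA = make_read(strrep("A", 22L)),
          too_short = make_read(random_dna(sample(10:17, 1))))
        cls <- classify_reads(r, cfg$adapter_3p, cfg$adapter_5p)$category[1]
        if (as.character(cls) == class) { out[j] <- r; break }
        if (tries == 100) stop("could not construct artifact read: ", class)
      }
    }
    out
  }
  for (a in names(art_counts)) {
    ar <- gen_artifact(a, art_counts[[a]])
    reads <- c(reads, ar)
    src <- c(src, rep(paste0("artifact|", a, "|na"), length(ar)))
  }

  ord <- sample.int(length(reads))
  reads <- reads[ord]
  src <- src[ord]
  ids <- sprintf("sim%s_%06d|%s", condition, seq_along(reads), src)

  qc_truth <- c(art_counts, clean = sum(locus_counts))
  # expected counts under the realised sampling design (fixed library
  # total, so planted fold changes are compressed by the weight-sum ratio)
  expected <- n * p[-seq_along(art_p)]
  locus_truth <- data.frame(locus_id = loci$id, class = loci$class,
                            count = locus_counts, star_count = star_counts,
                            expected = expected, stringsAsFactors = FALSE)
  list(reads = data.frame(id = ids, sequence = reads,
                          stringsAsFactors = FALSE),
       qc_truth = qc_truth, locus_truth = locus_truth)
}

#' Write the complete synthetic dataset to disk
#'
#' Produces genome FASTA, per-condition FASTQ (constant Sanger qualities),
#' a miRBase-flavour mature/hairpin FASTA pair, a feature BED (class in
#' the name field), and manifest TSVs.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if missing).
#' @return invisibly, a list with all file paths plus the in-memory
#'   `manifest` and per-condition truth tables.
#' @export
write_synthetic_dataset <- function(config = simulation_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  built <- build_toy_genome(config)
  genome <- built$genome
  manifest <- built$manifest
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    reads_D = file.path(dir, "reads_D.fastq"),
    reads_P = file.path(dir, "reads_P.fastq"),
    mature = file.path(dir, "mature.fa"),
    hairpin = file.path(dir, "hairpin.fa"),
    features = file.path(dir, "features.bed"),
    loci = file.path(dir, "manifest_loci.tsv"))
  gset <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(gset, paths$genome)
  libs <- list()
  for (cond in c("D", "P")) {
    sim <- simulate_library(genome, manifest, cond)
    libs[[cond]] <- sim
    set <- Biostrings::DNAStringSet(sim$reads$sequence)
    names(set) <- sim$reads$id
    qual <- Biostrings::BStringSet(strrep("I", nchar(sim$reads$sequence)))
    Biostrings::writeXStringSet(set, paths[[paste0("reads_", cond)]],
                                format = "fastq", qualities = qual)
  }
  write_mirna_fasta(manifest$reference$mature, paths$mature, "SIMMAT")
  write_mirna_fasta(manifest$reference$hairpin, paths$hairpin, "SIMHP")
  fb <- manifest$features
  bed <- data.frame(fb$chrom, fb$start, fb$end, fb$class, 0L, fb$strand)
  write.table(bed, paths$features, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(manifest$loci[, c("id", "class", "start", "end", "strand",
                                "length", "log2fc")],
              paths$loci, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(manifest = manifest, libraries = libs)))
}
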