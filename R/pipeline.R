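#' Library-overlap summary between two tag tables
#'
#' Splits the two libraries' reads into tags common to both, specific to
#' the first, and specific to the second, reporting percentages over
#' total reads and the common fraction of unique tags.
#'
#' @param tags_a,tags_b data.frames with `sequence` and `count`.
#' @return list with `common_total_pct`, `a_specific_total_pct`,
#'   `b_specific_total_pct` (percent of summed reads; they sum to 100) and
#'   `common_unique_pct` (percent of the unique-tag union).
#' @export
overlap_summary <- function(tags_a, tags_b) {
  common <- intersect(tags_a$sequence, tags_b$sequence)
  tot <- sum(tags_a$count) + sum(tags_b$count)
  if (tot == 0) {
    return(list(common_total_pct = 0, a_specific_total_pct = 0,
                b_specific_total_pct = 0, common_unique_pct = 0))
  }
  in_a <- tags_a$sequence %in% common
  in_b <- tags_b$sequence %in% common
  common_reads <- sum(tags_a$count[in_a]) + sum(tags_b$count[in_b])
  a_spec <- sum(tags_a$count[!in_a])
  b_spec <- sum(tags_b$count[!in_b])
  uni <- length(union(tags_a$sequence, tags_b$sequence))
  list(common_total_pct = 100 * common_reads / tot,
       a_specific_total_pct = 100 * a_spec / tot,
       b_specific_total_pct = 100 * b_spec / tot,
       common_unique_pct = if (uni > 0) 100 * length(common) / uni else 0)
}

#' Configuration for an end-to-end pipeline run
#'
#' All thresholds default to the published workflow's values: one mapping
#' mismatch, minimum tag count 5 for novel prediction, the seven criteria
#' bounds of [criteria_bounds()], and the significance gates |log2 fold
#' change| > 1 with p < 0.01.
#'
#' @param reads_D,reads_P FASTQ/FASTA paths for the two libraries.
#' @param genome genome FASTA path (or sequences).
#' @param mature_fa,hairpin_fa known-miRNA reference FASTA paths.
#' @param features feature BED/GFF path, a `GRanges`, or NULL.
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param max_mismatch mapping mismatch tolerance.
#' @param min_novel_count minimum pooled tag count for novel candidates.
#' @param bounds seven-criteria bounds.
#' @param fc_gate,p_gate significance gates.
#' @param outdir output directory for report TSVs, or NULL to skip
#'   writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads_D, reads_P, genome, mature_fa, hairpin_fa,
                            features = NULL,
                            adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                            adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                            max_mismatch = 1L, min_novel_count = 5L,
                            bounds = criteria_bounds(), fc_gate = 1,
                            p_gate = 0.01, outdir = NULL) {
  for (p in c(reads_D, reads_P)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("input file does not exist: ", p)
  }
  if (is.character(genome) && length(genome) == 1 &&
      !grepl("^[ACGTNacgtn]+$", genome) && !file.exists(genome))
    stop("genome file does not exist: ", genome)
  structure(list(reads_D = reads_D, reads_P = reads_P, genome = genome,
                 mature_fa = mature_fa, hairpin_fa = hairpin_fa,
                 features = features, adapter_3p = adapter_3p,
                 adapter_5p = adapter_5p,
                 max_mismatch = as.integer(max_mismatch),
                 min_novel_count = as.integer(min_novel_count),
                 bounds = bounds, fc_gate = fc_gate, p_gate = p_gate,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the complete two-library small-RNA pipeline
#'
#' Cleans both libraries, maps the pooled unique tags with one-mismatch
#' tolerance, annotates them hierarchically, quantifies conserved miRNAs
#' against the reference, predicts novel miRNAs from unannotated
#' uniquely-mapping tags with pooled count >= 5, and computes the
#' two-library differential expression table for conserved and novel
#' miRNAs together with the library overlap summary.  When `outdir` is
#' set, all stage reports are written as TSV.
#'
#' @param config a `pipeline_config`.
#' @return list with components `qc` (per-library `library_qc`), `tags`
#'   (per-library tag tables), `length_dist`, `alignments`, `annotations`,
#'   `category_summary` (per library), `known` (per-library count tables),
#'   `known_matches`, `novel`, `diffexp`, `overlap` and `log` (character
#'   vector of stage messages).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  cleaned <- list()
  for (cond in c("D", "P")) {
    res <- clean_library(cfg[[paste0("reads_", cond)]], cfg$adapter_3p,
                         cfg$adapter_5p)
    cleaned[[cond]] <- res
    say("library %s: %d raw reads, %d clean (%d unique tags)", cond,
        res$report$reads[res$report$category == "raw_reads"],
        res$report$reads[res$report$category == "clean_reads"],
        nrow(res$tags))
  }
  tags_D <- cleaned$D$tags
  tags_P <- cleaned$P$tags

  pooled <- merge(tags_D, tags_P, by = "sequence", all = TRUE,
                  suffixes = c("_D", "_P"))
  pooled[is.na(pooled)] <- 0L
  pooled$count <- pooled$count_D + pooled$count_P
  pooled_tags <- pooled[, c("sequence", "count")]

  index <- build_index(cfg$genome)
  alignments <- map_tags(pooled_tags$sequence, index, cfg$max_mismatch)
  n_mapped <- length(unique(alignments$tag))
  say("mapped %d / %d unique tags (<=%d mismatch)", n_mapped,
      nrow(pooled_tags), cfg$max_mismatch)

  reference <- read_mirbase(cfg$mature_fa, cfg$hairpin_fa)
  matches <- match_conserved_all(pooled_tags$sequence, reference)
  say("%d unique tags matched %d known miRNAs", nrow(matches),
      length(unique(matches$mirna)))

  features <- cfg$features
  if (is.character(features)) features <- read_features(features)
  annotations <- annotate_tags(alignments, features, matches$tag)
  category_summary <- list(
    D = summarize_categories(annotations, tags_D),
    P = summarize_categories(annotations, tags_P))

  known <- list(
    D = count_table(matches, tags_D),
    P = count_table(matches, tags_P))

  candidates <- extract_candidates(pooled_tags, alignments, annotations,
                                   index, cfg$min_novel_count)
  novel <- predict_novel(candidates, list(D = tags_D, P = tags_P),
                         bounds = cfg$bounds)
  say("novel prediction: %d candidate windows, %d predicted hairpins",
      nrow(candidates), nrow(novel))

  N1 <- sum(tags_D$count)
  N2 <- sum(tags_P$count)
  counts_named <- function(kt, novel, lib) {
    kn <- setNames(kt$total_reads, kt$mirna)
    if (nrow(novel)) {
      nv <- setNames(novel[[paste0("count_", lib)]], novel$id)
      kn <- c(kn, nv)
    }
    kn
  }
  de <- diff_table(counts_named(known$D, novel, "D"),
                   counts_named(known$P, novel, "P"), N1 = N1, N2 = N2,
                   fc_gate = cfg$fc_gate, p_gate = cfg$p_gate)
  s <- attr(de, "summary")
  say("differential expression: %d up, %d down of %d tested", s$up, s$down,
      s$tested)

  overlap <- overlap_summary(tags_D, tags_P)
  ld <- list(D = length_distribution(tags_D), P = length_distribution(tags_P))

  out <- list(qc = list(D = cleaned$D$report, P = cleaned$P$report),
              tags = list(D = tags_D, P = tags_P), length_dist = ld,
              alignments = alignments, annotations = annotations,
              category_summary = category_summary, known = known,
              known_matches = matches, novel = novel, diffexp = de,
              overlap = overlap, log = log)
  if (!is.null(cfg$outdir)) write_pipeline_reports(out, cfg$outdir)
  out
}

write_pipeline_reports <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_qc_tsv(res$qc$D, file.path(outdir, "qc_D.tsv"))
  write_qc_tsv(res$qc$P, file.path(outdir, "qc_P.tsv"))
  for (cond in c("D", "P")) {
    write.table(res$category_summary[[cond]],
                file.path(outdir, sprintf("categories_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$known[[cond]],
                file.path(outdir, sprintf("known_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$length_dist[[cond]],
                file.path(outdir, sprintf("length_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(res$novel[, setdiff(names(res$novel), "dot_bracket")],
              file.path(outdir, "novel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(res$novel))
    write_structures(res$novel, file.path(outdir, "novel_structures.txt"))
  write_diffexp_tsv(res$diffexp, file.path(outdir, "diffexp.tsv"))
  write.table(as.data.frame(res$overlap), file.path(outdir, "overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
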