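#' Default bounds for the seven stem-loop criteria
#'
#' The seven filters a candidate hairpin must pass: (1) at least
#' `min_stem_pairs` base pairs in the stem; (2) no single-side unpaired run
#' (bulge) in the stem longer than `max_bulge` nt; (3) folding free energy
#' strictly below `max_mfe` kcal/mol; (4) at least `min_mature_in_stem`
#' percent of the mature bases paired; (5) hairpin (stem + terminal loop)
#' span at least `min_hairpin_len` nt; (6) terminal loop at most `max_loop`
#' nt; (7) mature A+U percentage within `au_range`.
#'
#' @return named list of bounds.
#' @export
criteria_bounds <- function() {
  list(min_stem_pairs = 18L, max_bulge = 18L, max_mfe = -20,
       min_mature_in_stem = 80, min_hairpin_len = 53L, max_loop = 22L,
       au_range = c(30, 70))
}

#' Excise candidate precursor windows for novel-miRNA prediction
#'
#' Keeps tags that are unannotated, map to a single locus, and carry at
#' least `min_count` reads, then excises two strand-aware genomic windows
#' per tag: the tag at the 5' end with `flank` nt of downstream sequence,
#' and the tag at the 3' end with `flank` nt upstream (clipped at
#' chromosome ends; identical windows are merged).
#'
#' @param tags data.frame with `sequence` and `count` (counts pooled over
#'   libraries).
#' @param alignments data.frame from [map_tags()] covering these tags.
#' @param annotations data.frame from [annotate_tags()].
#' @param genome a `genome_index` (or anything [build_index()] accepts).
#' @param min_count minimum read count (default 5).
#' @param flank flank length in nt (default 70).
#' @return data.frame with one row per candidate window: `tag`, `count`,
#'   `chrom`, `start`, `end`, `strand`, `window` ("tag5p"/"tag3p"),
#'   `win_seq`, `mature_start`, `mature_end` (1-based in window).
#' @export
extract_candidates <- function(tags, alignments, annotations, genome,
                               min_count = 5L, flank = 70L) {
  if (!inherits(genome, "genome_index")) genome <- build_index(genome)
  unann <- annotations$tag[annotations$category == "unannotated"]
  keep <- tags$sequence %in% unann & tags$count >= min_count
  out <- list()
  for (tg in tags$sequence[keep]) {
    al <- alignments[alignments$tag == tg, , drop = FALSE]
    cls <- classify_mapping(al)
    if (cls$status != "unique") next
    al <- al[1, , drop = FALSE]
    chrlen <- nchar(as.character(genome$seqs[[al$chrom]]))
    len <- al$end - al$start
    cnt <- tags$count[tags$sequence == tg]
    for (w in c("tag5p", "tag3p")) {
      # genomic span of the window, honouring the tag's strand
      downstream <- (w == "tag5p") == (al$strand == "+")
      if (downstream) {
        gs <- al$start; ge <- min(al$end + flank, chrlen)
      } else {
        gs <- max(al$start - flank, 0L); ge <- al$end
      }
      seq <- substr(as.character(genome$seqs[[al$chrom]]), gs + 1L, ge)
      if (al$strand == "-") seq <- revcomp(seq)
      if (w == "tag5p") {
        ms <- 1L; me <- len
      } else {
        me <- nchar(seq); ms <- me - len + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        tag = tg, count = cnt, chrom = al$chrom, start = gs, end = ge,
        strand = al$strand, window = w, win_seq = seq,
        mature_start = ms, mature_end = me, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tag = character(0), count = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      window = character(0), win_seq = character(0),
                      mature_start = integer(0), mature_end = integer(0))
  res <- res[!duplicated(res[, c("tag", "chrom", "start", "end", "strand")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Derive hairpin features from a folded candidate window
#'
#' @param structure a `hairpin_structure` from [fold_mfe()].
#' @param mature_span integer vector `c(start, end)` of the mature tag
#'   within the window (1-based, inclusive).
#' @return a list of class `hairpin_features`: `n_stem_pairs`,
#'   `loop_length`, `max_bulge`, `hairpin_length`, `mature_in_stem_pct`,
#'   `mature_AU_pct`, `mfe`.  A pairless structure yields zero stem pairs
#'   and NA loop/length so that all structural criteria fail downstream.
#' @export
extract_features <- function(structure, mature_span) {
  stopifnot(inherits(structure, "hairpin_structure"), length(mature_span) == 2)
  p <- structure$pairs
  ms <- mature_span[1]; me <- mature_span[2]
  mat_seq <- substr(structure$sequence, ms, me)
  au <- au_percent(chartr("U", "T", mat_seq))
  np <- nrow(p)
  if (np == 0) {
    feats <- list(n_stem_pairs = 0L, loop_length = NA_integer_,
                  max_bulge = NA_integer_, hairpin_length = NA_integer_,
                  mature_in_stem_pct = 0, mature_AU_pct = au,
                  mfe = structure$mfe)
    class(feats) <- "hairpin_features"
    return(feats)
  }
  p <- p[order(p[, 1]), , drop = FALSE]
  loop_len <- p[np, 2] - p[np, 1] - 1L
  hp_len <- p[1, 2] - p[1, 1] + 1L
  max_bulge <- 0L
  if (np > 1) {
    g1 <- p[-1, 1] - p[-np, 1] - 1L
    g2 <- p[-np, 2] - p[-1, 2] - 1L
    max_bulge <- max(pmax(g1, g2))
  }
  paired <- c(p[, 1], p[, 2])
  mat_pos <- ms:me
  in_stem <- 100 * sum(mat_pos %in% paired) / length(mat_pos)
  feats <- list(n_stem_pairs = np, loop_length = as.integer(loop_len),
                max_bulge = as.integer(max_bulge),
                hairpin_length = as.integer(hp_len),
                mature_in_stem_pct = in_stem, mature_AU_pct = au,
                mfe = structure$mfe)
  class(feats) <- "hairpin_features"
  feats
}

#' Apply the seven stem-loop criteria to hairpin features
#'
#' @param features a `hairpin_features` list from [extract_features()].
#' @param bounds criteria bounds, see [criteria_bounds()].
#' @return list with logicals `c1`..`c7` and `overall` (their conjunction).
#' @export
apply_criteria <- function(features, bounds = criteria_bounds()) {
  f <- features
  v <- list(
    c1 = isTRUE(f$n_stem_pairs >= bounds$min_stem_pairs),
    c2 = isTRUE(!is.na(f$max_bulge) && f$max_bulge <= bounds$max_bulge),
    c3 = isTRUE(f$mfe < bounds$max_mfe),
    c4 = isTRUE(f$mature_in_stem_pct >= bounds$min_mature_in_stem),
    c5 = isTRUE(!is.na(f$hairpin_length) &&
                  f$hairpin_length >= bounds$min_hairpin_len),
    c6 = isTRUE(!is.na(f$loop_length) && f$loop_length <= bounds$max_loop),
    c7 = isTRUE(f$mature_AU_pct >= bounds$au_range[1] &&
                  f$mature_AU_pct <= bounds$au_range[2])
  )
  v$overall <- all(unlist(v))
  v
}

# fold + features + criteria for one candidate window
evaluate_candidate_window <- function(win_seq, mature_span,
                                      params = fold_params(),
                                      bounds = criteria_bounds()) {
  st <- fold_mfe(win_seq, params)
  feats <- extract_features(st, mature_span)
  verdict <- apply_criteria(feats, bounds)
  list(structure = st, features = feats, verdict = verdict)
}

#' Predict novel miRNAs from candidate windows
#'
#' Folds each candidate window, derives features and applies the seven
#' criteria.  When both windows of a tag pass, the lower-MFE window wins.
#' Passing candidates are assigned ids `novel_miR_1..n` in order of
#' decreasing total read count.
#'
#' @param candidates data.frame from [extract_candidates()].
#' @param library_tags optional named list of per-library tag data.frames
#'   (`sequence`, `count`) used to report per-library counts.
#' @param params folding parameters ([fold_params()]).
#' @param bounds criteria bounds ([criteria_bounds()]).
#' @return data.frame with one row per predicted novel miRNA: `id`, `tag`,
#'   `chrom`, `start`, `end`, `strand`, `mature`, `precursor`,
#'   `dot_bracket`, `mfe`, feature columns, `count` and one
#'   `count_<library>` column per supplied library.
#' @export
predict_novel <- function(candidates, library_tags = NULL,
                          params = fold_params(), bounds = criteria_bounds()) {
  empty <- data.frame(id = character(0), tag = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mature = character(0), precursor = character(0),
                      prec_start = integer(0), prec_end = integer(0),
                      dot_bracket = character(0), mfe = numeric(0),
                      n_stem_pairs = integer(0), loop_length = integer(0),
                      max_bulge = integer(0), hairpin_length = integer(0),
                      mature_in_stem_pct = numeric(0),
                      mature_AU_pct = numeric(0), count = integer(0))
  if (nrow(candidates) == 0) return(empty)
  rows <- list()
  for (tg in unique(candidates$tag)) {
    cand <- candidates[candidates$tag == tg, , drop = FALSE]
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      ev <- evaluate_candidate_window(
        cand$win_seq[r], c(cand$mature_start[r], cand$mature_end[r]),
        params, bounds)
      if (!ev$verdict$overall) next
      if (is.null(best) || ev$structure$mfe < best$ev$structure$mfe)
        best <- list(row = cand[r, , drop = FALSE], ev = ev)
    }
    if (is.null(best)) next
    st <- best$ev$structure; f <- best$ev$features; rw <- best$row
    p <- st$pairs[order(st$pairs[, 1]), , drop = FALSE]
    prec <- substr(st$sequence, p[1, 1], p[1, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      tag = rw$tag, chrom = rw$chrom, start = rw$start, end = rw$end,
      strand = rw$strand,
      mature = substr(st$sequence, rw$mature_start, rw$mature_end),
      precursor = prec, prec_start = p[1, 1], prec_end = p[1, 2],
      dot_bracket = st$dot_bracket, mfe = st$mfe,
      n_stem_pairs = f$n_stem_pairs, loop_length = f$loop_length,
      max_bulge = f$max_bulge, hairpin_length = f$hairpin_length,
      mature_in_stem_pct = f$mature_in_stem_pct,
      mature_AU_pct = f$mature_AU_pct, count = rw$count,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$count, out$tag), , drop = FALSE]
  out <- cbind(id = sprintf("novel_miR_%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  if (!is.null(library_tags)) {
    for (lib in names(library_tags)) {
      lt <- library_tags[[lib]]
      cnt <- lt$count[match(out$tag, lt$sequence)]
      cnt[is.na(cnt)] <- 0L
      out[[paste0("count_", lib)]] <- cnt
    }
  }
  rownames(out) <- NULL
  out
}

#' Write predicted precursor structures in Vienna dot-bracket format
#'
#' @param novel data.frame from [predict_novel()].
#' @param path output path.
#' @export
write_structures <- function(novel, path) {
  lines <- unlist(lapply(seq_len(nrow(novel)), function(i) c(
    paste0(">", novel$id[i]),
    novel$precursor[i],
    sprintf("%s (%.2f)",
            substr(novel$dot_bracket[i], novel$prec_start[i],
                   novel$prec_end[i]),
            novel$mfe[i]))))
  writeLines(lines, path)
  invisible(path)
}
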