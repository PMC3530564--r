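#' Load a miRBase-flavour mature/hairpin reference
#'
#' Accepts mature and hairpin FASTA files with `>name accession` headers
#' (U or T; normalised to DNA internally).  Each mature is located inside
#' its precursor: precursors are matched by name (case-insensitive, with
#' the `-5p`/`-3p`/`*` suffix stripped and miR/mir equated), with a
#' substring search as fallback; matures that cannot be placed are dropped
#' with a warning.
#'
#' @param mature_fa,hairpin_fa FASTA paths (or named character vectors of
#'   sequences for programmatic use).
#' @return an object of class `mirna_reference`: a list with `precursors`
#'   (named character) and `matures` (data.frame `name`, `sequence`,
#'   `precursor`, `start`, `end` (1-based, within precursor), `arm`).
#' @export
read_mirbase <- function(mature_fa, hairpin_fa) {
  load_fa <- function(x) {
    if (length(x) == 1 && file.exists(x) && !grepl("^[ACGTUacgtu]+$", x)) {
      # miRBase ships RNA-alphabet FASTA; read untyped, normalise below
      set <- Biostrings::readBStringSet(x)
      x <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
    }
    setNames(vapply(x, normalize_dna, character(1)), names(x))
  }
  mat <- load_fa(mature_fa)
  hp <- load_fa(hairpin_fa)
  base_key <- function(n) tolower(sub("[*]$", "", sub("-[35]p$", "", n)))
  hp_key <- base_key(names(hp))
  rows <- lapply(seq_along(mat), function(i) {
    name <- names(mat)[i]
    seq <- mat[[i]]
    cand <- which(hp_key == base_key(name))
    if (!length(cand)) cand <- seq_along(hp)
    for (j in cand) {
      pos <- regexpr(seq, hp[[j]], fixed = TRUE)
      if (pos > 0) {
        return(data.frame(name = name, sequence = seq,
                          precursor = names(hp)[j],
                          start = as.integer(pos),
                          end = as.integer(pos) + nchar(seq) - 1L,
                          arm = assign_arm(name), stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " mature sequence(s) not found in any precursor; dropped")
  matures <- do.call(rbind, rows)
  structure(list(precursors = hp, matures = matures), class = "mirna_reference")
}

#' Assign the arm category from a mature miRNA name
#'
#' Names ending in `*` are passenger strands; `-5p`/`-3p` carry the arm of
#' origin; anything else is reported as the plain guide `miRNA` category.
#'
#' @param name mature miRNA name(s).
#' @return character vector over `miRNA`, `miRNA*`, `miRNA-5p`, `miRNA-3p`.
#' @export
assign_arm <- function(name) {
  ifelse(endsWith(name, "*"), "miRNA*",
         ifelse(endsWith(name, "-5p"), "miRNA-5p",
                ifelse(endsWith(name, "-3p"), "miRNA-3p", "miRNA")))
}

#' Match a tag against the known-miRNA reference
#'
#' A tag matches a mature miRNA when it aligns inside the precursor with at
#' most `max_mismatch` substitutions, overlaps the mature region, and both
#' of its ends lie within `max_shift` nt of the mature's ends.  Ties are
#' broken by fewer mismatches, then smaller total end shift, then
#' lexicographic mature name, so a tag is counted once.
#'
#' @param tag tag sequence (DNA/RNA).
#' @param reference a `mirna_reference` from [read_mirbase()].
#' @param max_mismatch maximum substitutions (default 0).
#' @param max_shift maximum end offset in nt (default 2).
#' @return one-row data.frame (`mirna`, `precursor`, `arm`, `mismatches`,
#'   `shift`) or NULL if the tag matches nothing.
#' @export
match_conserved <- function(tag, reference, max_mismatch = 0L, max_shift = 2L) {
  tag <- normalize_dna(tag)
  len <- nchar(tag)
  best <- NULL
  for (j in seq_along(reference$precursors)) {
    prec <- reference$precursors[[j]]
    pname <- names(reference$precursors)[j]
    m <- Biostrings::matchPattern(tag, prec, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m) == 0) next
    starts <- BiocGenerics::start(m)
    nmm <- Biostrings::neditStartingAt(Biostrings::DNAString(tag),
                                       Biostrings::DNAString(prec),
                                       starting.at = starts,
                                       with.indels = FALSE)
    mt <- reference$matures[reference$matures$precursor == pname, , drop = FALSE]
    if (nrow(mt) == 0) next
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- s + len - 1L
      for (r in seq_len(nrow(mt))) {
        if (e < mt$start[r] || s > mt$end[r]) next  # no overlap with mature
        sh <- abs(s - mt$start[r]) + abs(e - mt$end[r])
        if (abs(s - mt$start[r]) > max_shift || abs(e - mt$end[r]) > max_shift)
          next
        cand <- data.frame(mirna = mt$name[r], precursor = pname,
                           arm = mt$arm[r], mismatches = as.integer(nmm[k]),
                           shift = as.integer(sh), stringsAsFactors = FALSE)
        if (is.null(best) ||
            cand$mismatches < best$mismatches ||
            (cand$mismatches == best$mismatches && cand$shift < best$shift) ||
            (cand$mismatches == best$mismatches && cand$shift == best$shift &&
             cand$mirna < best$mirna)) {
          best <- cand
        }
      }
    }
  }
  best
}

#' Match many tags against the known-miRNA reference
#'
#' @param tags character vector of tag sequences.
#' @inheritParams match_conserved
#' @return data.frame with one row per matched tag: `tag`, `mirna`,
#'   `precursor`, `arm`, `mismatches`, `shift`.
#' @export
match_conserved_all <- function(tags, reference, max_mismatch = 0L,
                                max_shift = 2L) {
  rows <- lapply(tags, function(t) {
    m <- match_conserved(t, reference, max_mismatch, max_shift)
    if (is.null(m)) NULL else cbind(tag = t, m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tag = character(0), mirna = character(0),
                      precursor = character(0), arm = character(0),
                      mismatches = integer(0), shift = integer(0))
  rownames(out) <- NULL
  out
}

#' Per-miRNA count table for one library
#'
#' @param matches data.frame from [match_conserved_all()].
#' @param tags data.frame with `sequence` and `count` for the library.
#' @return data.frame (`mirna`, `arm`, `unique_tags`, `total_reads`) sorted
#'   by decreasing total reads, with a `summary` attribute listing
#'   `detected_mirnas`, `precursors_hit`, `unique_tags_matched` and
#'   `total_reads_matched`.
#' @export
count_table <- function(matches, tags) {
  if (nrow(matches) == 0) {
    out <- data.frame(mirna = character(0), arm = character(0),
                      unique_tags = integer(0), total_reads = integer(0))
    attr(out, "summary") <- list(detected_mirnas = 0L, precursors_hit = 0L,
                                 unique_tags_matched = 0L,
                                 total_reads_matched = 0L)
    return(out)
  }
  cnt <- tags$count[match(matches$tag, tags$sequence)]
  cnt[is.na(cnt)] <- 0L
  keep <- cnt > 0L
  matches <- matches[keep, , drop = FALSE]
  cnt <- cnt[keep]
  u <- tapply(rep(1L, nrow(matches)), matches$mirna, sum)
  r <- tapply(cnt, matches$mirna, sum)
  arm <- matches$arm[!duplicated(matches$mirna)]
  names(arm) <- matches$mirna[!duplicated(matches$mirna)]
  out <- data.frame(mirna = names(u), arm = unname(arm[names(u)]),
                    unique_tags = as.integer(u), total_reads = as.integer(r),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$total_reads, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    detected_mirnas = nrow(out),
    precursors_hit = length(unique(matches$precursor)),
    unique_tags_matched = nrow(matches),
    total_reads_matched = sum(cnt))
  out
}

#' Write a miRBase-flavour FASTA (RNA alphabet)
#'
#' @param seqs named character vector of DNA/RNA sequences.
#' @param path output path.
#' @param accession_prefix accession stub written after the name.
#' @export
write_mirna_fasta <- function(seqs, path, accession_prefix = "SIM") {
  rna <- chartr("Tt", "Uu", seqs)
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- sprintf(">%s %s%04d", names(seqs),
                                   accession_prefix, seq_along(seqs))
  lines[c(FALSE, TRUE)] <- unname(rna)
  writeLines(lines, path)
  invisible(path)
}
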