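#' Read small-RNA sequencing reads from FASTQ or FASTA
#'
#' @param path file path; `.fastq`/`.fq` (optionally `.gz`) is read as
#'   FASTQ, anything else as FASTA.
#' @return character vector of read sequences, named by record id.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  setNames(as.character(set), names(set))
}

# locate the 3' adapter in each read: leftmost occurrence of a >= seed_len
# prefix of the adapter that either runs to the read end or spans the full
# adapter.  Returns the 1-based adapter start, or NA if absent.
find_adapter <- function(seqs, adapter, seed_len = 6L) {
  n <- length(seqs)
  L <- nchar(seqs)
  alen <- nchar(adapter)
  seed <- substr(adapter, 1, seed_len)
  pos <- rep(NA_integer_, n)
  from <- rep(1L, n)
  done <- L < seed_len
  while (any(!done & is.na(pos))) {
    idx <- which(!done & is.na(pos))
    sub <- substr(seqs[idx], from[idx], L[idx])
    m <- regexpr(seed, sub, fixed = TRUE)
    hit <- m > 0
    done[idx[!hit]] <- TRUE
    if (any(hit)) {
      ih <- idx[hit]
      s <- from[ih] + as.integer(m[hit]) - 1L
      overlap <- pmin(L[ih] - s + 1L, alen)
      ok <- substr(seqs[ih], s, s + overlap - 1L) == substring(adapter, 1, overlap)
      pos[ih[ok]] <- s[ok]
      from[ih[!ok]] <- s[!ok] + 1L
      done[ih[!ok][from[ih[!ok]] > L[ih[!ok]] - seed_len + 1L]] <- TRUE
    }
  }
  pos
}

#' Classify raw reads into cleaning categories
#'
#' Applies the standard small-RNA library cleaning filters in a fixed
#' priority order: reads containing N are low quality; reads without a
#' recognisable 3' adapter (a >= `seed_len` nt adapter prefix) are
#' `adapter3_null`; an adapter starting at position 1 means no insert;
#' inserts that begin with the 3'-most `contaminant_len` nt of the 5'
#' adapter are 5'-adapter contaminants; inserts that are at least
#' `polyA_frac` adenosine are polyA artifacts; inserts shorter than
#' `min_insert` are too short.  Everything else is clean and the trimmed
#' insert is returned.  Inserts longer than `max_insert` cannot retain a
#' >= `seed_len` adapter match and fall into `adapter3_null`.
#'
#' @param seqs character vector of read sequences (ACGTN).
#' @param adapter_3p,adapter_5p adapter sequences (DNA).
#' @param min_insert,max_insert insert length bounds in nt (defaults 18/30).
#' @param polyA_frac minimum A fraction calling a polyA insert.
#' @param seed_len minimum matched 3'-adapter prefix (nt).
#' @param contaminant_len length of the 5'-adapter tail used to flag
#'   contaminant inserts (nt).
#' @return data.frame with columns `category` (factor over low_quality,
#'   adapter3_null, insert_null, adapter5_contaminant, polyA, too_short,
#'   clean) and `insert` (trimmed insert, NA unless clean).
#' @export
classify_reads <- function(seqs, adapter_3p, adapter_5p,
                           min_insert = 18L, max_insert = 30L,
                           polyA_frac = 0.8, seed_len = 6L,
                           contaminant_len = 8L) {
  if (!nzchar(adapter_3p) || !nzchar(adapter_5p))
    stop("adapters must be non-empty")
  if (length(seqs) == 0) {
    return(data.frame(category = factor(character(0), levels = qc_categories()),
                      insert = character(0), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(seqs))) stop("empty read sequence")
  seqs <- toupper(seqs)
  n <- length(seqs)
  cat <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)

  lowq <- grepl("N", seqs, fixed = TRUE)
  cat[lowq] <- "low_quality"

  pos <- find_adapter(seqs, toupper(adapter_3p), seed_len)
  ins_all <- substr(seqs, 1L, ifelse(is.na(pos), 0L, pos - 1L))
  ins_len <- ifelse(is.na(pos), NA_integer_, pos - 1L)

  todo <- is.na(cat)
  cat[todo & is.na(pos)] <- "adapter3_null"

  todo <- is.na(cat)
  cat[todo & ins_len == 0L] <- "insert_null"

  tail5 <- substr(toupper(adapter_5p),
                  nchar(adapter_5p) - contaminant_len + 1L, nchar(adapter_5p))
  todo <- is.na(cat)
  contam <- todo & startsWith(ins_all, tail5)
  cat[contam] <- "adapter5_contaminant"

  todo <- is.na(cat)
  n_a <- nchar(ins_all) - nchar(gsub("A", "", ins_all, fixed = TRUE))
  cat[todo & n_a >= polyA_frac * ins_len] <- "polyA"

  todo <- is.na(cat)
  cat[todo & ins_len < min_insert] <- "too_short"
  # overlong inserts cannot occur with a seed_len anchor on typical read
  # lengths, but guard anyway
  todo <- is.na(cat)
  cat[todo & ins_len > max_insert] <- "adapter3_null"

  todo <- is.na(cat)
  cat[todo] <- "clean"
  insert[cat == "clean"] <- ins_all[cat == "clean"]
  data.frame(category = factor(cat, levels = qc_categories()),
             insert = insert, stringsAsFactors = FALSE)
}

#' @rdname classify_reads
#' @param seq a single read sequence.
#' @param ... passed on to [classify_reads()].
#' @return `classify_read()`: a list with `category` (character scalar) and
#'   `insert` (trimmed insert or NA).
#' @export
classify_read <- function(seq, adapter_3p, adapter_5p, ...) {
  res <- classify_reads(seq, adapter_3p, adapter_5p, ...)
  list(category = as.character(res$category[1]), insert = res$insert[1])
}

qc_categories <- function() {
  c("low_quality", "adapter3_null", "insert_null", "adapter5_contaminant",
    "polyA", "too_short", "clean")
}

#' Construct a library QC report from category counts
#'
#' @param raw_reads,adapter3_null,insert_null,adapter5_contaminant,shorter_than_18,polyA,clean_reads
#'   read counts per cleaning category.
#' @param high_quality reads surviving the quality filter; defaults to
#'   `raw_reads - low_quality`.
#' @param low_quality reads failing the quality filter.
#' @return an object of class `library_qc`: a data.frame with columns
#'   `category`, `reads` and `pct` (percentage of raw reads).
#' @export
qc_report <- function(raw_reads, low_quality = 0L,
                      adapter3_null = 0L, insert_null = 0L,
                      adapter5_contaminant = 0L, shorter_than_18 = 0L,
                      polyA = 0L, clean_reads = NULL,
                      high_quality = raw_reads - low_quality) {
  if (is.null(clean_reads))
    clean_reads <- high_quality - (adapter3_null + insert_null +
      adapter5_contaminant + shorter_than_18 + polyA)
  counts <- c(raw_reads = raw_reads, high_quality = high_quality,
              adapter3_null = adapter3_null, insert_null = insert_null,
              adapter5_contaminant = adapter5_contaminant,
              shorter_than_18 = shorter_than_18, polyA = polyA,
              clean_reads = clean_reads)
  df <- data.frame(category = names(counts), reads = unname(counts),
                   pct = round(100 * unname(counts) / raw_reads, 2),
                   stringsAsFactors = FALSE)
  df$pct[df$category == "raw_reads"] <- NA_real_
  class(df) <- c("library_qc", "data.frame")
  df
}

#' Clean a small-RNA library and collapse it to unique tags
#'
#' Runs [classify_reads()] over a library, collapses the clean inserts to
#' unique tags with read counts, and tallies a Table-1-style accounting
#' report (percentages over raw reads).
#'
#' @param reads character vector of read sequences, or a FASTQ/FASTA path.
#' @inheritParams classify_reads
#' @return list with `tags` (data.frame `sequence`, `count`, sorted by
#'   decreasing count) and `report` (a `library_qc`).
#' @export
clean_library <- function(reads, adapter_3p, adapter_5p, ...) {
  if (length(reads) == 1 && !grepl("^[ACGTUNacgtun]+$", reads) &&
      file.exists(reads)) {
    reads <- read_reads(reads)
  }
  if (length(reads) == 0) {
    rep0 <- qc_report(0L)
    return(list(tags = data.frame(sequence = character(0), count = integer(0)),
                report = rep0))
  }
  cls <- classify_reads(reads, adapter_3p, adapter_5p, ...)
  tab <- table(cls$category)
  inserts <- cls$insert[cls$category == "clean"]
  tt <- sort(table(inserts), decreasing = TRUE)
  tags <- data.frame(sequence = names(tt), count = as.integer(tt),
                     stringsAsFactors = FALSE)
  report <- qc_report(
    raw_reads = length(reads),
    low_quality = as.integer(tab[["low_quality"]]),
    adapter3_null = as.integer(tab[["adapter3_null"]]),
    insert_null = as.integer(tab[["insert_null"]]),
    adapter5_contaminant = as.integer(tab[["adapter5_contaminant"]]),
    shorter_than_18 = as.integer(tab[["too_short"]]),
    polyA = as.integer(tab[["polyA"]]),
    clean_reads = as.integer(tab[["clean"]])
  )
  list(tags = tags, report = report)
}

#' Read-count histogram by insert length
#'
#' @param tags data.frame with `sequence` and `count` (collapsed tags).
#' @param lengths integer range of insert lengths to report.
#' @return data.frame with `length`, `reads` and `proportion` (of total
#'   reads; proportions sum to 1 when all tag lengths fall in `lengths`).
#' @export
length_distribution <- function(tags, lengths = 18:30) {
  stopifnot(is.data.frame(tags))
  len <- nchar(tags$sequence)
  reads <- vapply(lengths, function(l) sum(tags$count[len == l]), numeric(1))
  total <- sum(tags$count)
  data.frame(length = lengths, reads = reads,
             proportion = if (total > 0) reads / total else rep(0, length(lengths)))
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the collapsed-read convention `tag_<i>_x<count>`.
#'
#' @param tags data.frame with `sequence` and `count`.
#' @param path output path.
#' @export
write_tags_fasta <- function(tags, path) {
  set <- Biostrings::DNAStringSet(tags$sequence)
  names(set) <- sprintf("tag_%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a QC report as TSV
#'
#' @param report a `library_qc` object.
#' @param path output path.
#' @export
write_qc_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
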