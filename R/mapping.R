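#' Build a genome index for short-tag mapping
#'
#' Wraps the reference chromosomes (plus lazily-computed reverse
#' complements) for use by [map_tag()].  Exact and one-mismatch matching is
#' delegated to Biostrings' C matching kernels, so no k-mer hash is stored;
#' `k` is kept for [index_lookup()] queries.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param k seed length for [index_lookup()] (>= 8).
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome, k = 11L) {
  if (k < 8) stop("seed length k must be >= 8")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    genome <- Biostrings::DNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(seqs = genome, k = as.integer(k)), class = "genome_index")
}

#' Locate all exact occurrences of a k-mer in the indexed genome
#'
#' @param index a `genome_index`.
#' @param kmer query sequence (plus strand only).
#' @return data.frame with `chrom` and 0-based `start` positions.
#' @export
index_lookup <- function(index, kmer) {
  hits <- lapply(seq_along(index$seqs), function(i) {
    m <- Biostrings::matchPattern(kmer, index$seqs[[i]])
    if (length(m) == 0) return(NULL)
    data.frame(chrom = names(index$seqs)[i], start = BiocGenerics::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) hits <- data.frame(chrom = character(0), start = integer(0))
  hits
}

empty_alignments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

#' Map one tag to the genome with at most one mismatch
#'
#' Reports every locus on either strand whose Hamming distance to the tag
#' is at most `max_mismatch` (no indels), as 0-based half-open intervals.
#'
#' @param tag tag sequence (ACGT, >= 18 nt for library tags; shorter
#'   queries are allowed for diagnostic use down to 10 nt).
#' @param index a `genome_index` from [build_index()].
#' @param max_mismatch maximum substitutions (default 1).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `mismatches`; one row per alignment.
#' @export
map_tag <- function(tag, index, max_mismatch = 1L) {
  tag <- normalize_dna(tag)
  if (nchar(tag) < 10) stop("tag too short to map")
  pat_fwd <- Biostrings::DNAString(tag)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  out <- vector("list", 2L * length(index$seqs))
  idx <- 0L
  for (i in seq_along(index$seqs)) {
    chr <- index$seqs[[i]]
    cname <- names(index$seqs)[i]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      m <- Biostrings::matchPattern(pat, chr, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      st <- BiocGenerics::start(m)
      nmm <- Biostrings::neditStartingAt(pat, chr, starting.at = st,
                                         with.indels = FALSE)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        chrom = cname, start = st - 1L, end = st - 1L + nchar(tag),
        strand = strand, mismatches = as.integer(nmm),
        stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) return(empty_alignments())
  res <- do.call(rbind, out[seq_len(idx)])
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Map many tags, returning one combined alignment table
#'
#' @param tags character vector of tag sequences.
#' @param index a `genome_index`.
#' @param max_mismatch maximum substitutions per alignment.
#' @return data.frame as [map_tag()] with an extra leading `tag` column.
#' @export
map_tags <- function(tags, index, max_mismatch = 1L) {
  res <- lapply(tags, function(t) {
    a <- map_tag(t, index, max_mismatch)
    if (nrow(a)) cbind(tag = t, a, stringsAsFactors = FALSE) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- cbind(tag = character(0), empty_alignments())
  rownames(res) <- NULL
  res
}

#' Classify a tag's alignments as unmapped, unique or multi-locus
#'
#' Uniqueness counts distinct loci (`chrom`, `start`, `end`); a palindromic
#' site hit on both strands is a single locus.
#'
#' @param alignments data.frame from [map_tag()].
#' @return list with `status` (one of "unmapped", "unique", "multi") and
#'   `n_loci`.
#' @export
classify_mapping <- function(alignments) {
  if (is.null(alignments) || nrow(alignments) == 0)
    return(list(status = "unmapped", n_loci = 0L))
  loci <- unique(alignments[, c("chrom", "start", "end")])
  n <- nrow(loci)
  list(status = if (n == 1L) "unique" else "multi", n_loci = n)
}

#' Write alignments as BED6
#'
#' Score column holds the mismatch count.
#'
#' @param alignments data.frame with a `tag` column as from [map_tags()].
#' @param path output path.
#' @export
write_alignments_bed <- function(alignments, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = alignments$chrom,
    ranges = IRanges::IRanges(start = alignments$start + 1L,
                              end = alignments$end),
    strand = alignments$strand)
  gr$name <- alignments$tag
  gr$score <- alignments$mismatches
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
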