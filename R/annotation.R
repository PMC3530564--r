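#' Small-RNA annotation category vocabulary, in priority order
#'
#' Categories are assigned by a fixed hierarchy so each tag gets exactly
#' one label: known miRNA first (so miRNA reads inside genes are not lost
#' to exon), then the structural/non-coding classes, then repeat, exon,
#' intron, and finally unannotated.
#'
#' @return character vector of category names, highest priority first.
#' @export
annotation_categories <- function() {
  c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA",
    "repeat", "exon", "intron", "unannotated")
}

feature_classes <- function() annotation_categories()[-c(1, 11)]

#' Read a labelled feature set from BED or GFF
#'
#' For BED6 the feature class is taken from the name field; for GFF3 from
#' the type column.  Classes outside the fixed vocabulary are rejected.
#'
#' @param path BED or GFF file path.
#' @return a `GRanges` with a `feature_class` metadata column.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  cls <- if (!is.null(gr$name)) as.character(gr$name) else as.character(gr$type)
  cls <- sub("[:_.].*$", "", cls)
  bad <- setdiff(unique(cls), feature_classes())
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  gr$feature_class <- cls
  gr
}

#' Build a feature set from a data.frame
#'
#' @param df data.frame with `chrom`, `start` (0-based), `end` (half-open),
#'   `strand`, `class`.
#' @return a `GRanges` with a `feature_class` metadata column.
#' @export
feature_set <- function(df) {
  bad <- setdiff(unique(df$class), feature_classes())
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$feature_class <- df$class
  gr
}

#' Annotate mapped tags by feature overlap and known-miRNA membership
#'
#' A tag is `known_miRNA` if its sequence is in `known_tags`; otherwise it
#' takes the highest-priority feature class whose interval overlaps any of
#' its alignments by at least one base (strand-agnostic); otherwise it is
#' `unannotated`.
#'
#' @param alignments data.frame from [map_tags()] (`tag`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param features a `GRanges` from [feature_set()]/[read_features()], or
#'   NULL for no features.
#' @param known_tags character vector of tag sequences matched to known
#'   miRNAs.
#' @return data.frame with `tag` and `category` (factor over
#'   [annotation_categories()]); one row per distinct tag in `alignments`
#'   or `known_tags`.
#' @export
annotate_tags <- function(alignments, features = NULL, known_tags = character(0)) {
  tags <- unique(c(alignments$tag, known_tags))
  if (length(tags) == 0) {
    return(data.frame(tag = character(0),
                      category = factor(character(0),
                                        levels = annotation_categories())))
  }
  prio <- annotation_categories()
  rank <- setNames(seq_along(prio), prio)
  best <- setNames(rep(rank[["unannotated"]], length(tags)), tags)
  if (!is.null(features) && length(features) > 0 && nrow(alignments) > 0) {
    agr <- GenomicRanges::GRanges(
      seqnames = alignments$chrom,
      ranges = IRanges::IRanges(start = alignments$start + 1L,
                                end = alignments$end),
      strand = "*")
    ov <- GenomicRanges::findOverlaps(agr, features, ignore.strand = TRUE)
    if (length(ov)) {
      hit_tag <- alignments$tag[S4Vectors::queryHits(ov)]
      hit_rank <- rank[features$feature_class[S4Vectors::subjectHits(ov)]]
      agg <- tapply(hit_rank, hit_tag, min)
      best[names(agg)] <- pmin(best[names(agg)], agg)
    }
  }
  best[names(best) %in% known_tags] <- rank[["known_miRNA"]]
  data.frame(tag = tags,
             category = factor(prio[best], levels = prio),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname annotate_tags
#' @param tag a single tag sequence.
#' @param known_mirna_hit logical; whether the tag matched a known miRNA.
#' @return `annotate_tag()`: a single category string.
#' @export
annotate_tag <- function(tag, alignments, features = NULL,
                         known_mirna_hit = FALSE) {
  res <- annotate_tags(alignments,
                       features = features,
                       known_tags = if (known_mirna_hit) tag else character(0))
  row <- res$category[res$tag == tag]
  if (!length(row)) "unannotated" else as.character(row[1])
}

#' Summarise per-category read and unique-tag totals
#'
#' @param annotations data.frame from [annotate_tags()].
#' @param tags data.frame with `sequence` and `count` per tag; tags missing
#'   from `annotations` (e.g. unmapped) are excluded.
#' @return data.frame with `category`, `unique_tags`, `total_reads` and the
#'   corresponding percentages; totals conserve input counts.
#' @export
summarize_categories <- function(annotations, tags) {
  if (nrow(annotations) == 0 || nrow(tags) == 0) {
    return(data.frame(category = character(0), unique_tags = integer(0),
                      total_reads = integer(0), pct_unique = numeric(0),
                      pct_reads = numeric(0)))
  }
  m <- match(annotations$tag, tags$sequence)
  keep <- !is.na(m)
  ann <- annotations[keep, , drop = FALSE]
  cnt <- tags$count[m[keep]]
  u <- tapply(rep(1L, nrow(ann)), ann$category, sum, default = 0L)
  r <- tapply(cnt, ann$category, sum, default = 0L)
  out <- data.frame(category = annotation_categories(),
                    unique_tags = as.integer(u[annotation_categories()]),
                    total_reads = as.integer(r[annotation_categories()]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pct_unique <- 100 * out$unique_tags / sum(out$unique_tags)
  out$pct_reads <- 100 * out$total_reads / sum(out$total_reads)
  out
}
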