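#' Delta-delta-Ct between a sample and a calibrator
#'
#' @param ct_target,ct_reference cycle-threshold values for the target
#'   miRNA and the reference gene (18S rRNA by convention) in the sample.
#' @param cal_target,cal_reference the same pair in the calibrator sample.
#' @return ddCt in cycles:
#'   `(ct_target - ct_reference) - (cal_target - cal_reference)`.
#' @export
delta_delta_ct <- function(ct_target, ct_reference, cal_target,
                           cal_reference) {
  stopifnot(all(is.finite(c(ct_target, ct_reference, cal_target,
                            cal_reference))),
            all(c(ct_target, ct_reference, cal_target, cal_reference) > 0))
  (ct_target - ct_reference) - (cal_target - cal_reference)
}

#' Relative expression from ddCt (Livak method)
#'
#' Assumes perfect amplification efficiency (doubling per cycle), as in
#' the 2^-ddCt method.
#'
#' @param ddct delta-delta-Ct in cycles.
#' @return fold change `2^-ddct`.
#' @export
relative_expression <- function(ddct) {
  stopifnot(all(is.finite(ddct)))
  2^(-ddct)
}

#' Mean and standard deviation over biological replicates
#'
#' @param folds numeric vector of per-replicate fold changes (n >= 2).
#' @return list with `mean` and `sd` (sample, n - 1 denominator).
#' @export
summarize_replicates <- function(folds) {
  if (length(folds) < 2) stop("at least two replicates are required")
  list(mean = mean(folds), sd = sd(folds))
}

#' Relative quantification of a Ct table by 2^-ddCt
#'
#' Reads stem-loop qPCR measurements, averages technical/biological
#' replicates on the dCt scale within each sample (standard Livak
#' practice), references every sample to the calibrator sample, and
#' reports per-sample fold changes with replicate spread.
#'
#' @param ct data.frame (or TSV path) with columns `sample`, `target`,
#'   `ct_target`, `ct_reference`, `replicate`.
#' @param calibrator name of the calibrator sample (fold 1 by
#'   construction).
#' @return data.frame with `sample`, `target`, `fold` (from the mean dCt)
#'   and `sd` (sample SD of per-replicate folds; NA with one replicate).
#' @export
qpcr_relative <- function(ct, calibrator) {
  if (is.character(ct) && length(ct) == 1) {
    ct <- read.table(ct, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("sample", "target", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (!calibrator %in% ct$sample) stop("calibrator sample not found")
  ct$dct <- ct$ct_target - ct$ct_reference
  out <- list()
  for (tgt in unique(ct$target)) {
    sub <- ct[ct$target == tgt, , drop = FALSE]
    cal <- sub$dct[sub$sample == calibrator]
    if (!length(cal)) next
    cal_mean <- mean(cal)
    for (smp in unique(sub$sample)) {
      d <- sub$dct[sub$sample == smp]
      folds <- relative_expression(d - cal_mean)
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, target = tgt,
        fold = relative_expression(mean(d) - cal_mean),
        sd = if (length(folds) >= 2) sd(folds) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
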