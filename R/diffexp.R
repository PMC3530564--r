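#' Normalise a read count to transcripts per million
#'
#' @param count raw read count(s).
#' @param total total clean reads in the library.
#' @return `count / total * 1e6`, at full precision (reports round to 4
#'   decimals).
#' @export
normalize_tpm <- function(count, total) {
  if (any(total <= 0)) stop("library total must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count / total * 1e6
}

#' Zero-adjust and low-expression filter for a pair of normalised values
#'
#' A zero normalised expression is replaced by 0.01 so a fold change is
#' defined; records below 1 transcript per million in both libraries are
#' flagged for discarding from the comparative analysis.
#'
#' @param X,Y normalised expressions in the two libraries.
#' @return list with `X`, `Y` (adjusted) and `filtered` (logical).
#' @export
adjust_and_filter <- function(X, Y) {
  stopifnot(all(X >= 0), all(Y >= 0))
  Xa <- ifelse(X == 0, 0.01, X)
  Ya <- ifelse(Y == 0, 0.01, Y)
  list(X = Xa, Y = Ya, filtered = Xa < 1 & Ya < 1)
}

#' Log2 fold change between adjusted normalised expressions
#'
#' @param X adjusted normalised expression in the reference (dry) library.
#' @param Y adjusted normalised expression in the comparison (peak)
#'   library.
#' @return `log2(Y / X)`.
#' @export
fold_change <- function(X, Y) {
  stopifnot(all(X > 0), all(Y > 0))
  log2(Y / X)
}

ac_log_tails <- function(x, y, N1, N2) {
  # conditional distribution of the second library's count given the
  # first: K | x ~ NegBinomial(size = x + 1, prob = N1 / (N1 + N2))
  pr <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = pr, log.p = TRUE)
  upper <- if (y == 0) 0 else
    pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE, log.p = TRUE)
  c(lower = lower, upper = upper)
}

#' Exact two-library count test (Audic-Claverie)
#'
#' Tests whether the counts `x` and `y` of one miRNA in two libraries of
#' total sizes `N1`, `N2` are consistent with equal underlying
#' concentration.  Conditional on the count in one library, the other
#' count follows `p(k | x) = (N2/N1)^k (x+k)! / (x! k! (1+N2/N1)^(x+k+1))`,
#' which is a negative binomial; tails are evaluated through
#' [stats::pnbinom()] in log space, so extreme significance levels do not
#' underflow before the caller asks for a plain probability.
#'
#' `condition` picks which library is conditioned on: `"larger"` (the
#' library holding the larger count; this convention reproduces published
#' two-library small RNA significance values), `"x"` or `"y"`.  `variant`
#' selects the two-sided tail sum (default), a one-sided tail, or the
#' point probability.
#'
#' @param x,y non-negative integer counts in library 1 and 2.
#' @param N1,N2 library totals (clean reads).
#' @param variant one of "two.sided", "less", "greater", "point".  "less"
#'   tests for depletion of `y` relative to `x`, "greater" for enrichment.
#' @param condition one of "larger", "x", "y".
#' @param log10 if TRUE return log10 of the p-value (no underflow).
#' @return p-value in (0, 1] (or its log10).
#' @export
ac_pvalue <- function(x, y, N1, N2,
                      variant = c("two.sided", "less", "greater", "point"),
                      condition = c("larger", "x", "y"), log10 = FALSE) {
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  if (length(x) > 1 || length(y) > 1) {
    return(mapply(ac_pvalue, x, y,
                  MoreArgs = list(N1 = N1, N2 = N2, variant = variant,
                                  condition = condition, log10 = log10)))
  }
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  swap <- switch(condition, x = FALSE, y = TRUE, larger = y > x)
  if (swap) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
    # one-sided directions are stated for y relative to x; conditioning on
    # the other library mirrors the tail
    if (variant == "less") variant <- "greater"
    else if (variant == "greater") variant <- "less"
  }
  if (variant == "point") {
    r <- N2 / N1
    lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
      (x + y + 1) * log1p(r)
  } else {
    tails <- ac_log_tails(x, y, N1, N2)
    lp <- switch(variant,
      less = tails[["lower"]],
      greater = tails[["upper"]],
      two.sided = min(log(2) + min(tails), 0))
  }
  if (log10) lp / log(10) else exp(lp)
}

#' Significance label for a fold change / p-value pair
#'
#' @param log2fc log2 fold change.
#' @param pvalue p-value.
#' @param fc_gate absolute log2 fold-change gate (strict).
#' @param p_gate p-value gate (strict).
#' @return `"**"` when `|log2fc| > fc_gate` and `pvalue < p_gate`, else
#'   `""`.
#' @export
sig_label <- function(log2fc, pvalue, fc_gate = 1, p_gate = 0.01) {
  ifelse((log2fc > fc_gate | log2fc < -fc_gate) & pvalue < p_gate, "**", "")
}

#' Two-library differential expression table
#'
#' Builds the full per-miRNA comparison between a dry-period (`x`) and a
#' peak-lactation (`y`) count table: normalised expressions, zero
#' adjustment and the both-below-1 discard flag, log2 fold change,
#' Audic-Claverie p-value and significance label.
#'
#' @param counts_x,counts_y named numeric vectors (or data.frames with
#'   `name`/`count` columns) of raw counts; missing names count as 0.
#' @param N1,N2 library totals; default to the sum of each count vector.
#' @param variant,condition passed to [ac_pvalue()].
#' @param fc_gate,p_gate passed to [sig_label()].
#' @return data.frame with one row per miRNA in either input: `name`, `x`,
#'   `y`, `X`, `Y` (adjusted normalised expressions), `log2fc`, `pvalue`,
#'   `log10p`, `sig`, `filtered`; attribute `summary` holds the up/down
#'   counts at the significance gates (filtered records excluded).
#' @export
diff_table <- function(counts_x, counts_y, N1 = NULL, N2 = NULL,
                       variant = "two.sided", condition = "larger",
                       fc_gate = 1, p_gate = 0.01) {
  as_named <- function(v) {
    if (is.data.frame(v)) setNames(v$count, v$name) else v
  }
  cx <- as_named(counts_x); cy <- as_named(counts_y)
  if (is.null(N1)) N1 <- sum(cx)
  if (is.null(N2)) N2 <- sum(cy)
  nm <- union(names(cx), names(cy))
  if (length(nm) == 0) {
    out <- data.frame(name = character(0), x = numeric(0), y = numeric(0),
                      X = numeric(0), Y = numeric(0), log2fc = numeric(0),
                      pvalue = numeric(0), log10p = numeric(0),
                      sig = character(0), filtered = logical(0))
    attr(out, "summary") <- list(up = 0L, down = 0L, tested = 0L)
    return(out)
  }
  x <- unname(ifelse(is.na(cx[nm]), 0, cx[nm]))
  y <- unname(ifelse(is.na(cy[nm]), 0, cy[nm]))
  adj <- adjust_and_filter(normalize_tpm(x, N1), normalize_tpm(y, N2))
  lfc <- fold_change(adj$X, adj$Y)
  p <- ac_pvalue(x, y, N1, N2, variant = variant, condition = condition)
  l10 <- ac_pvalue(x, y, N1, N2, variant = variant, condition = condition,
                   log10 = TRUE)
  sig <- sig_label(lfc, p, fc_gate, p_gate)
  out <- data.frame(name = nm, x = x, y = y, X = adj$X, Y = adj$Y,
                    log2fc = lfc, pvalue = p, log10p = l10, sig = sig,
                    filtered = adj$filtered, stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  kept <- !out$filtered
  attr(out, "summary") <- list(
    up = sum(kept & out$sig == "**" & out$log2fc > 0),
    down = sum(kept & out$sig == "**" & out$log2fc < 0),
    tested = sum(kept))
  out
}

#' Write a differential-expression table as TSV
#'
#' Normalised expressions and fold changes are printed with 4 decimals and
#' p-values in scientific notation, mirroring the published table layout.
#'
#' @param de data.frame from [diff_table()].
#' @param path output path.
#' @export
write_diffexp_tsv <- function(de, path) {
  fmt <- data.frame(
    name = de$name, D = de$x, P = de$y,
    `D-NE` = sprintf("%.4f", de$X), `P-NE` = sprintf("%.4f", de$Y),
    `log2.P-NE.D-NE` = sprintf("%.4f", de$log2fc),
    `P-value` = sprintf("%.3g", de$pvalue), sig = de$sig,
    filtered = de$filtered, check.names = FALSE)
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
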