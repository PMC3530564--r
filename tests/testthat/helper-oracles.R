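# Independent reference implementations used as oracles.  They share the
# energy/statistical model definitions with the package (that model IS the
# specification) but none of its search or summation code paths.

# --- folding oracle: exhaustive depth-first enumeration of all nested
# single-hairpin chains, energies computed inline ---------------------------

oracle_pair_type <- function(a, b) {
  key <- paste0(a, b)
  match(key, c("AU", "UA", "CG", "GC", "GU", "UG"))
}

exhaustive_fold_min <- function(seq, params = fold_params()) {
  s <- strsplit(chartr("Tt", "UU", toupper(seq)), "")[[1]]
  n <- length(s)
  minloop <- params$min_loop
  maxint <- params$max_interior
  pt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) pt[i, j] <- oracle_pair_type(s[i], s[j])
  }
  hairpinE <- function(len) params$hairpin_a + params$loop_b * log(len / 3)
  joinE <- function(po, pi, g1, g2) {
    if (g1 == 0 && g2 == 0) return(params$stack[po, pi])
    if (g1 + g2 > maxint) return(Inf)
    if (g1 == 0 || g2 == 0) return(params$bulge_a + params$loop_b * log(g1 + g2))
    params$internal_a + params$loop_b * log((g1 + g2) / 2) +
      min(params$asym_max, params$asym * abs(g1 - g2))
  }
  best <- 0
  dfs <- function(i, j, acc) {
    # (i, j) is the current innermost pair; acc holds the loop energies
    # joining all enclosing pairs
    if (j - i - 1 >= minloop) {
      tot <- acc + hairpinE(j - i - 1)
      if (tot < best) best <<- tot
    }
    if (j - i - 1 < minloop + 2) return(invisible())
    for (k in (i + 1):(j - minloop - 2)) {
      g1 <- k - i - 1
      if (g1 > maxint) break
      for (l in (j - 1):(k + minloop + 1)) {
        g2 <- j - l - 1
        if (g1 + g2 > maxint) break
        if (is.na(pt[k, l])) next
        e <- joinE(pt[i, j], pt[k, l], g1, g2)
        if (is.finite(e)) dfs(k, l, acc + e)
      }
    }
    invisible()
  }
  for (i in seq_len(max(n - minloop - 1, 0))) {
    for (j in (i + minloop + 1):n) {
      if (!is.na(pt[i, j])) dfs(i, j, 0)
    }
  }
  best
}

# --- mapping oracle: naive Hamming scan over every genome position ---------

oracle_hamming_map <- function(tag, genome_str, max_mismatch = 1L) {
  tag_i <- utf8ToInt(tag)
  L <- length(tag_i)
  g_i <- utf8ToInt(genome_str)
  rc <- function(x) {
    comp <- setNames(utf8ToInt("TGCA"), utf8ToInt("ACGT"))
    rev(unname(comp[as.character(x)]))
  }
  scan_one <- function(query, strand) {
    n <- length(g_i)
    if (n < L) return(NULL)
    hits <- integer(0)
    mms <- integer(0)
    for (p in seq_len(n - L + 1)) {
      mm <- sum(g_i[p:(p + L - 1)] != query)
      if (mm <= max_mismatch) {
        hits <- c(hits, p - 1L)
        mms <- c(mms, mm)
      }
    }
    if (!length(hits)) return(NULL)
    data.frame(start = hits, strand = strand, mismatches = mms)
  }
  out <- rbind(scan_one(tag_i, "+"), scan_one(rc(tag_i), "-"))
  if (is.null(out)) {
    out <- data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# vectorised variant used for the large acceptance comparison: returns the
# per-position mismatch counts for one strand in one shot
oracle_hamming_hits_fast <- function(tag, win_mat, max_mismatch = 1L) {
  # win_mat: L x (positions) integer matrix of genome windows
  which(colSums(win_mat != utf8ToInt(tag)) <= max_mismatch)
}

build_window_matrix <- function(genome_str, L) {
  g <- utf8ToInt(genome_str)
  n <- length(g)
  if (n < L) return(matrix(integer(0), nrow = L))
  idx <- outer(seq_len(L), 0:(n - L), `+`)
  matrix(g[idx], nrow = L)
}

# --- Audic-Claverie oracle: direct term-by-term summation ------------------

oracle_ac_point <- function(x, k, N1, N2) {
  r <- N2 / N1
  exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log1p(r))
}

oracle_ac_lower <- function(x, y, N1, N2) {
  sum(oracle_ac_point(x, 0:y, N1, N2))
}

oracle_ac_upper <- function(x, y, N1, N2, horizon = 50000L) {
  sum(oracle_ac_point(x, y:(y + horizon), N1, N2))
}

# --- misc ------------------------------------------------------------------

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

small_sim_config <- function(seed = 101L) {
  simulation_config(
    seed = seed, reads_per_library = 20000L, n_known_mirnas = 10L,
    n_novel_hairpins = 5L, n_decoy_hairpins = 4L, n_ncrna_loci = 1L,
    n_background_loci = 60L, genome_length = 40000L)
}

# loci in `pred` (with start/end columns) overlapping each manifest locus
loci_recovered <- function(pred, loci) {
  vapply(seq_len(nrow(loci)), function(i) {
    any(pred$start < loci$end[i] & pred$end > loci$start[i])
  }, logical(1))
}
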