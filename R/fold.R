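#' Energy parameters for the built-in hairpin folding model
#'
#' Returns the parameter set of the simplified nearest-neighbour energy model
#' used by [fold_mfe()]: a 6 x 6 stacking table over the pair types
#' AU, UA, CG, GC, GU, UG (kcal/mol, outer pair in rows, inner pair in
#' columns) and logarithmic length penalties for hairpin loops, bulges and
#' internal loops.  The values are Turner-flavoured but deliberately compact;
#' the model is intended for ranking candidate precursor hairpins, not for
#' reproducing reference folding energies base for base.
#'
#' @param min_loop minimum hairpin loop length (nt).
#' @param max_interior maximum total unpaired length of a bulge or internal
#'   loop between two consecutive stem pairs (nt).
#' @return a list with elements `stack`, `hairpin_a`, `bulge_a`,
#'   `internal_a`, `loop_b`, `asym`, `asym_max`, `min_loop`, `max_interior`
#'   and `pair_levels`.
#' @export
fold_params <- function(min_loop = 3L, max_interior = 30L) {
  pair_levels <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(c(
    # inner:  AU     UA     CG     GC     GU     UG
    -0.9, -1.1, -2.2, -2.1, -0.6, -1.4,  # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
    -2.1, -2.1, -3.3, -2.4, -1.4, -2.1,  # outer CG
    -2.4, -2.2, -3.4, -3.3, -1.5, -2.5,  # outer GC
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.4,  # outer GU
    -1.0, -0.6, -2.1, -1.4, -0.2, -0.5   # outer UG
  ), nrow = 6, byrow = TRUE, dimnames = list(pair_levels, pair_levels))
  list(
    stack = stack,
    hairpin_a = 5.4, bulge_a = 3.8, internal_a = 1.7,
    loop_b = 1.08, asym = 0.3, asym_max = 3.0,
    min_loop = as.integer(min_loop), max_interior = as.integer(max_interior),
    pair_levels = pair_levels
  )
}

#' Fold a sequence into its minimum-free-energy hairpin
#'
#' Computes the minimum-free-energy secondary structure of a short RNA (or
#' DNA, normalised to RNA) sequence under the built-in single-hairpin
#' nearest-neighbour model: structures are chains of nested base pairs
#' (Watson-Crick plus GU wobble) joined by stacks, bulges and internal
#' loops and closed by a terminal loop of at least `min_loop` nt;
#' multibranch loops are not considered, which matches the topology of
#' miRNA precursors and keeps the optimisation exact and fast.
#'
#' @param sequence a single character string, alphabet ACGU/ACGT.
#' @param params energy parameters, see [fold_params()].
#' @return an object of class `hairpin_structure`: a list with `sequence`
#'   (RNA alphabet), `dot_bracket`, `mfe` (kcal/mol, 0 iff no pairs) and
#'   `pairs` (two-column matrix of 1-based paired positions).
#' @examples
#' fold_mfe(paste0(strrep("GC", 10), "GAAA", strrep("GC", 10)))
#' @export
fold_mfe <- function(sequence, params = fold_params()) {
  seq <- normalize_rna(sequence)
  n <- nchar(seq)
  if (n < 10) stop("sequence must be at least 10 nt long")
  if (n > 200) stop("sequence longer than 200 nt; not a hairpin window")
  res <- fold_mfe_cpp(seq, params)
  structure(
    list(sequence = seq, dot_bracket = res$dot_bracket,
         mfe = res$mfe, pairs = res$pairs),
    class = "hairpin_structure"
  )
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", sep = "")
  cat(sprintf("%s (%.2f)\n", x$dot_bracket, x$mfe))
  invisible(x)
}

#' Evaluate the energy of an explicit chain structure
#'
#' Reference evaluator for the built-in energy model: given a set of base
#' pairs forming a single nested chain, returns its free energy.  Used to
#' cross-check the folding engine and available for inspecting alternative
#' structures.
#'
#' @param sequence character string, ACGU/ACGT.
#' @param pairs two-column matrix of 1-based paired positions (may be
#'   unordered); `NULL` or zero rows means the open structure (energy 0).
#' @param params energy parameters, see [fold_params()].
#' @return energy in kcal/mol, `Inf` for a forbidden structure.
#' @export
structure_energy <- function(sequence, pairs, params = fold_params()) {
  seq <- normalize_rna(sequence)
  if (is.null(pairs) || NROW(pairs) == 0) return(0)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  # chain check: strictly nested
  if (np > 1) {
    ok <- all(diff(pairs[, 1]) > 0) && all(diff(pairs[, 2]) < 0)
    if (!ok) stop("pairs do not form a single nested chain")
  }
  type <- pair_type_of(substring(seq, pairs[, 1], pairs[, 1]),
                       substring(seq, pairs[, 2], pairs[, 2]))
  if (anyNA(type)) return(Inf)
  e <- 0
  for (k in seq_len(np - 1)) {
    g1 <- pairs[k + 1, 1] - pairs[k, 1] - 1L
    g2 <- pairs[k, 2] - pairs[k + 1, 2] - 1L
    if (g1 < 0 || g2 < 0) stop("pairs do not form a single nested chain")
    e <- e + loop_energy(type[k], type[k + 1], g1, g2, params)
  }
  loop <- pairs[np, 2] - pairs[np, 1] - 1L
  if (loop < params$min_loop) return(Inf)
  e + params$hairpin_a + params$loop_b * log(loop / 3)
}

# energy of joining two consecutive chain pairs (by type index) across
# g1/g2 unpaired bases; shared definition with the C++ engine
loop_energy <- function(outer, inner, g1, g2, params) {
  if (g1 == 0 && g2 == 0) return(params$stack[outer, inner])
  if (g1 + g2 > params$max_interior) return(Inf)
  if (g1 == 0 || g2 == 0) return(params$bulge_a + params$loop_b * log(g1 + g2))
  params$internal_a + params$loop_b * log((g1 + g2) / 2) +
    min(params$asym_max, params$asym * abs(g1 - g2))
}

# pair type index (1..6, order AU UA CG GC GU UG) or NA if not pairable
pair_type_of <- function(a, b) {
  key <- paste0(a, b)
  match(key, c("AU", "UA", "CG", "GC", "GU", "UG"))
}

#' Parse a dot-bracket string into a pair matrix
#'
#' @param dot_bracket a string over "(", ")" and ".".
#' @return two-column integer matrix of 1-based paired positions.
#' @export
pairs_from_dotbracket <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  res <- vector("list", 0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      res[[length(res) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    } else if (chars[i] != ".") {
      stop("dot-bracket string contains an invalid character")
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (!length(res)) return(out)
  m <- do.call(rbind, res)
  m[order(m[, 1]), , drop = FALSE]
}
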