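#' Design constraints for fragment selection
#'
#' Bundles the tunable parameters of the specificity rule and the fragment
#' search. The defaults encode the validated design rule: within every 21-bp
#' window of the fragment there must be at least 3 mismatches to every
#' off-target (one- and two-mismatch windows can still silence), fragments of
#' roughly 70 bp are long enough to silence efficiently, and whole chimeric
#' inserts of 200-1500 bp are suitable for TRV-based VIGS vectors.
#'
#' @param window_len siRNA window length in nt; 21-24 (21, the shortest
#'   siRNA class, is the conservative default).
#' @param min_mismatch Minimum mismatches required in every window against
#'   every off-target (default 3).
#' @param min_fragment_len,max_fragment_len Fragment length bounds in nt.
#' @param insert_len_bounds Length-2 integer vector: acceptable whole-insert
#'   length for the viral vector.
#' @param both_strands Screen off-targets on both strands? VIGS replication
#'   produces dsRNA, so siRNAs of both polarities arise; `TRUE` is the
#'   conservative default.
#' @param apply_mirna_rules Also reject fragments any of whose windows forms
#'   a functional miRNA-like site on an off-target (see [mirna_rules()]).
#' @param mirna A [mirna_rules()] configuration.
#' @param min_exact_windows Efficacy threshold: a fragment silences an
#'   intended target if at least this many of its windows match the target
#'   with zero mismatches.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(window_len = 21L,
                               min_mismatch = 3L,
                               min_fragment_len = 70L,
                               max_fragment_len = 400L,
                               insert_len_bounds = c(200L, 1500L),
                               both_strands = TRUE,
                               apply_mirna_rules = TRUE,
                               mirna = mirna_rules(window_len = window_len),
                               min_exact_windows = 1L) {
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 21L || window_len > 24L) {
    abort("'window_len' must be between 21 and 24 nt (the siRNA size range).")
  }
  min_mismatch <- as.integer(min_mismatch)
  if (is.na(min_mismatch) || min_mismatch < 1L || min_mismatch > window_len) {
    abort("'min_mismatch' must be between 1 and window_len.")
  }
  min_fragment_len <- as.integer(min_fragment_len)
  max_fragment_len <- as.integer(max_fragment_len)
  if (min_fragment_len < window_len) {
    abort("'min_fragment_len' must be at least window_len.")
  }
  if (max_fragment_len < min_fragment_len) {
    abort("'max_fragment_len' must be >= min_fragment_len.")
  }
  insert_len_bounds <- as.integer(insert_len_bounds)
  if (length(insert_len_bounds) != 2L || any(is.na(insert_len_bounds)) ||
      insert_len_bounds[1] > insert_len_bounds[2] || insert_len_bounds[1] < 1L) {
    abort("'insert_len_bounds' must be an increasing pair of positive lengths.")
  }
  if (!inherits(mirna, "mirna_rules")) abort("'mirna' must come from mirna_rules().")
  if (mirna$window_len != window_len) {
    abort("'mirna' rules were built for a different window length.")
  }
  structure(
    list(window_len = window_len, min_mismatch = min_mismatch,
         min_fragment_len = min_fragment_len,
         max_fragment_len = max_fragment_len,
         insert_len_bounds = insert_len_bounds,
         both_strands = isTRUE(both_strands),
         apply_mirna_rules = isTRUE(apply_mirna_rules),
         mirna = mirna,
         min_exact_windows = as.integer(min_exact_windows)),
    class = "design_constraints")
}

#' @export
print.design_constraints <- function(x, ...) {
  cat("<design_constraints>\n")
  cat(sprintf("  window %d nt, >= %d mismatches per window vs off-targets\n",
              x$window_len, x$min_mismatch))
  cat(sprintf("  fragment length %d-%d nt; insert bounds %d-%d nt\n",
              x$min_fragment_len, x$max_fragment_len,
              x$insert_len_bounds[1], x$insert_len_bounds[2]))
  cat(sprintf("  both strands: %s; miRNA-like-site filter: %s\n",
              x$both_strands, x$apply_mirna_rules))
  invisible(x)
}
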