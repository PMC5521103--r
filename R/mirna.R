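#' miRNA-like trigger recognition rules
#'
#' Configuration for deciding whether a 21-nt siRNA could down-regulate a
#' transcript the way a plant miRNA recognises a functional target, used as
#' a secondary off-target filter on top of the per-window mismatch rule.
#' Under the defaults a site is functional when: at most one mismatch falls
#' in the 5' region (small-RNA positions 2-12), or two if the 3' portion
#' pairs perfectly with no loop; the presumptive cleavage site (positions
#' 10-11) pairs exactly; the 3' portion (positions 13 to the end) carries at
#' most two substitution mismatches and may bulge a target-side loop of at
#' most two unpaired nucleotides. Position 1 is never counted. G:U wobbles
#' count as mismatches unless `count_gu_as_match` is set.
#'
#' @param window_len Small-RNA length (matches the design window).
#' @param five_prime_region Length-2 integer vector: 1-based positions of the
#'   5' pairing region on the small RNA.
#' @param cleavage_positions Positions that must pair exactly (the strict
#'   reading of the cleavage-site requirement; set to `integer(0)` to only
#'   budget them inside the 5' region).
#' @param max_5p_mismatch Mismatch budget in the 5' region.
#' @param max_5p_mismatch_if_3p_perfect Relaxed 5' budget when the 3' portion
#'   pairs perfectly (no mismatch, no loop).
#' @param max_3p_mismatch Substitution-mismatch budget in the 3' portion.
#' @param max_3p_loop_nt Longest tolerated target-side loop in the 3'
#'   portion, nt.
#' @param count_gu_as_match Treat G:U wobble pairs as matches.
#' @return An object of class `mirna_rules`.
#' @export
mirna_rules <- function(window_len = 21L,
                        five_prime_region = c(2L, 12L),
                        cleavage_positions = c(10L, 11L),
                        max_5p_mismatch = 1L,
                        max_5p_mismatch_if_3p_perfect = 2L,
                        max_3p_mismatch = 2L,
                        max_3p_loop_nt = 2L,
                        count_gu_as_match = FALSE) {
  window_len <- as.integer(window_len)
  five_prime_region <- as.integer(five_prime_region)
  cleavage_positions <- as.integer(cleavage_positions)
  if (length(five_prime_region) != 2L ||
      five_prime_region[1] < 1L || five_prime_region[2] > window_len ||
      five_prime_region[1] > five_prime_region[2]) {
    abort("'five_prime_region' must be an increasing pair within 1..window_len.")
  }
  if (length(cleavage_positions) &&
      (min(cleavage_positions) < 1L || max(cleavage_positions) > window_len)) {
    abort("'cleavage_positions' must lie within 1..window_len.")
  }
  structure(
    list(window_len = window_len,
         five_prime_region = five_prime_region,
         cleavage_positions = cleavage_positions,
         max_5p_mismatch = as.integer(max_5p_mismatch),
         max_5p_mismatch_if_3p_perfect = as.integer(max_5p_mismatch_if_3p_perfect),
         max_3p_mismatch = as.integer(max_3p_mismatch),
         max_3p_loop_nt = as.integer(max_3p_loop_nt),
         count_gu_as_match = isTRUE(count_gu_as_match)),
    class = "mirna_rules")
}

#' @export
print.mirna_rules <- function(x, ...) {
  cat("<mirna_rules>\n")
  cat(sprintf("  5' region %d-%d: <= %d mismatches (%d if 3' perfect); cleavage %s exact\n",
              x$five_prime_region[1], x$five_prime_region[2],
              x$max_5p_mismatch, x$max_5p_mismatch_if_3p_perfect,
              paste(x$cleavage_positions, collapse = "-")))
  cat(sprintf("  3' portion: <= %d mismatches, loop <= %d nt; G:U as match: %s\n",
              x$max_3p_mismatch, x$max_3p_loop_nt, x$count_gu_as_match))
  invisible(x)
}

base_matches <- function(f, t, gu) {
  f == t | (gu & ((f == 1L & t == 3L) | (f == 0L & t == 2L)))
}

#' Score one siRNA against one candidate target site
#'
#' Evaluates a single small RNA / site pair under the miRNA target
#' recognition rules (see [mirna_rules()]). The site may be longer than the
#' small RNA by up to `max_3p_loop_nt + 1` nt; the surplus is modelled as a
#' target-side loop inserted somewhere in the 3' pairing region, and the
#' placement minimising 3' mismatches is reported. A loop one nucleotide
#' beyond the tolerated length is evaluated (and is never functional); longer
#' sites are rejected as inadmissible.
#'
#' @param sirna Small RNA as a DNA string, exactly `window_len` nt.
#' @param site Candidate target site, same orientation as the small RNA
#'   (identical sequence means perfect pairing).
#' @param rules A [mirna_rules()] configuration.
#' @return A one-row tibble: `loop_len`, `loop_after` (small-RNA position the
#'   loop follows, `NA` when loop-free), `mismatches_5p`, `mismatches_3p`,
#'   `cleavage_ok`, `functional`, `reason`.
#' @examples
#' evaluate_duplex(strrep("A", 21), strrep("A", 21))
#' @export
evaluate_duplex <- function(sirna, site, rules = mirna_rules()) {
  w <- rules$window_len
  sirna <- check_dna(sirna, "sirna")
  site <- check_dna(site, "site")
  if (nchar(sirna) != w) {
    abort(sprintf("'sirna' must be exactly %d nt (got %d).", w, nchar(sirna)))
  }
  L <- nchar(site) - w
  if (L < 0L || L > rules$max_3p_loop_nt + 1L) {
    abort(sprintf(
      "Site length %d admits no loop placement (allowed %d to %d nt).",
      nchar(site), w, w + rules$max_3p_loop_nt + 1L))
  }
  s <- dna_int(sirna); t <- dna_int(site)
  gu <- rules$count_gu_as_match
  r5 <- rules$five_prime_region
  p5 <- seq(r5[1], r5[2])
  m5 <- sum(!base_matches(s[p5], t[p5], gu))
  cleav_ok <- all(base_matches(s[rules$cleavage_positions],
                               t[rules$cleavage_positions], gu))
  p3 <- if (r5[2] < w) seq(r5[2] + 1L, w) else integer(0)
  if (L == 0L) {
    m3 <- sum(!base_matches(s[p3], t[p3], gu))
    loop_after <- NA_integer_
  } else {
    qs <- seq(r5[2], w - 1L)
    m3s <- vapply(qs, function(q) {
      tpos <- ifelse(p3 <= q, p3, p3 + L)
      sum(!base_matches(s[p3], t[tpos], gu))
    }, integer(1))
    best <- which.min(m3s)
    m3 <- m3s[best]
    loop_after <- qs[best]
  }
  functional <- cleav_ok &&
    L <= rules$max_3p_loop_nt &&
    m3 <= rules$max_3p_mismatch &&
    (m5 <= rules$max_5p_mismatch ||
       (m5 <= rules$max_5p_mismatch_if_3p_perfect && m3 == 0L && L == 0L))
  reason <- if (functional) {
    "functional miRNA-like site"
  } else if (!cleav_ok) {
    "cleavage positions mismatched"
  } else if (L > rules$max_3p_loop_nt) {
    sprintf("3' loop of %d nt exceeds %d", L, rules$max_3p_loop_nt)
  } else if (m3 > rules$max_3p_mismatch) {
    sprintf("%d mismatches in 3' portion exceed %d", m3, rules$max_3p_mismatch)
  } else {
    sprintf("%d mismatches in 5' region exceed budget", m5)
  }
  tibble(sirna = sirna, site = site, loop_len = L, loop_after = loop_after,
         mismatches_5p = m5, mismatches_3p = m3,
         cleavage_ok = cleav_ok, functional = functional, reason = reason)
}

# Fast scan used by the designer: all functional miRNA-like sites of every
# fragment window in `target`. Returns a tibble with 1-based coordinates;
# minus-strand hits are reported on the plus-strand coordinate system.
mirna_site_scan <- function(fragment, target, rules = mirna_rules(),
                            both_strands = TRUE) {
  w <- rules$window_len
  f <- dna_int(fragment)
  scan1 <- function(tseq, strand) {
    t <- dna_int(tseq)
    if (length(t) < w || length(f) < w) {
      return(tibble(window_start = integer(0), target_start = integer(0),
                    strand = character(0), loop_len = integer(0),
                    loop_after = integer(0), mismatches_5p = integer(0),
                    mismatches_3p = integer(0)))
    }
    hits <- as_tibble(cpp_mirna_scan(
      f, t, w,
      rules$five_prime_region[1], rules$five_prime_region[2],
      rules$cleavage_positions,
      rules$max_5p_mismatch, rules$max_5p_mismatch_if_3p_perfect,
      rules$max_3p_mismatch, rules$max_3p_loop_nt, rules$count_gu_as_match))
    if (strand == "-" && nrow(hits)) {
      m <- nchar(target)
      hits$target_start <- m - (hits$target_start + w + hits$loop_len - 1L) + 1L
    }
    hits$strand <- strand
    dplyr::relocate(hits, "window_start", "target_start", "strand")
  }
  out <- scan1(target, "+")
  if (both_strands) out <- dplyr::bind_rows(out, scan1(revcomp(target), "-"))
  out
}

#' Find functional miRNA-like sites of one siRNA in a target
#'
#' Scans every offset of `target` (and, optionally, its reverse complement)
#' and every admissible 3'-loop placement for sites the siRNA could
#' recognise as a miRNA-like trigger.
#'
#' @param sirna Small RNA as a DNA string, exactly `window_len` nt.
#' @param target Target sequence, at least `window_len` nt.
#' @param rules A [mirna_rules()] configuration.
#' @param both_strands Also scan the reverse complement of `target`.
#' @return A tibble of functional hits: `target_start` (1-based, on the given
#'   strand of `target`), `strand`, `loop_len`, `loop_after`,
#'   `mismatches_5p`, `mismatches_3p`. Zero rows when no site qualifies.
#' @export
find_mirna_like_sites <- function(sirna, target, rules = mirna_rules(),
                                  both_strands = FALSE) {
  sirna <- check_dna(sirna, "sirna")
  target <- check_dna(target, "target")
  if (nchar(sirna) != rules$window_len) {
    abort(sprintf("'sirna' must be exactly %d nt.", rules$window_len))
  }
  if (nchar(target) < rules$window_len) {
    abort("'target' is shorter than the window length.")
  }
  dplyr::select(mirna_site_scan(sirna, target, rules, both_strands),
                -"window_start")
}
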