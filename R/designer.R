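# Resolve which members act as off-targets for a design run: members with an
# explicit "offtarget" role; if none is marked, every member that is neither
# intended nor the source.
resolve_offtargets <- function(family, intended_ids, source_id = NULL) {
  fam <- as_gene_family(family)
  off <- fam[fam$role == "offtarget", , drop = FALSE]
  if (nrow(off) == 0L) {
    off <- fam[!(fam$id %in% c(intended_ids, source_id)), , drop = FALSE]
  }
  off
}

#' Per-window validity mask of a source gene against its off-targets
#'
#' For every window start of the source sequence, computes the minimum
#' scan-mode mismatch count over all off-targets and the number of
#' functional miRNA-like sites the window's siRNA would have on any
#' off-target, and flags the window valid when it clears both filters. The
#' mask is the search structure behind [search_fragments()]: a fragment is
#' specificity-valid iff the mask is true at every window start it contains.
#'
#' @param source Source sequence (DNA string).
#' @param offtargets A [gene_family()] or data frame (`id`, `seq`) of
#'   off-target transcripts; may have zero rows.
#' @param constraints A [design_constraints()] object.
#' @return A tibble of class `validity_mask` with columns `window_start`
#'   (1-based), `min_mismatch` (minimum over off-targets; `Inf`-like
#'   `window_len` when there are none), `mirna_hits`, `valid`. The
#'   per-off-target scan minima are attached as attribute `per_offtarget`
#'   (windows x off-targets integer matrix).
#' @export
validity_mask <- function(source, offtargets, constraints = design_constraints()) {
  source <- check_dna(source, "source")
  w <- constraints$window_len
  if (nchar(source) < w) abort("Source is shorter than the window length.")
  offtargets <- if (is.null(offtargets) || NROW(offtargets) == 0L) {
    tibble(id = character(0), seq = character(0))
  } else {
    as_gene_family(offtargets)
  }
  nw <- nchar(source) - w + 1L
  per_off <- matrix(w, nrow = nw, ncol = nrow(offtargets),
                    dimnames = list(NULL, offtargets$id))
  mirna_hits <- integer(nw)
  for (j in seq_len(nrow(offtargets))) {
    prof <- min_distance_scan(source, offtargets$seq[j], w,
                              both_strands = constraints$both_strands,
                              fragment_id = "source",
                              comparator_id = offtargets$id[j])
    per_off[, j] <- prof$mismatches
    if (constraints$apply_mirna_rules) {
      hits <- mirna_site_scan(source, offtargets$seq[j], constraints$mirna,
                              both_strands = constraints$both_strands)
      if (nrow(hits)) {
        tab <- table(factor(hits$window_start, levels = seq_len(nw)))
        mirna_hits <- mirna_hits + as.integer(tab)
      }
    }
  }
  min_mm <- if (ncol(per_off)) apply(per_off, 1L, min) else rep(w, nw)
  out <- new_tibble(
    tibble(window_start = seq_len(nw),
           min_mismatch = as.integer(min_mm),
           mirna_hits = mirna_hits,
           valid = min_mm >= constraints$min_mismatch & mirna_hits == 0L),
    class = "validity_mask")
  attr(out, "per_offtarget") <- per_off
  attr(out, "window_len") <- w
  out
}

#' Specificity verdict for a candidate fragment
#'
#' Checks the two off-target filters for one fragment: every fragment
#' window must sit at scan-mode Hamming distance of at least
#' `min_mismatch` (default 3) from every window of every off-target, on
#' both strands, and (by default) no fragment window may form a functional
#' miRNA-like site on any off-target. Windows at distance 1 or 2 still
#' silence, so any such window fails the fragment.
#'
#' @param fragment Fragment sequence (DNA string), at least one window long.
#' @param offtargets A [gene_family()] or data frame (`id`, `seq`) of
#'   off-targets; rows with other roles are screened too (pass what you mean
#'   to screen against). An empty set passes with a notice.
#' @param constraints A [design_constraints()] object.
#' @return A `design_verdict` object: `pass`, `per_offtarget_min` (named
#'   integer vector), and a `violations` tibble (`offtarget_id`,
#'   `window_start`, `type` of `"window_mismatch"` or `"mirna_site"`,
#'   `detail`). Use [tidy()] for the violations, [glance()] for a one-row
#'   summary.
#' @export
specificity_verdict <- function(fragment, offtargets,
                                constraints = design_constraints()) {
  fragment <- check_dna(fragment, "fragment")
  w <- constraints$window_len
  if (nchar(fragment) < w) abort("Fragment is shorter than the window length.")
  mask <- validity_mask(fragment, offtargets, constraints)
  per_off <- attr(mask, "per_offtarget")
  viol <- list()
  notice <- NULL
  if (ncol(per_off) == 0L) {
    notice <- "No off-targets supplied; specificity passes vacuously."
  } else {
    for (id in colnames(per_off)) {
      bad <- which(per_off[, id] < constraints$min_mismatch)
      if (length(bad)) {
        viol[[length(viol) + 1L]] <- tibble(
          offtarget_id = id, window_start = bad, type = "window_mismatch",
          detail = sprintf("window has only %d mismatch(es), below %d",
                           per_off[bad, id], constraints$min_mismatch))
      }
    }
  }
  if (constraints$apply_mirna_rules && ncol(per_off) > 0L) {
    offt <- as_gene_family(offtargets)
    for (j in seq_len(nrow(offt))) {
      hits <- mirna_site_scan(fragment, offt$seq[j], constraints$mirna,
                              both_strands = constraints$both_strands)
      if (nrow(hits)) {
        viol[[length(viol) + 1L]] <- tibble(
          offtarget_id = offt$id[j], window_start = hits$window_start,
          type = "mirna_site",
          detail = sprintf(
            "miRNA-like site at %s:%d (%s strand, %d nt loop, 5' mm %d, 3' mm %d)",
            offt$id[j], hits$target_start, hits$strand, hits$loop_len,
            hits$mismatches_5p, hits$mismatches_3p))
      }
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(offtarget_id = character(0), window_start = integer(0),
           type = character(0), detail = character(0))
  per_min <- if (ncol(per_off)) apply(per_off, 2L, min) else integer(0)
  structure(
    list(kind = "specificity",
         pass = nrow(violations) == 0L,
         per_offtarget_min = per_min,
         violations = violations,
         notice = notice,
         constraints = constraints),
    class = "design_verdict")
}

#' Efficacy verdict of a fragment for one intended target
#'
#' A fragment is expected to silence an intended target when it shares at
#' least one perfect `window_len`-mer with it (default threshold; raise
#' `min_exact_windows` in the constraints for more margin). Coverage is the
#' fraction of fragment windows matching the target with zero mismatches.
#' When the check fails but the longest identical stretch is still 11 nt or
#' more, a weak-silencing warning is attached: stretches that short have
#' been observed to reduce expression of homologues by roughly 15%, enough
#' to matter as an off-target but too little to count as silencing.
#'
#' @param fragment Fragment sequence.
#' @param intended A single intended target: either a one-row
#'   [gene_family()] slice or a DNA string.
#' @param constraints A [design_constraints()] object.
#' @param intended_id Label used in messages when `intended` is a string.
#' @return A `design_verdict` with `pass`, `coverage`, `exact_windows`,
#'   `longest_identical` and optional `warning`.
#' @export
efficacy_verdict <- function(fragment, intended,
                             constraints = design_constraints(),
                             intended_id = "intended") {
  fragment <- check_dna(fragment, "fragment")
  if (is.data.frame(intended)) {
    stopifnot(nrow(intended) == 1L)
    intended_id <- intended$id[[1]]
    intended <- intended$seq[[1]]
  }
  intended <- check_dna(intended, intended_id)
  w <- constraints$window_len
  if (nchar(fragment) < w) abort("Fragment is shorter than the window length.")
  prof <- min_distance_scan(fragment, intended, w,
                            both_strands = constraints$both_strands,
                            fragment_id = "fragment",
                            comparator_id = intended_id)
  exact <- sum(prof$mismatches == 0L)
  coverage <- exact / nrow(prof)
  f <- dna_int(fragment)
  lcs <- cpp_lcs_len(f, dna_int(intended))
  if (constraints$both_strands) {
    lcs <- max(lcs, cpp_lcs_len(f, dna_int(revcomp(intended))))
  }
  pass <- exact >= constraints$min_exact_windows
  warning_msg <- NULL
  if (!pass && lcs >= 11L) {
    warning_msg <- sprintf(
      "longest identical stretch with '%s' is %d nt (< %d): expect weak (~15%%) knockdown only",
      intended_id, lcs, w)
  }
  structure(
    list(kind = "efficacy", pass = pass, intended_id = intended_id,
         coverage = coverage, exact_windows = exact,
         longest_identical = lcs, warning = warning_msg,
         constraints = constraints),
    class = "design_verdict")
}

#' @export
print.design_verdict <- function(x, ...) {
  cat(sprintf("<design_verdict: %s %s>\n", x$kind,
              if (x$pass) "PASS" else "FAIL"))
  if (x$kind == "specificity") {
    if (!is.null(x$notice)) cat(" ", x$notice, "\n")
    if (length(x$per_offtarget_min)) {
      cat(sprintf("  per-off-target minimum window mismatches: %s\n",
                  paste(sprintf("%s=%d", names(x$per_offtarget_min),
                                x$per_offtarget_min), collapse = ", ")))
    }
    if (nrow(x$violations)) {
      cat(sprintf("  %d violation(s); first: %s\n", nrow(x$violations),
                  x$violations$detail[[1]]))
    }
  } else {
    cat(sprintf("  target '%s': %d exact window(s), coverage %.2f, longest identical %d nt\n",
                x$intended_id, x$exact_windows, x$coverage,
                x$longest_identical))
    if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  }
  invisible(x)
}

#' Search a source gene for specific, efficacious VIGS fragments
#'
#' Builds the per-window [validity_mask()] of the source against all
#' off-targets, enumerates maximal runs of valid window starts (a run of R
#' consecutive valid starts supports fragments up to R + window_len - 1
#' nt), keeps the maximal fragment of each run whose length fits the
#' configured bounds (anchored at the run start and capped at
#' `max_fragment_len`), requires efficacy against every intended member,
#' and ranks candidates by worst-case off-target margin (descending), mean
#' intended coverage (descending) and leftmost start.
#'
#' @param family A [gene_family()] with roles assigned (see [set_roles()]).
#' @param source_id Member to cut the fragment from; defaults to the first
#'   member with role `"intended"`.
#' @param constraints A [design_constraints()] object.
#' @return A tibble of class `fragment_candidates`, one row per candidate:
#'   `source_id`, `start`, `end` (1-based inclusive), `length`, `seq`,
#'   `min_offtarget_mismatch`, `mean_intended_coverage`, `verdict`, with
#'   list-columns `per_offtarget_min` and `intended_coverage` (named
#'   vectors). When empty, attribute `diagnostics` is a tibble naming, for
#'   each maximal valid run, the constraint that ended it.
#' @export
search_fragments <- function(family, source_id = NULL,
                             constraints = design_constraints()) {
  family <- as_gene_family(family)
  intended_ids <- family$id[family$role == "intended"]
  if (is.null(source_id)) {
    if (length(intended_ids) == 0L) {
      abort("No intended member: set roles with set_roles() or give source_id.")
    }
    source_id <- intended_ids[[1]]
  }
  if (length(intended_ids) == 0L) intended_ids <- source_id
  src <- family_member(family, source_id)
  w <- constraints$window_len
  if (nchar(src$seq) < constraints$min_fragment_len) {
    abort(sprintf("Source '%s' (%d nt) is shorter than min_fragment_len (%d nt).",
                  source_id, nchar(src$seq), constraints$min_fragment_len))
  }
  offt <- resolve_offtargets(family, intended_ids, source_id)
  mask <- validity_mask(src$seq, offt, constraints)
  per_off <- attr(mask, "per_offtarget")
  intended <- family[family$id %in% intended_ids, , drop = FALSE]

  empty_result <- function(diag) {
    out <- new_tibble(
      tibble(source_id = character(0), start = integer(0), end = integer(0),
             length = integer(0), seq = character(0),
             min_offtarget_mismatch = integer(0),
             mean_intended_coverage = double(0), verdict = character(0),
             per_offtarget_min = list(), intended_coverage = list()),
      class = "fragment_candidates")
    attr(out, "diagnostics") <- diag
    attr(out, "source_id") <- source_id
    out
  }

  runs <- with(rle(mask$valid), {
    ends <- cumsum(lengths)
    tibble(start = ends - lengths + 1L, len = lengths, valid = values)
  })
  runs <- runs[runs$valid, c("start", "len")]
  if (nrow(runs) == 0L) {
    return(empty_result(tibble(
      run_start = NA_integer_, supported_len = 0L,
      reason = "no window of the source clears the off-target filters")))
  }

  diag <- list()
  cands <- list()
  for (r in seq_len(nrow(runs))) {
    run_start <- runs$start[r]
    supported <- runs$len[r] + w - 1L   # longest fragment this run supports
    if (supported < constraints$min_fragment_len) {
      diag[[length(diag) + 1L]] <- tibble(
        run_start = run_start, supported_len = supported,
        reason = sprintf("min_fragment_len not met (run supports %d nt < %d)",
                         supported, constraints$min_fragment_len))
      next
    }
    len <- min(supported, constraints$max_fragment_len)
    start <- run_start
    end <- start + len - 1L
    frag <- substr(src$seq, start, end)
    eff <- purrr::map(seq_len(nrow(intended)), function(i) {
      efficacy_verdict(frag, intended[i, ], constraints)
    })
    eff_pass <- purrr::map_lgl(eff, "pass")
    if (!all(eff_pass)) {
      failed <- intended$id[!eff_pass]
      diag[[length(diag) + 1L]] <- tibble(
        run_start = run_start, supported_len = supported,
        reason = sprintf("efficacy failed for intended target(s): %s",
                         paste(failed, collapse = ", ")))
      next
    }
    win_idx <- seq(start, end - w + 1L)
    per_min <- if (ncol(per_off)) {
      apply(per_off[win_idx, , drop = FALSE], 2L, min)
    } else {
      setNames(integer(0), character(0))
    }
    coverage <- setNames(purrr::map_dbl(eff, "coverage"), intended$id)
    cands[[length(cands) + 1L]] <- tibble(
      source_id = source_id, start = start, end = end, length = len,
      seq = frag,
      min_offtarget_mismatch = if (length(per_min)) min(per_min) else w,
      mean_intended_coverage = mean(coverage),
      verdict = "pass",
      per_offtarget_min = list(per_min),
      intended_coverage = list(coverage))
  }
  if (length(cands) == 0L) {
    return(empty_result(dplyr::bind_rows(diag)))
  }
  out <- dplyr::bind_rows(cands) %>%
    dplyr::arrange(dplyr::desc(.data$min_offtarget_mismatch),
                   dplyr::desc(.data$mean_intended_coverage),
                   .data$start)
  out <- new_tibble(out, class = "fragment_candidates")
  attr(out, "diagnostics") <- if (length(diag)) dplyr::bind_rows(diag) else NULL
  attr(out, "source_id") <- source_id
  out
}

#' @export
print.fragment_candidates <- function(x, ...) {
  cat(sprintf("<fragment_candidates: %d candidate(s) from '%s'>\n",
              nrow(x), attr(x, "source_id") %||% "?"))
  if (nrow(x) == 0L && !is.null(attr(x, "diagnostics"))) {
    d <- attr(x, "diagnostics")
    if (nrow(d)) {
      cat("  no qualifying fragment; diagnostics:\n")
      for (i in seq_len(nrow(d))) {
        cat(sprintf("  - %s\n", d$reason[i]))
      }
    }
  }
  NextMethod()
}
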