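new_window_profile <- function(df, fragment_id, comparator_id, window_len,
                               mode, ...) {
  out <- new_tibble(df, class = "window_profile")
  attr(out, "fragment_id") <- fragment_id
  attr(out, "comparator_id") <- comparator_id
  attr(out, "window_len") <- window_len
  attr(out, "mode") <- mode
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Minimum-mismatch scan of a fragment against a transcript
#'
#' The authoritative specificity computation: for every `window_len`-mer of
#' the fragment, the minimum Hamming distance over *all* same-length windows
#' of the transcript, optionally minimised over the transcript's reverse
#' complement as well (VIGS produces dsRNA, so siRNAs of both polarities
#' arise). An off-target is safe from a fragment only when every one of
#' these minima is at least the mismatch threshold (3 under the defaults):
#' windows at distance 1 or 2 can still silence it.
#'
#' @param fragment Fragment sequence (DNA string), at least `window_len` nt.
#' @param transcript Comparator transcript (DNA string).
#' @param window_len Window length in nt (default 21).
#' @param both_strands Minimise over the transcript's reverse complement too.
#' @param fragment_id,comparator_id Optional labels carried into the result.
#' @return A `window_profile` tibble with one row per fragment window:
#'   `window_start` (1-based), `mismatches` (the minimum), `best_start`
#'   (1-based transcript position achieving it) and `strand`. If the
#'   transcript is shorter than the window a warning is issued and all
#'   minima are `window_len` (no placement exists). If the fragment is
#'   shorter than the window the profile is empty, with a warning.
#' @export
min_distance_scan <- function(fragment, transcript, window_len = 21L,
                              both_strands = TRUE,
                              fragment_id = "fragment",
                              comparator_id = "transcript") {
  fragment <- check_dna(fragment, fragment_id)
  transcript <- check_dna(transcript, comparator_id)
  w <- as.integer(window_len)
  empty <- function() new_window_profile(
    tibble(window_start = integer(0), mismatches = integer(0),
           best_start = integer(0), strand = character(0)),
    fragment_id, comparator_id, w, "scan")
  if (nchar(fragment) < w) {
    warn(sprintf("Fragment '%s' (%d nt) is shorter than the %d-nt window; empty profile.",
                 fragment_id, nchar(fragment), w))
    return(empty())
  }
  if (nchar(transcript) < w) {
    warn(sprintf("Transcript '%s' (%d nt) is shorter than the %d-nt window; all minima set to %d.",
                 comparator_id, nchar(transcript), w, w))
    nw <- nchar(fragment) - w + 1L
    return(new_window_profile(
      tibble(window_start = seq_len(nw), mismatches = rep(w, nw),
             best_start = NA_integer_, strand = NA_character_),
      fragment_id, comparator_id, w, "scan"))
  }
  f <- dna_int(fragment)
  fwd <- cpp_scan_min(f, dna_int(transcript), w)
  mins <- fwd$min; best <- fwd$argmin
  strand <- rep("+", length(mins))
  if (both_strands) {
    rev <- cpp_scan_min(f, dna_int(revcomp(transcript)), w)
    take <- rev$min < mins
    m <- nchar(transcript)
    # map a hit on the reverse complement back to plus-strand coordinates
    best[take] <- m - (rev$argmin[take] + w - 1L) + 1L
    mins[take] <- rev$min[take]
    strand[take] <- "-"
  }
  new_window_profile(
    tibble(window_start = seq_along(mins), mismatches = as.integer(mins),
           best_start = as.integer(best), strand = strand),
    fragment_id, comparator_id, w, "scan")
}

#' Per-window mismatch counts over a global alignment
#'
#' Reproduces the alignment-anchored window bookkeeping used to audit
#' candidate fragments against the corresponding region of each family
#' member: the fragment and comparator region are globally aligned, every
#' run of `window_len` consecutive fragment nucleotides is a window, and a
#' window's count is the number of substitution plus gap columns the
#' alignment places within it (gap columns are counted as mismatches — the
#' conservative choice for silencing risk). Use [min_distance_scan()] for
#' the authoritative any-register specificity check.
#'
#' @inheritParams min_distance_scan
#' @param comparator_region The comparator sequence region to align against.
#' @param ... Alignment scoring parameters passed to
#'   [Biostrings::pairwiseAlignment()] via [pairwise_identity()] defaults
#'   (match 1, mismatch -1, gap opening 2, gap extension 1).
#' @return A `window_profile` tibble (mode `"aligned"`) with `window_start`
#'   and `mismatches`, carrying the alignment and its mismatch columns as
#'   attributes for downstream site tabulation.
#' @export
window_mismatches_aligned <- function(fragment, comparator_region,
                                      window_len = 21L,
                                      fragment_id = "fragment",
                                      comparator_id = "comparator", ...) {
  fragment <- check_dna(fragment, fragment_id)
  comparator_region <- check_dna(comparator_region, comparator_id)
  w <- as.integer(window_len)
  if (nchar(fragment) < w) {
    warn(sprintf("Fragment '%s' (%d nt) is shorter than the %d-nt window; empty profile.",
                 fragment_id, nchar(fragment), w))
    return(new_window_profile(
      tibble(window_start = integer(0), mismatches = integer(0)),
      fragment_id, comparator_id, w, "aligned"))
  }
  aln <- Biostrings::pairwiseAlignment(
    fragment, comparator_region, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 2, gapExtension = 1, ...)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mismatch_col <- p != s | p == "-" | s == "-"
  frag_col <- which(p != "-")               # alignment column of fragment nt i
  nw <- nchar(fragment) - w + 1L
  cum <- cumsum(mismatch_col)
  counts <- vapply(seq_len(nw), function(i) {
    lo <- frag_col[i]; hi <- frag_col[i + w - 1L]
    cum[hi] - if (lo > 1L) cum[lo - 1L] else 0L
  }, numeric(1))
  new_window_profile(
    tibble(window_start = seq_len(nw), mismatches = as.integer(counts)),
    fragment_id, comparator_id, w, "aligned",
    aligned_fragment = paste(p, collapse = ""),
    aligned_comparator = paste(s, collapse = ""),
    mismatch_columns = which(mismatch_col),
    fragment_columns = frag_col)
}

#' Count discrete mismatch sites at a given per-window mismatch level
#'
#' Tabulates, from an aligned-mode profile, the number of distinct *sites*
#' at which exactly `k` nucleotides are mismatched within a window — the
#' summary used to audit why a construct silenced off-targets (sites with
#' one or two mismatches per 21-bp stretch still silence). Overlapping
#' qualifying windows are merged by an explicit convention: maximal runs of
#' consecutive window starts with count `k` collapse to one site while all
#' windows in the run share at least one common mismatch column; when the
#' running intersection empties, a new site begins. Raw per-window counts
#' remain available in the profile.
#'
#' @param profile A `window_profile` from [window_mismatches_aligned()].
#' @param k Exact number of mismatches per window defining a site.
#' @return Integer: the number of sites.
#' @export
tabulate_mismatch_sites <- function(profile, k) {
  if (!inherits(profile, "window_profile") ||
      !identical(attr(profile, "mode"), "aligned")) {
    abort("'profile' must come from window_mismatches_aligned().")
  }
  w <- attr(profile, "window_len")
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > w) {
    abort(sprintf("'k' must be between 0 and the window length (%d).", w))
  }
  starts <- profile$window_start[profile$mismatches == k]
  if (length(starts) == 0L) return(0L)
  mcols <- attr(profile, "mismatch_columns")
  fcol <- attr(profile, "fragment_columns")
  win_cols <- function(i) {
    lo <- fcol[i]; hi <- fcol[i + w - 1L]
    mcols[mcols >= lo & mcols <= hi]
  }
  sites <- 0L
  current <- NULL   # intersection of mismatch columns of the open site
  prev <- -2L
  for (i in starts) {
    cols <- win_cols(i)
    if (i != prev + 1L) {        # run break: close the open site
      sites <- sites + 1L
      current <- cols
    } else {
      shared <- intersect(current, cols)
      if (length(shared) == 0L && k > 0L) {
        sites <- sites + 1L
        current <- cols
      } else {
        current <- shared
      }
    }
    prev <- i
  }
  sites
}

#' Table of one- and two-mismatch sites of a fragment against family members
#'
#' Aligns the fragment to each comparator and counts the discrete sites at
#' which exactly one or exactly two nucleotides are mismatched within a
#' window (see [tabulate_mismatch_sites()]). Off-targets showing any such
#' site are at risk of silencing.
#'
#' @param fragment Fragment sequence.
#' @param family A [gene_family()] (or data frame with `id`, `seq`); the
#'   fragment is compared against every member.
#' @param window_len Window length in nt.
#' @param ks Mismatch levels to tabulate.
#' @param fragment_id Label for the fragment.
#' @return A tibble with one row per comparator and one `k<j>_sites` column
#'   per level in `ks`.
#' @export
mismatch_site_table <- function(fragment, family, window_len = 21L,
                                ks = c(1L, 2L), fragment_id = "fragment") {
  family <- as_gene_family(family)
  rows <- purrr::map(seq_len(nrow(family)), function(i) {
    prof <- window_mismatches_aligned(fragment, family$seq[i], window_len,
                                      fragment_id, family$id[i])
    counts <- purrr::map_int(ks, ~ tabulate_mismatch_sites(prof, .x))
    tibble(fragment_id = fragment_id, comparator_id = family$id[i],
           !!!setNames(as.list(counts), sprintf("k%d_sites", ks)))
  })
  dplyr::bind_rows(rows)
}

#' Export a window profile as TSV
#'
#' Writes the per-window mismatch counts with their identifying labels in
#' the four-column layout `fragment_id`, `comparator_id`,
#' `window_start_1based`, `mismatches`.
#'
#' @param profile A `window_profile`.
#' @param path Output path.
#' @return The exported tibble, invisibly.
#' @export
export_profile_tsv <- function(profile, path) {
  out <- tibble(fragment_id = attr(profile, "fragment_id"),
                comparator_id = attr(profile, "comparator_id"),
                window_start_1based = profile$window_start,
                mismatches = profile$mismatches)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Text report of an aligned-mode profile
#'
#' Renders the global alignment with a mark line (`*` under substitution or
#' gap columns) and annotates each maximal stretch of windows sharing a
#' mismatch count at or below `max_level`, the alignment-figure style used
#' to audit fragment specificity.
#'
#' @param profile An aligned-mode `window_profile`.
#' @param max_level Annotate stretches with counts up to this level.
#' @return Character vector of report lines (also printed invisibly via
#'   `cat()` when `print = TRUE`).
#' @param print Print the report to the console.
#' @export
profile_report <- function(profile, max_level = 2L, print = TRUE) {
  if (!identical(attr(profile, "mode"), "aligned")) {
    abort("'profile' must come from window_mismatches_aligned().")
  }
  p <- attr(profile, "aligned_fragment")
  s <- attr(profile, "aligned_comparator")
  marks <- strsplit(p, "")[[1]] != strsplit(s, "")[[1]]
  lines <- c(
    sprintf("fragment   %s", p),
    sprintf("comparator %s", s),
    sprintf("           %s", paste(ifelse(marks, "*", " "), collapse = "")))
  sel <- profile$mismatches <= max_level
  starts <- profile$window_start[sel]
  mm <- profile$mismatches[sel]
  if (length(starts)) {
    grp <- cumsum(c(TRUE, diff(starts) != 1L | diff(mm) != 0L))
    w <- attr(profile, "window_len")
    from <- as.integer(tapply(starts, grp, min))
    to <- as.integer(tapply(starts, grp, max)) + w - 1L
    mmg <- as.integer(tapply(mm, grp, function(x) x[1]))
    lines <- c(lines, "stretches (fragment coordinates, 1-based):",
               sprintf("  %d-%d: %d mismatch(es) per %d-bp window",
                       from, to, mmg, w))
  } else {
    lines <- c(lines, sprintf(
      "no %d-bp stretch with <= %d mismatches (all windows exceed %d)",
      attr(profile, "window_len"), max_level, max_level))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile: %s vs %s, %s mode, %d-nt windows>\n",
              attr(x, "fragment_id"), attr(x, "comparator_id"),
              attr(x, "mode"), attr(x, "window_len")))
  NextMethod()
}
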