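#' Partition a gene family into subgroups by sequence identity
#'
#' Single-linkage clustering on global pairwise percent identity: two
#' members join the same subgroup when a chain of pairs at or above the
#' identity threshold connects them. Subgroups formalise the operational
#' notion behind multi-target design — a cluster of near-identical members
#' that one fragment can co-silence — without building a phylogeny. Each
#' subgroup's representative is the member with the highest mean identity
#' to the rest of its subgroup (first in input order on ties); subgroup
#' labels are letters in order of first appearance.
#'
#' @param family A [gene_family()] tibble.
#' @param identity_threshold Percent identity in (0, 100] at which members
#'   are linked.
#' @param id_matrix Optional precomputed [identity_matrix()] (to avoid
#'   recomputing alignments).
#' @return A tibble of class `subgroup_partition`: `id`, `subgroup`,
#'   `is_representative`; the identity matrix and threshold are attached as
#'   attributes.
#' @export
partition_subgroups <- function(family, identity_threshold = 90,
                                id_matrix = NULL) {
  family <- as_gene_family(family)
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 100) {
    abort("'identity_threshold' must be in (0, 100].")
  }
  m <- id_matrix %||% identity_matrix(family)
  n <- nrow(family)
  cl <- if (n == 1L) {
    1L
  } else {
    hc <- hclust(as.dist(100 - m), method = "single")
    # single linkage at distance 100 - threshold; subtract a hair so pairs
    # exactly at the threshold stay linked despite float fuzz
    cutree(hc, h = 100 - identity_threshold + 1e-9)
  }
  labels_in_order <- unique(cl)
  subgroup <- letters[match(cl, labels_in_order)]
  rep_flag <- logical(n)
  for (g in unique(subgroup)) {
    idx <- which(subgroup == g)
    if (length(idx) == 1L) {
      rep_flag[idx] <- TRUE
    } else {
      mean_id <- vapply(idx, function(i) mean(m[i, setdiff(idx, i)]), 0)
      rep_flag[idx[which.max(mean_id)]] <- TRUE
    }
  }
  out <- new_tibble(
    tibble(id = family$id, subgroup = subgroup, is_representative = rep_flag),
    class = "subgroup_partition")
  attr(out, "identity_matrix") <- m
  attr(out, "identity_threshold") <- identity_threshold
  out
}

#' Assemble fragments into a chimeric VIGS insert
#'
#' Concatenates the given fragments (in the supplied order, no linker) into
#' one insert and re-screens it: each fragment must individually pass
#' specificity against the family's off-targets, and every
#' junction-spanning window — the `window_len - 1` novel k-mers minted at
#' each fragment boundary — is checked with the scan-mode mismatch rule and
#' the miRNA-like-site filter. The insert length is compared against the
#' vector's insert bounds (200-1500 bp for TRV by default); an
#' out-of-bounds length attaches a warning rather than failing the
#' construct.
#'
#' @param fragments A [search_fragments()] result (or any data frame with
#'   `source_id` and `seq`), one row per fragment, in assembly order.
#' @param family The [gene_family()] the fragments were designed against;
#'   off-targets are resolved as in [search_fragments()] (explicit
#'   `"offtarget"` roles, otherwise all members not among the fragments'
#'   sources or intended members).
#' @param constraints A [design_constraints()] object.
#' @param screen_junctions Set `FALSE` to skip junction re-screening (strict
#'   emulation of assembly protocols that do not re-screen; novel junction
#'   k-mers then go unchecked).
#' @return An object of class `chimeric_construct`: `fragments`,
#'   `insert_seq`, `total_len`, `junctions` tibble (`junction`, `position`,
#'   `window_start`, `min_mismatch`, `mirna_hits`, `pass`), `pass`,
#'   `length_ok`, `warnings`.
#' @export
build_chimera <- function(fragments, family,
                          constraints = design_constraints(),
                          screen_junctions = TRUE) {
  if (!is.data.frame(fragments) || nrow(fragments) == 0L ||
      !all(c("source_id", "seq") %in% names(fragments))) {
    abort("'fragments' must be a non-empty data frame with columns 'source_id' and 'seq'.")
  }
  family <- as_gene_family(family)
  intended_ids <- union(family$id[family$role == "intended"],
                        fragments$source_id)
  offt <- resolve_offtargets(family, intended_ids)
  w <- constraints$window_len

  for (i in seq_len(nrow(fragments))) {
    sv <- specificity_verdict(fragments$seq[[i]], offt, constraints)
    if (!sv$pass) {
      abort(sprintf(
        "Fragment %d (from '%s') fails specificity (%d violation(s)); fix fragments before assembly.",
        i, fragments$source_id[[i]], nrow(sv$violations)))
    }
  }

  insert <- paste(fragments$seq, collapse = "")
  total <- nchar(insert)
  boundaries <- cumsum(nchar(fragments$seq))
  boundaries <- boundaries[-length(boundaries)]  # junction after each but last

  junctions <- tibble(junction = integer(0), position = integer(0),
                      window_start = integer(0), min_mismatch = integer(0),
                      mirna_hits = integer(0), pass = logical(0))
  if (screen_junctions && length(boundaries)) {
    rows <- purrr::map(seq_along(boundaries), function(k) {
      b <- boundaries[k]
      lo <- max(1L, b - w + 2L)           # first junction-spanning window
      hi <- min(total - w + 1L, b)        # last one
      region <- substr(insert, lo, min(total, hi + w - 1L))
      mask <- validity_mask(region, offt, constraints)
      keep <- mask$window_start + lo - 1L >= lo &
        mask$window_start + lo - 1L <= hi
      tibble(junction = k, position = b,
             window_start = mask$window_start[keep] + lo - 1L,
             min_mismatch = mask$min_mismatch[keep],
             mirna_hits = mask$mirna_hits[keep],
             pass = mask$valid[keep])
    })
    junctions <- dplyr::bind_rows(rows)
  }

  length_ok <- total >= constraints$insert_len_bounds[1] &&
    total <= constraints$insert_len_bounds[2]
  warnings <- character(0)
  if (!length_ok) {
    warnings <- sprintf(
      "insert length %d nt is outside the vector bounds %d-%d nt",
      total, constraints$insert_len_bounds[1], constraints$insert_len_bounds[2])
  }
  structure(
    list(fragments = as_tibble(fragments), insert_seq = insert,
         total_len = total, junctions = junctions,
         pass = all(junctions$pass), length_ok = length_ok,
         warnings = warnings, primers = NULL, constraints = constraints),
    class = "chimeric_construct")
}

#' Overlap-extension PCR primers for a chimeric construct
#'
#' For each junction, emits the bridging oligo — the last `primer_half_len`
#' nt of the upstream fragment fused to the first `primer_half_len` nt of
#' the downstream fragment — and its reverse complement, plus forward and
#' reverse terminal primers from the insert ends. Melting temperatures use
#' the Wallace rule, 2(A+T) + 4(G+C), reported per half and for the whole
#' oligo.
#'
#' @param construct A [build_chimera()] result.
#' @param primer_half_len Half-length of bridging oligos, nt (default 20).
#' @return The construct with its `primers` tibble filled in: `name`,
#'   `role`, `junction`, `seq`, `tm_5p_half`, `tm_3p_half`, `tm`.
#' @export
design_overlap_primers <- function(construct, primer_half_len = 20L) {
  if (!inherits(construct, "chimeric_construct")) {
    abort("'construct' must come from build_chimera().")
  }
  h <- as.integer(primer_half_len)
  frags <- construct$fragments
  too_short <- nchar(frags$seq) < h
  if (any(too_short)) {
    abort(sprintf("Fragment(s) %s shorter than primer_half_len (%d nt).",
                  paste(which(too_short), collapse = ", "), h))
  }
  wallace <- function(s) {
    b <- strsplit(s, "")[[1]]
    2L * sum(b %in% c("A", "T")) + 4L * sum(b %in% c("G", "C"))
  }
  rows <- list(
    tibble(name = "terminal_fwd", role = "terminal", junction = NA_integer_,
           seq = substr(construct$insert_seq, 1L, h),
           tm_5p_half = NA_integer_, tm_3p_half = NA_integer_),
    tibble(name = "terminal_rev", role = "terminal", junction = NA_integer_,
           seq = revcomp(substr(construct$insert_seq,
                                construct$total_len - h + 1L,
                                construct$total_len)),
           tm_5p_half = NA_integer_, tm_3p_half = NA_integer_))
  if (nrow(frags) > 1L) {
    for (k in seq_len(nrow(frags) - 1L)) {
      up <- frags$seq[[k]]; down <- frags$seq[[k + 1L]]
      half5 <- substr(up, nchar(up) - h + 1L, nchar(up))
      half3 <- substr(down, 1L, h)
      bridge <- paste0(half5, half3)
      rows[[length(rows) + 1L]] <- tibble(
        name = sprintf("bridge_%d_fwd", k), role = "bridge", junction = k,
        seq = bridge, tm_5p_half = wallace(half5), tm_3p_half = wallace(half3))
      rows[[length(rows) + 1L]] <- tibble(
        name = sprintf("bridge_%d_rev", k), role = "bridge", junction = k,
        seq = revcomp(bridge),
        tm_5p_half = wallace(revcomp(half3)), tm_3p_half = wallace(revcomp(half5)))
    }
  }
  primers <- dplyr::bind_rows(rows)
  primers$tm <- vapply(primers$seq, wallace, integer(1), USE.NAMES = FALSE)
  construct$primers <- primers
  construct
}

#' @export
print.chimeric_construct <- function(x, ...) {
  cat(sprintf("<chimeric_construct: %d fragment(s), %d nt, %s>\n",
              nrow(x$fragments), x$total_len,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  order: %s\n", paste(x$fragments$source_id, collapse = " + ")))
  if (nrow(x$junctions)) {
    bad <- x$junctions[!x$junctions$pass, ]
    cat(sprintf("  junction windows screened: %d, failing: %d\n",
                nrow(x$junctions), nrow(bad)))
    if (nrow(bad)) {
      cat(sprintf("  first failure: junction %d, window at %d (min mismatch %d, miRNA hits %d)\n",
                  bad$junction[1], bad$window_start[1], bad$min_mismatch[1],
                  bad$mirna_hits[1]))
    }
  }
  for (wmsg in x$warnings) cat("  warning:", wmsg, "\n")
  if (!is.null(x$primers)) {
    cat(sprintf("  primers: %d oligo(s), Tm %d-%d\n", nrow(x$primers),
                min(x$primers$tm), max(x$primers$tm)))
  }
  invisible(x)
}

#' Write construct outputs to files
#'
#' Writes the insert FASTA, primers FASTA (when designed) and the junction
#' screening TSV next to the given prefix.
#'
#' @param construct A [build_chimera()] result.
#' @param prefix Output path prefix; files `<prefix>_insert.fasta`,
#'   `<prefix>_primers.fasta`, `<prefix>_junctions.tsv` are created.
#' @return Invisibly, the character vector of files written.
#' @export
export_construct <- function(construct, prefix) {
  if (!inherits(construct, "chimeric_construct")) {
    abort("'construct' must come from build_chimera().")
  }
  files <- character(0)
  ins <- paste0(prefix, "_insert.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(construct$insert_seq, "chimeric_insert")),
    ins)
  files <- c(files, ins)
  if (!is.null(construct$primers)) {
    pf <- paste0(prefix, "_primers.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(construct$primers$seq,
                                        construct$primers$name)), pf)
    files <- c(files, pf)
  }
  jf <- paste0(prefix, "_junctions.tsv")
  write.table(construct$junctions, jf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, jf)
  invisible(files)
}
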