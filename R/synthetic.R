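mutate_seq <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, "", USE.NAMES = FALSE)
  }
  chars
}

apply_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  out <- list()
  for (b in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) next                      # deletion
    if (u < rate) {                             # insertion after this base
      out[[length(out) + 1L]] <- c(b, sample(DNA_BASES, 1L))
    } else {
      out[[length(out) + 1L]] <- b
    }
  }
  unlist(out)
}

#' Simulate a homologous gene family with known subgroup structure
#'
#' Deterministic generator of synthetic families shaped like the
#' twelve-member, six-subgroup E2 gene group that motivates this package:
#' a uniform-random ancestor of `ancestor_len` nt spawns one ancestor per
#' subgroup by i.i.d. substitution at `between_divergence` per site
#' (uniform choice among the three alternative bases), and each member
#' derives from its subgroup ancestor at `within_divergence`. Under this
#' model the expected per-site match probability between two members at
#' per-site substitution probability p from a common ancestor is
#' (1 - p)^2 + p^2 / 3. Indels are off by default; a positive `indel_rate`
#' applies per-site deletions and insertions at `rate/2` each.
#'
#' @param n_subgroups Number of subgroups.
#' @param members_per_subgroup Integer vector (recycled to `n_subgroups`) of
#'   subgroup sizes; the default mimics the motivating family (3,3,2,2,1,1).
#' @param ancestor_len Ancestor length, nt.
#' @param between_divergence Per-site substitution probability between the
#'   root and each subgroup ancestor.
#' @param within_divergence Per-site substitution probability between a
#'   subgroup ancestor and each member.
#' @param indel_rate Per-site indel probability applied to each member.
#' @param seed Integer seed; the generator is byte-reproducible for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @return A [gene_family()] tibble with an extra `subgroup` column (ground
#'   truth labels a, b, ...), all roles `"neutral"`; the root ancestor is
#'   attached as attribute `ancestor`.
#' @examples
#' fam <- generate_family(seed = 1)
#' dplyr::count(fam, subgroup)
#' @export
generate_family <- function(n_subgroups = 6L,
                            members_per_subgroup = c(3L, 3L, 2L, 2L, 1L, 1L),
                            ancestor_len = 450L,
                            between_divergence = 0.15,
                            within_divergence = 0.02,
                            indel_rate = 0,
                            seed = NULL) {
  n_subgroups <- as.integer(n_subgroups)
  sizes <- rep_len(as.integer(members_per_subgroup), n_subgroups)
  if (sum(sizes) < 2L) abort("The family must have at least 2 members.")
  probs <- c(between = between_divergence, within = within_divergence,
             indel = indel_rate)
  if (any(probs < 0 | probs >= 1)) {
    abort("Divergence and indel probabilities must lie in [0, 1).")
  }
  with_local_seed(seed, {
    ancestor <- sample(DNA_BASES, ancestor_len, replace = TRUE)
    ids <- character(0); seqs <- character(0); grp <- character(0)
    member_no <- 0L
    for (g in seq_len(n_subgroups)) {
      sub_anc <- mutate_seq(ancestor, between_divergence)
      for (k in seq_len(sizes[g])) {
        member_no <- member_no + 1L
        chars <- mutate_seq(sub_anc, within_divergence)
        chars <- apply_indels(chars, indel_rate)
        ids <- c(ids, sprintf("m%02d", member_no))
        seqs <- c(seqs, paste(chars, collapse = ""))
        grp <- c(grp, letters[g])
      }
    }
    fam <- gene_family(ids, seqs, "neutral")
    fam$subgroup <- grp
    attr(fam, "ancestor") <- paste(ancestor, collapse = "")
    fam
  })
}

#' Plant a guaranteed design region into a family member
#'
#' Rewrites a region of the host member so that a known-good fragment
#' exists, for validation: under `guarantee = "min_mismatch"` the region is
#' rejection-sampled (uniform random sequence) until every window of the
#' region sits at scan-mode distance of at least `min_mismatch` from every
#' non-exempt member, on both strands, and (when `apply_mirna_rules`) forms
#' no functional miRNA-like site on any of them — i.e. until the region
#' fully qualifies as a specific fragment — verified by re-scanning; under
#' `guarantee = "exact_shared"` the host's region is copied verbatim into
#' the `shared_with` members (so efficacy holds for those co-targets).
#' When both behaviours are wanted, plant with `"min_mismatch"` and list
#' the co-targets in `shared_with`: they are exempted from the mismatch
#' guarantee and receive the planted region.
#'
#' @param family A [gene_family()] tibble.
#' @param host Host member ID.
#' @param start 1-based region start on the host; default centres the
#'   region.
#' @param region_len Region length, nt (default 80).
#' @param guarantee `"min_mismatch"` or `"exact_shared"`.
#' @param shared_with Member IDs that receive a verbatim copy of the region.
#' @param min_mismatch Per-window mismatch guarantee (default 3).
#' @param window_len Window length, nt.
#' @param apply_mirna_rules Also require the planted region to be free of
#'   functional miRNA-like sites on non-exempt members.
#' @param mirna A [mirna_rules()] configuration for that check.
#' @param seed Integer seed for the rejection sampler.
#' @param max_iter Rejection-sampling cap; exceeding it errors with a hint
#'   to raise the divergence or shrink the region.
#' @return The modified family; planted coordinates accumulate in the
#'   `planted` attribute (see [planted_regions()]).
#' @export
plant_region <- function(family, host, start = NULL, region_len = 80L,
                         guarantee = c("min_mismatch", "exact_shared"),
                         shared_with = NULL, min_mismatch = 3L,
                         window_len = 21L, apply_mirna_rules = TRUE,
                         mirna = mirna_rules(window_len = window_len),
                         seed = NULL, max_iter = 50L) {
  family <- as_gene_family(family)
  guarantee <- match.arg(guarantee)
  host_row <- family_member(family, host)
  host_len <- nchar(host_row$seq)
  region_len <- as.integer(region_len)
  if (region_len < window_len) abort("'region_len' must be at least window_len.")
  if (is.null(start)) start <- max(1L, (host_len - region_len) %/% 2L + 1L)
  start <- as.integer(start)
  end <- start + region_len - 1L
  if (start < 1L || end > host_len) {
    abort(sprintf("Region %d-%d does not fit in host '%s' (%d nt).",
                  start, end, host, host_len))
  }
  unknown <- setdiff(shared_with, family$id)
  if (length(unknown)) {
    abort(sprintf("'shared_with' names unknown member(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  exempt <- c(host, shared_with)
  others <- family[!(family$id %in% exempt), , drop = FALSE]

  region <- substr(host_row$seq, start, end)
  if (guarantee == "min_mismatch") {
    ok <- FALSE
    with_local_seed(seed, {
      for (iter in seq_len(max_iter)) {
        region <- random_dna(region_len)
        ok <- all(purrr::map_lgl(seq_len(nrow(others)), function(j) {
          prof <- min_distance_scan(region, others$seq[j], window_len,
                                    both_strands = TRUE,
                                    fragment_id = "planted",
                                    comparator_id = others$id[j])
          if (!all(prof$mismatches >= min_mismatch)) return(FALSE)
          !apply_mirna_rules ||
            nrow(mirna_site_scan(region, others$seq[j], mirna,
                                 both_strands = TRUE)) == 0L
        }))
        if (ok) break
      }
    })
    if (!ok) {
      abort(sprintf(
        "Could not plant a region meeting the >=%d-mismatch guarantee in %d tries; increase family divergence or shorten the region.",
        min_mismatch, max_iter))
    }
  }

  put <- function(seq, s) {
    paste0(substr(seq, 1L, s - 1L), region,
           substr(seq, s + region_len, nchar(seq)))
  }
  family$seq[family$id == host] <- put(host_row$seq, start)
  for (id in shared_with) {
    tseq <- family$seq[family$id == id]
    if (nchar(tseq) < end) {
      abort(sprintf("Region %d-%d does not fit in shared member '%s'.",
                    start, end, id))
    }
    family$seq[family$id == id] <- put(tseq, start)
  }
  planted <- rbind(attr(family, "planted"),
                   tibble(host = host, start = start, end = end,
                          guarantee = guarantee,
                          shared_with = paste(shared_with, collapse = ",")))
  attr(family, "planted") <- planted
  family
}

#' Planted-region coordinates of a synthetic family
#'
#' @param family A family returned by [plant_region()].
#' @return A tibble of planted regions (`host`, `start`, `end`, `guarantee`,
#'   `shared_with`), or `NULL` when nothing was planted.
#' @export
planted_regions <- function(family) {
  attr(family, "planted")
}
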