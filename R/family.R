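#' Construct a gene family table
#'
#' A gene family is a tibble with one row per member and columns `id`, `seq`
#' and `role`. The `role` column drives fragment design: `"intended"` members
#' must be silenced by a fragment, `"offtarget"` members must not be, and
#' `"neutral"` members are carried along (e.g. for clustering) but not
#' screened against. Sequences are validated (uppercase, strict A/C/G/T;
#' IUPAC ambiguity codes are rejected because window mismatch counts would be
#' ill-defined on them).
#'
#' @param id Character vector of unique member identifiers.
#' @param seq Character vector of coding sequences (A/C/G/T, case
#'   insensitive).
#' @param role Member roles, recycled; one of `"intended"`, `"offtarget"`,
#'   `"neutral"`.
#' @return A tibble of class `gene_family` with columns `id`, `seq`, `role`.
#' @examples
#' fam <- gene_family(c("g1", "g2"), c("ACGTACGTACGT", "ACGTACGAACGT"),
#'                    role = c("intended", "offtarget"))
#' fam
#' @export
gene_family <- function(id, seq, role = "neutral") {
  if (length(id) != length(seq)) abort("'id' and 'seq' must have equal length.")
  if (length(id) == 0L) abort("A gene family needs at least one member.")
  if (anyDuplicated(id)) {
    abort(sprintf("Duplicate member ID(s): %s.",
                  paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  role <- rep_len(as.character(role), length(id))
  bad_role <- setdiff(role, c("intended", "offtarget", "neutral"))
  if (length(bad_role)) {
    abort(sprintf("Unknown role(s): %s.", paste(bad_role, collapse = ", ")))
  }
  seq <- vapply(seq_along(seq), function(i) check_dna(seq[[i]], id[[i]]), "")
  new_tibble(list(id = as.character(id), seq = seq, role = role),
             class = "gene_family")
}

#' Read a gene family from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or single-line) into a [gene_family()]
#' tibble. Record IDs are the first whitespace-delimited token of each
#' header. IDs named in `roles` take that role; all others default to
#' `"neutral"`.
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @param roles Named character vector or list mapping record IDs to roles
#'   (`"intended"`, `"offtarget"`, `"neutral"`). Every name must match a
#'   record ID.
#' @return A [gene_family()] tibble.
#' @export
read_family <- function(path, roles = NULL) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("Failed to parse FASTA '%s': %s",
                                      path, conditionMessage(e))))
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' contains no records.", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  role <- rep("neutral", length(ids))
  if (!is.null(roles)) {
    roles <- unlist(roles)
    missing <- setdiff(names(roles), ids)
    if (length(missing)) {
      abort(sprintf("Role assigned to unknown record ID(s): %s.",
                    paste(missing, collapse = ", ")))
    }
    role[match(names(roles), ids)] <- unname(roles)
  }
  gene_family(ids, as.character(set), role)
}

#' Write a gene family to FASTA
#'
#' @param family A [gene_family()] tibble.
#' @param path Output file path.
#' @return `family`, invisibly.
#' @export
write_family <- function(family, path) {
  family <- as_gene_family(family)
  set <- Biostrings::DNAStringSet(setNames(family$seq, family$id))
  Biostrings::writeXStringSet(set, path)
  invisible(family)
}

#' Assign design roles to family members
#'
#' Convenience verb for pipelines: marks the given members as intended
#' targets and off-targets. By default every member not named in `intended`
#' or `offtarget` keeps (or is reset to) the `"neutral"` role.
#'
#' @param family A [gene_family()] tibble.
#' @param intended Character vector of member IDs to silence.
#' @param offtarget Character vector of member IDs to protect. Default: all
#'   members not in `intended`.
#' @return The family with updated `role` column.
#' @export
set_roles <- function(family, intended, offtarget = NULL) {
  family <- as_gene_family(family)
  unknown <- setdiff(c(intended, offtarget), family$id)
  if (length(unknown)) {
    abort(sprintf("Unknown member ID(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (is.null(offtarget)) offtarget <- setdiff(family$id, intended)
  family$role <- dplyr::case_when(
    family$id %in% intended ~ "intended",
    family$id %in% offtarget ~ "offtarget",
    .default = "neutral")
  family
}

as_gene_family <- function(x) {
  if (inherits(x, "gene_family")) return(x)
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x))) {
    role <- if ("role" %in% names(x)) x$role else "neutral"
    fam <- gene_family(x$id, x$seq, role)
    extra <- setdiff(names(x), names(fam))
    for (col in extra) fam[[col]] <- x[[col]]
    return(fam)
  }
  abort("Expected a gene_family or a data frame with columns 'id' and 'seq'.")
}

family_member <- function(family, id) {
  i <- match(id, family$id)
  if (is.na(i)) abort(sprintf("No family member named '%s'.", id))
  family[i, ]
}

#' Reverse complement of a DNA string
#'
#' @param seq A DNA string (A/C/G/T, case insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("AAACC") # "GGTTT"
#' @export
revcomp <- function(seq) {
  seq <- check_dna(seq, "sequence")
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

#' Percent identity of two sequences under global alignment
#'
#' Aligns the two sequences end to end (Needleman-Wunsch) and reports
#' 100 * matched columns / alignment columns, gap columns included in the
#' denominator. Scoring defaults: match +1, mismatch -1, gap opening -2, gap
#' extension -1. On the near-identical inputs this package targets, any
#' reasonable global aligner gives equivalent identities.
#'
#' @param a,b DNA strings.
#' @param match,mismatch Substitution scores.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_opening = 2, gap_extension = 1) {
  a <- check_dna(a, "a"); b <- check_dna(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension)
  unname(Biostrings::pid(aln, type = "PID1"))
}

#' Pairwise identity matrix of a family
#'
#' @param family A [gene_family()] tibble.
#' @param ... Passed on to [pairwise_identity()].
#' @return Symmetric numeric matrix of percent identities, diagonal 100,
#'   dimnames the member IDs.
#' @export
identity_matrix <- function(family, ...) {
  family <- as_gene_family(family)
  n <- nrow(family)
  m <- matrix(100, n, n, dimnames = list(family$id, family$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(family$seq[i], family$seq[j], ...)
      }
    }
  }
  m
}

#' Long-format pairwise identities
#'
#' @inheritParams identity_matrix
#' @return A tibble with columns `id1`, `id2`, `identity`, one row per
#'   unordered member pair.
#' @export
family_identity <- function(family, ...) {
  m <- identity_matrix(family, ...)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(id1 = rownames(m)[idx[, 1]],
         id2 = colnames(m)[idx[, 2]],
         identity = m[idx])
}
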