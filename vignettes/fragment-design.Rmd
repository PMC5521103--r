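---
title: "Designing specific VIGS fragments for highly homologous gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing specific VIGS fragments for highly homologous gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigsdesign)
library(dplyr)
```

## The problem

Virus-induced gene silencing (VIGS) knocks down a plant gene by infecting
the plant with a recombinant virus (typically *Tobacco rattle virus*, TRV)
carrying a fragment of that gene. Viral replication produces double-stranded
RNA that is diced into 21–24-nt siRNAs, and any transcript sufficiently
complementary to one of those siRNAs is degraded. When the gene of interest
belongs to a family of near-identical paralogues — ubiquitin-conjugating (E2)
enzymes are a classic case, with family groups of a dozen members above 90%
coding-sequence identity — almost every fragment of one member also silences
the others. Silencing "specifically" then requires quantitative control over
how similar the fragment is allowed to be to every non-target member.

A widely used heuristic holds that avoiding any shared identical 21-mer is
enough. Empirically it is not: off-target transcripts whose best 21-bp window
differs from the fragment by only one or even two nucleotides are still
silenced. The validated rule this package implements is stricter:

> a fragment is acceptable only if **every** 21-bp window it contains has
> **at least three mismatches** to **every** off-target transcript,

and, as a secondary filter, no 21-mer of the fragment may qualify as a
*miRNA-like trigger* on any off-target (below). On the efficacy side,
fragments of roughly **70 bp** are already sufficient for efficient
silencing — well below the ≥100 bp floor of common web design tools, and
short fragments are exactly what makes qualifying regions findable inside a
highly conserved family. Whole inserts of 200–1500 bp are suitable for the
TRV vector.

## The window engine

`min_distance_scan()` is the authoritative specificity computation. For a
fragment $f$ and transcript $t$ with window length $w = 21$:

$$ d_i \;=\; \min_{j,\;s \in \{+,-\}} \operatorname{Ham}\!\big(f[i..i+w-1],\; t_s[j..j+w-1]\big) $$

i.e. the minimum Hamming distance of each fragment window over *all*
registers of the transcript and, by default, of its reverse complement too
(the viral dsRNA yields siRNAs of both polarities, so screening one strand
only would miss half the risk; `both_strands = FALSE` is available but not
recommended). A fragment passes against an off-target iff $\min_i d_i \ge 3$.
The kernel is lag-based C++ ($O(nm)$), and the test suite pins it exactly —
not approximately — to an independent brute-force all-pairs oracle on
hundreds of random instances.

`window_mismatches_aligned()` is the companion *audit* view: it globally
aligns a fragment to the corresponding region of a family member and counts
substitution plus gap columns per window, reproducing the alignment-figure
bookkeeping used when dissecting why a construct silenced something it
should not have. Gap columns count as mismatches: an indel column is
non-consensus, and counting it is the conservative choice for silencing
risk. The scan, not the aligned view, is what the designer enforces — an
siRNA can match an off-target at any register, not just the aligned one.

`tabulate_mismatch_sites()` condenses an aligned profile into the number of
discrete *sites* with exactly $k$ mismatches per window. How overlapping
qualifying windows should merge into sites is not standardised anywhere we
know of, so the package states its convention explicitly: a maximal run of
consecutive windows with count $k$ is one site while all of its windows
share at least one mismatch column; when the running intersection empties, a
new site starts. The raw per-window counts are always retained, so nothing
downstream depends on this convention.

## The miRNA-like trigger filter

Plant miRNAs down-regulate targets they pair with imperfectly, so a 21-mer
that fails perfect complementarity can still act through a miRNA-like
mechanism — the leading explanation for why two-mismatch windows silence.
The secondary filter applies the classical artificial-miRNA target rules,
evaluated per siRNA/site pair (`evaluate_duplex()`, `mirna_rules()`):

* positions 2–12 of the small RNA (the 5′ region) tolerate **at most one**
  mismatch, or **two** if the 3′ portion pairs perfectly;
* the presumptive cleavage site, positions 10–11, must pair exactly;
* the 3′ portion (positions 13–21) tolerates at most two substitution
  mismatches and a target-side bulge ("mismatch loop") of at most 2 nt;
* position 1 is ignored throughout.

Three conventions deserve comment, because the source rules leave them
open. First, whether the cleavage positions must pair exactly or merely fit
inside the 5′ budget is ambiguous; the strict reading is implemented
(configurable through `cleavage_positions`). Second, the 3′ region boundary
is taken as position 13, the complement of the quoted 2–12 region. Third,
G:U wobble pairs count as mismatches — the rules never mention wobble — with
`count_gu_as_match = TRUE` available to relax that. Loops are modelled as
target-side insertions only; small-RNA-side bulges are out of scope. For a
site longer than 21 nt, every admissible loop placement (after positions
12–20) is tried and the most favourable one is reported, so the filter never
under-calls a site because of loop registration.

`find_mirna_like_sites()` scans all offsets and loop placements of a target;
the same kernel, over every fragment window, feeds the designer. The whole
rule engine is pinned to an exhaustive enumeration of all 0-, 1- and
2-mismatch placements crossed with loop lengths 0–3 (≈ 930 cases).

## Fragment search

`search_fragments()` screens one source gene against the family:

1. `validity_mask()` marks each window start of the source as valid iff its
   scan distance to every off-target is ≥ `min_mismatch` **and** (by
   default) it forms no functional miRNA-like site on any off-target.
2. Maximal runs of valid starts are enumerated. A run of $R$ consecutive
   valid starts supports fragments up to $R + w - 1$ nt; one candidate per
   run is emitted, anchored at the run start and capped at
   `max_fragment_len`. Runs supporting less than `min_fragment_len`
   (default 70 nt) are reported in the diagnostics instead — so a family
   whose best run supports only 69 nt returns an empty result that says
   exactly that, and lowering the bound to 69 recovers the fragment.
3. Efficacy: each candidate must share at least one exact 21-mer with every
   intended co-target (`efficacy_verdict()`; `min_exact_windows` raises the
   bar). No quantitative silencing threshold exists in the literature for
   the window-identity scale, so this default is a declared convention
   motivated by the observation that working designs rely on near-perfect
   identity between the fragment and its co-targets. When a fragment fails
   but still shares an identical stretch of ≥ 11 nt, a warning flags likely
   *weak* knockdown (~15% reduction has been reported for an 11-nt shared
   stretch) — too much similarity to ignore, too little to count as
   silencing.
4. Candidates are ranked by worst-case off-target margin (the minimum over
   off-targets of the per-window minimum mismatch count, descending), then
   mean intended coverage (descending), then leftmost start. The leftmost
   tie-break is arbitrary but deterministic; identical inputs always give
   identical output.

Passing is closed under taking subfragments (any ≥ 21-nt piece of a passing
fragment passes — its windows are a subset), and the valid-window set at
threshold $t$ is a subset of the set at $t - 1$; both properties are tested.

A degenerate source (shorter than `min_fragment_len`) is an error, not an
empty result. An empty off-target set passes vacuously with a notice.

## Subgroups and chimeric constructs

Multi-target designs exploit the family's internal structure: a cluster of
near-identical members (a *subgroup*) can be co-silenced by one fragment
from a representative member. `partition_subgroups()` formalises subgroups
as single-linkage clusters on global pairwise percent identity — an
operational replacement for tree building that needs no phylogenetics and
is exactly testable. The representative is the member with the highest mean
identity to the rest of its subgroup; first-in-input order breaks ties.
Partitions refine as the threshold rises, and at the default 90% the
generator's six planted subgroups are recovered with adjusted Rand index 1.

`build_chimera()` concatenates fragments (direct abutment, as in
overlap-extension PCR assembly; a linker option exists but defaults to
empty) and re-screens every *junction window*: concatenation mints
$w - 1$ novel 21-mers per boundary that none of the individual fragments
contained, and protocols that skip this step ship unscreened sequence. The
construct verdict is PASS iff every fragment passes and every junction
window passes — provably the same as brute-force re-screening of the whole
insert, and tested as such on random assemblies. Insert length is checked
against the 200–1500 bp vector bounds; an out-of-bounds insert is a warning
(the biology is vector-dependent), not a failure.

`design_overlap_primers()` emits, per junction, the bridging oligo (last 20
nt of the upstream fragment + first 20 nt of the downstream one) and its
reverse complement, plus terminal primers. Melting temperatures use the
Wallace rule, $2(A{+}T) + 4(G{+}C)$, reported per half and per oligo —
chosen for exact testability; nearest-neighbour thermodynamics is a
documented non-goal.

```{r chimera-example}
fam <- generate_family(seed = 20)
part <- partition_subgroups(fam, 90)
frags <- purrr::map_dfr(unique(part$subgroup), function(g) {
  rep_id <- part$id[part$subgroup == g & part$is_representative]
  fam |>
    set_roles(intended = part$id[part$subgroup == g]) |>
    search_fragments(source_id = rep_id) |>
    head(1)
})
con <- build_chimera(frags, set_roles(fam, intended = fam$id)) |>
  design_overlap_primers()
glance(con)
```

## The synthetic family generator

Real sequence IDs for the motivating family are not public, so validation
runs on synthetic families with known ground truth. `generate_family()`
draws a uniform-random ancestor (450 nt by default, the size of the
motivating ~450-bp E2 ORFs), derives one ancestor per subgroup by i.i.d.
substitution at `between_divergence` (default 0.15) with the replacement
base uniform over the three alternatives, and each member from its subgroup
ancestor at `within_divergence` (default 0.02). The default subgroup sizes
3, 3, 2, 2, 1, 1 mimic a twelve-member, six-subgroup family. Under this
model two sequences at per-site substitution probability $p$ from their
common ancestor match per site with probability $(1-p)^2 + p^2/3$ — the
closed form the calibration test checks the generator against (observed
mean identity within three standard errors over 50 seeds). Uniform base
composition and the Jukes–Cantor-like substitution scheme were chosen
precisely because they admit this closed form; GC bias and codon structure
are deliberately not modelled. Indels default to 0 — the alignments that
motivated the method are gap-free in the regions of interest — and a
positive `indel_rate` exists to exercise the gap-handling paths.

`plant_region()` rewrites a region of one member until it *qualifies*:
every window at scan distance ≥ 3 from every non-exempt member on both
strands, and no functional miRNA-like site on any of them (the second
condition matters — about one random 80-nt region in a few carries a rare
miRNA-functional window that would split the valid run). Verification is by
re-scanning, and the test suite re-verifies planted regions with the
independent brute-force oracle. `guarantee = "exact_shared"` instead copies
the host's region verbatim into chosen co-targets, creating ground truth
for the efficacy side.

What passing these tests shows — and what it does not: recovery of planted
regions across 100 seeded families demonstrates that the search is sound
and complete for the stated rule under the generator's assumptions
(independent sites, no repeats, no splice variants, no transcriptome
background beyond the family). It does not show that the rule itself is
biologically sufficient in a new system; screening against a full
transcriptome FASTA (supported by the same scan) and wet-lab validation
remain the user's responsibility.

## Conventions and numerics

* **Coordinates** are 1-based inclusive everywhere — input, API and reports
  — matching the R sequence ecosystem (IRanges/Biostrings).
* **Alphabet** is strict A/C/G/T; IUPAC ambiguity codes are rejected at
  validation with the record and position named, because a window mismatch
  count over ambiguity codes is ill-defined.
* **Alignment scoring** defaults: match +1, mismatch −1, gap opening −2,
  gap extension −1 (Needleman–Wunsch via Biostrings). On the near-identical
  inputs this tool targets, identity is insensitive to reasonable scoring
  changes; the parameters are exposed on `pairwise_identity()`.
* **Window length** is fixed per run; 21 nt — the shortest siRNA class —
  is the default and the conservative choice, since shorter windows make
  the ≥3-mismatch constraint harder to satisfy. Values up to 24 are
  accepted.
* **Validation problem sizes**: the shipped tests run the full acceptance
  battery at 200 random scan pairs, ≈ 930 rule-table cases, 100
  planted-recovery families, 20 clustering families and 50 random
  assemblies — sizes chosen so the whole suite completes in a few minutes
  on one core while keeping every check exact rather than sampled.

## Known limitations

No thermodynamic scoring (ΔG, secondary structure, target accessibility);
no silencing-efficiency prediction beyond window identity; no
vector-specific cloning details (att sites, backbones, restriction sites);
protein and RNA alphabets are out of scope. The scan is exact but
quadratic, which is instant for gene families and acceptable for a single
transcriptome pass, not for all-vs-all transcriptome screens.
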