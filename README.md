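# vigsdesign

Design of specific virus-induced gene silencing (VIGS) fragments for
highly homologous gene families.

## The problem

VIGS silences a plant gene by infecting the plant with a recombinant virus
(typically *Tobacco rattle virus*) carrying a fragment of that gene; the
viral dsRNA is processed into 21–24-nt siRNAs that degrade any sufficiently
similar transcript. Inside a family of near-identical paralogues — e.g.
twelve ubiquitin-conjugating (E2) enzyme genes above 90% identity — almost
any fragment co-silences unintended members. Off-targets are silenced even
when their best 21-bp window differs from the fragment by one or two
nucleotides, so the popular "no shared 21-mer" heuristic is not enough.

`vigsdesign` implements a stricter, validated rule as a reusable toolkit.
A fragment $f$ is accepted against off-targets $t$ only if every 21-bp
window sits at Hamming distance at least 3 from every register of every
off-target, on both strands:

$$\min_{i}\;\min_{j,\;s\in\{+,-\}} \operatorname{Ham}\big(f[i..i{+}20],\,t_s[j..j{+}20]\big)\;\ge\;3$$

and additionally no fragment 21-mer may qualify as a functional
**miRNA-like trigger** on any off-target (≤ 1 mismatch at small-RNA
positions 2–12 — or 2 with a perfect 3′ end —, exact pairing at the
cleavage site 10–11, ≤ 2-nt 3′ mismatch loop). Fragments of roughly
**70 bp** suffice for efficient silencing, which is what makes qualifying
regions findable inside conserved families; chimeric inserts of
200–1500 bp fit the TRV vector.

The package provides the sliding-window scan engine (exact, lag-based C++),
the miRNA-rule engine, a mask-based fragment search with efficacy checks
against intended co-targets, identity-based subgroup clustering with
representative selection, chimeric construct assembly with junction
re-screening and overlap-extension PCR primers, and a seeded synthetic
family generator with plantable ground-truth regions. Everything is
tibble-in/tibble-out and pipe-friendly, with `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

```r
library(vigsdesign)
library(dplyr)

fam <- generate_family(seed = 11) |>                  # 12 members, 6 subgroups
  plant_region("m01", start = 150, seed = 12) |>      # one designable region
  set_roles(intended = "m01")                         # others become off-targets

cands <- search_fragments(fam)
cands
#> <fragment_candidates: 1 candidate(s) from 'm01'>
#> # A tibble: 1 x 10
#>   source_id start   end length seq                        min_offtarget_mismatch
#>   <chr>     <int> <int>  <int> <chr>                                       <int>
#> 1 m01         131   246    116 ACAGCTCTGTGAAGCGATTCCTGGC...                    3
#> # i 4 more variables: mean_intended_coverage <dbl>, verdict <chr>,
#> #   per_offtarget_min <list>, intended_coverage <list>
```

One fragment qualifies: nucleotides 131–246 of `m01` (116 nt, containing
the planted 150–229 region). Every one of its 21-bp windows has at least
`min_offtarget_mismatch = 3` mismatches to the closest window of the
closest off-target, and `mean_intended_coverage = 1` means every window
matches the intended target exactly. The verdict can be re-audited:

```r
glance(specificity_verdict(cands$seq[1], filter(fam, role == "offtarget")))
#> # A tibble: 1 x 5
#>   kind        pass  n_offtargets worst_min_mismatch n_violations
#>   <chr>       <lgl>        <int>              <int>        <int>
#> 1 specificity TRUE            11                  3            0
```

Multi-gene constructs follow the subgroup-representative strategy: cluster
the family, take one qualifying fragment per subgroup, concatenate, and
re-screen the junction windows that concatenation mints:

```r
part <- partition_subgroups(fam, identity_threshold = 90)
frags <- purrr::map_dfr(unique(part$subgroup), function(g) {
  fam |>
    set_roles(intended = part$id[part$subgroup == g]) |>
    search_fragments(source_id = part$id[part$subgroup == g & part$is_representative]) |>
    head(1)
})
con <- build_chimera(frags, set_roles(fam, intended = fam$id)) |>
  design_overlap_primers()
glance(con)
```

`autoplot()` works on window profiles, validity masks, candidate sets and
subgroup partitions; `vignettes/fragment-design.Rmd` documents the model,
the rule conventions and the generator's assumptions. A command-line front
end (`inst/scripts/vigsdesign`) exposes `simulate`, `cluster`, `design`
and `chimera` subcommands.

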