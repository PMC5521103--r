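test_that("partitioning handles degenerate identity structures", {
  fam <- gene_family(c("a1", "a2", "a3"), rep(strrep("ACGT", 30), 3))
  p <- partition_subgroups(fam, 90)
  expect_equal(unique(p$subgroup), "a")
  expect_equal(sum(p$is_representative), 1)

  withr::with_seed(71, {
    fam2 <- gene_family(c("b1", "b2"), c(rand_seq(100), rand_seq(100)))
    p2 <- partition_subgroups(fam2, 100)
    expect_equal(p2$subgroup, c("a", "b"))
  })
})

test_that("planted subgroups are recovered exactly at 90% identity", {
  for (seed in 1:3) {
    fam <- generate_family(seed = seed)
    p <- partition_subgroups(fam, 90)
    expect_equal(mclust::adjustedRandIndex(p$subgroup, fam$subgroup), 1)
    # representative is the member with highest mean within-cluster identity
    m <- attr(p, "identity_matrix")
    for (g in unique(p$subgroup)) {
      idx <- which(p$subgroup == g)
      if (length(idx) > 1) {
        means <- vapply(idx, function(i) mean(m[i, setdiff(idx, i)]), 0)
        expect_equal(p$id[idx][p$is_representative[idx]],
                     p$id[idx][which.max(means)])
      }
    }
  }
})

test_that("partitions refine as the threshold rises", {
  fam <- generate_family(seed = 12)
  m <- identity_matrix(fam)
  lo <- partition_subgroups(fam, 70, id_matrix = m)
  hi <- partition_subgroups(fam, 95, id_matrix = m)
  # every high-threshold cluster sits inside one low-threshold cluster
  for (g in unique(hi$subgroup)) {
    parents <- unique(lo$subgroup[hi$subgroup == g])
    expect_length(parents, 1)
  }
})

test_that("a single-fragment construct is the fragment with no junctions", {
  withr::with_seed(72, {
    fam <- gene_family(c("g1", "g2"), c(rand_seq(300), rand_seq(300)),
                       role = c("intended", "offtarget"))
    cand <- search_fragments(fam, constraints = design_constraints(
      max_fragment_len = 150))
    expect_gt(nrow(cand), 0)
    con <- build_chimera(cand[1, ], fam)
    expect_equal(con$insert_seq, cand$seq[1])
    expect_equal(nrow(con$junctions), 0)
    expect_true(con$pass)
    # a lone 150-nt fragment sits below the 200-1500 nt insert bounds
    expect_false(con$length_ok)
    expect_match(con$warnings, "outside the vector bounds")
  })
})

test_that("junction windows minted at a boundary are screened and can fail", {
  withr::with_seed(73, {
    repeat {
      f1 <- rand_seq(80); f2 <- rand_seq(80)
      # off-target carrying the junction 21-mer at Hamming distance 2
      jwin <- paste0(substr(f1, 71, 80), substr(f2, 1, 11))
      jc <- strsplit(jwin, "")[[1]]
      flip <- c(A = "C", C = "A", G = "T", T = "G")
      jc[c(4, 12)] <- flip[jc[c(4, 12)]]
      off <- paste0(rand_seq(70), paste(jc, collapse = ""), rand_seq(70))
      # both fragments must individually pass against this off-target
      if (oracle_specific(f1, off) && oracle_specific(f2, off)) break
    }
    fam <- gene_family(c("s1", "s2", "off"), c(f1, f2, off),
                       role = c("intended", "intended", "offtarget"))
    frags <- tibble::tibble(source_id = c("s1", "s2"), seq = c(f1, f2))
    con <- build_chimera(frags, fam)
    expect_false(con$pass)
    bad <- con$junctions[!con$junctions$pass, ]
    expect_true(71 %in% bad$window_start)  # the minted 21-mer starts at 71
    expect_true(all(bad$junction == 1))
    # and the whole-insert brute force agrees
    expect_false(oracle_specific(con$insert_seq, off))
  })
})

test_that("assembly refuses fragments that fail specificity", {
  withr::with_seed(74, {
    off <- rand_seq(200)
    bad_frag <- substr(off, 50, 130)         # verbatim off-target match
    fam <- gene_family(c("s", "off"), c(rand_seq(200), off),
                       role = c("intended", "offtarget"))
    frags <- tibble::tibble(source_id = "s", seq = bad_frag)
    expect_error(build_chimera(frags, fam), "fails specificity")
  })
})

test_that("junction-aware verdict equals whole-insert brute-force screening", {
  n <- 0
  withr::with_seed(75, {
    for (trial in 1:8) {
      fam <- generate_family(n_subgroups = 4, members_per_subgroup = 1,
                             ancestor_len = 250, between_divergence = 0.25,
                             seed = 750 + trial)
      picks <- sample(fam$id, sample(2:3, 1))
      frags <- purrr::map_dfr(picks, function(id) {
        f <- set_roles(fam, intended = id)
        head(search_fragments(f), 1)
      })
      if (nrow(frags) < 2) next
      offt <- fam[!(fam$id %in% frags$source_id), ]
      fam_roles <- set_roles(fam, intended = frags$source_id)
      con <- build_chimera(frags, fam_roles)
      brute <- oracle_specific(con$insert_seq, offt$seq)
      expect_equal(con$pass, brute)
      n <- n + 1
    }
  })
  expect_gte(n, 5)
})

test_that("a six-fragment subgroup-representative chimera assembles in bounds", {
  fam <- generate_family(seed = 20)
  part <- partition_subgroups(fam, 90)
  frags <- purrr::map_dfr(unique(part$subgroup), function(g) {
    members <- part$id[part$subgroup == g]
    rep_id <- part$id[part$subgroup == g & part$is_representative]
    f <- set_roles(fam, intended = members)
    head(search_fragments(f, source_id = rep_id), 1)
  })
  expect_equal(nrow(frags), 6)
  # the whole family is targeted, so no member is an off-target
  con <- build_chimera(frags, set_roles(fam, intended = fam$id))
  expect_true(con$total_len >= 200 && con$total_len <= 1500)
  expect_true(con$length_ok)
  expect_equal(nrow(con$fragments), 6)
  g <- glance(con)
  expect_equal(g$n_junction_windows, 5 * 20)
})

test_that("overlap primers follow the bridge construction and Wallace rule", {
  up <- paste0(strrep("ACGT", 15), "AAAAAGGGGGTTTTTCCCCC")
  down <- paste0(strrep("AT", 10), strrep("GCTA", 15))
  fam <- gene_family(c("u", "d", "off"),
                     c(up, down, strrep("ACGGT", 40)),
                     role = c("intended", "intended", "offtarget"))
  frags <- tibble::tibble(source_id = c("u", "d"), seq = c(up, down))
  con <- build_chimera(frags, fam, design_constraints(apply_mirna_rules = FALSE,
                                                      min_mismatch = 1))
  con <- design_overlap_primers(con)
  primers <- tidy(con, "primers")
  bridge <- primers[primers$name == "bridge_1_fwd", ]
  expect_equal(bridge$seq, paste0("AAAAAGGGGGTTTTTCCCCC", strrep("AT", 10)))
  # Wallace rule on the first half: 10 A/T and 10 G/C
  expect_equal(bridge$tm_5p_half, 2 * 10 + 4 * 10)
  rev <- primers[primers$name == "bridge_1_rev", ]
  expect_equal(rev$seq, revcomp(bridge$seq))
  expect_equal(primers$seq[primers$name == "terminal_fwd"], substr(up, 1, 20))
  expect_equal(primers$seq[primers$name == "terminal_rev"],
               revcomp(substr(down, nchar(down) - 19, nchar(down))))
  expect_error(design_overlap_primers(con, primer_half_len = 100),
               "shorter than")
})

test_that("construct outputs export to FASTA and TSV", {
  withr::with_seed(76, {
    fam <- gene_family(c("g1", "g2"), c(rand_seq(300), rand_seq(300)),
                       role = c("intended", "offtarget"))
    cand <- search_fragments(fam)
    con <- design_overlap_primers(build_chimera(cand[1, ], fam))
    prefix <- file.path(withr::local_tempdir(), "con")
    files <- export_construct(con, prefix)
    expect_true(all(file.exists(files)))
    back <- Biostrings::readDNAStringSet(paste0(prefix, "_insert.fasta"))
    expect_equal(as.character(back[[1]]), con$insert_seq)
  })
})
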