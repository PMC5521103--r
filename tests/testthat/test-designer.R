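test_that("a two-mismatch window fails specificity; >=3 everywhere passes", {
  withr::with_seed(61, {
    frag <- rand_seq(80)
    # off-target sharing one 21-mer of the fragment at Hamming distance 2
    shared <- strsplit(substr(frag, 30, 50), "")[[1]]
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    shared[c(5, 15)] <- flip[shared[c(5, 15)]]
    off2 <- gene_family("off", paste0(rand_seq(60),
                                      paste(shared, collapse = ""),
                                      rand_seq(60)),
                        role = "offtarget")
    v2 <- specificity_verdict(frag, off2)
    expect_false(v2$pass)
    expect_true(any(tidy(v2)$type == "window_mismatch"))
    expect_lte(min(v2$per_offtarget_min), 2)

    # random unrelated off-target: every window >= 3 mismatches, no
    # miRNA-like site (re-checked by the independent oracle)
    repeat {
      off_ok <- rand_seq(200)
      if (oracle_specific(frag, off_ok)) break
    }
    v3 <- specificity_verdict(frag, gene_family("ok", off_ok, role = "offtarget"))
    expect_true(v3$pass)
    expect_equal(nrow(tidy(v3)), 0)
  })
})

test_that("a miRNA-like site fails an otherwise >=3-mismatch fragment", {
  withr::with_seed(62, {
    repeat {
      frag <- rand_seq(80)
      sirna <- substr(frag, 25, 45)
      # site: one 5' mismatch (position 6) plus a 2-nt loop in the 3' region
      s <- strsplit(sirna, "")[[1]]
      s[6] <- c(A = "C", C = "A", G = "T", T = "G")[s[6]]
      s <- append(s, rep(ifelse(s[16] == "G", "C", "G"), 2), after = 16L)
      site <- paste(s, collapse = "")
      off <- paste0(rand_seq(50), site, rand_seq(50))
      # keep only instances where the Hamming rule alone would pass
      if (all(oracle_scan(frag, off) >= 3)) break
    }
    v <- specificity_verdict(frag, gene_family("off", off, role = "offtarget"))
    expect_false(v$pass)
    expect_true(all(tidy(v)$type == "mirna_site"))
    expect_match(tidy(v)$detail[1], "miRNA-like site")
    # with the miRNA filter off, the Hamming rule passes it
    v_off <- specificity_verdict(
      frag, gene_family("off", off, role = "offtarget"),
      design_constraints(apply_mirna_rules = FALSE))
    expect_true(v_off$pass)
  })
})

test_that("empty off-target set passes with a notice", {
  withr::with_seed(63, frag <- rand_seq(80))
  v <- specificity_verdict(frag, NULL)
  expect_true(v$pass)
  expect_match(v$notice, "vacuously")
})

test_that("efficacy requires a shared exact window and warns on 11-nt stretches", {
  withr::with_seed(64, {
    gene <- rand_seq(300)
    frag <- substr(gene, 100, 179)
    v <- efficacy_verdict(frag, gene, intended_id = "g")
    expect_true(v$pass)
    expect_equal(v$coverage, 1)

    # fragment sharing only an 11-nt stretch: fail plus weak warning
    repeat {
      frag2 <- paste0(rand_seq(30), substr(gene, 50, 60), rand_seq(30))
      lcs_f <- max(vapply(list(gene, rc(gene)), function(g) {
        vigsdesign:::cpp_lcs_len(enc(frag2), enc(g))
      }, integer(1)))
      if (lcs_f == 11L) break
    }
    v2 <- efficacy_verdict(frag2, gene, intended_id = "g")
    expect_false(v2$pass)
    expect_match(v2$warning, "weak")
    expect_equal(v2$longest_identical, 11)

    # half-exact fragment: coverage reflects the zero-mismatch fraction
    frag3 <- paste0(substr(gene, 1, 50), rand_seq(30))
    v3 <- efficacy_verdict(frag3, gene, intended_id = "g")
    got_cov <- mean(oracle_scan(frag3, gene) == 0)
    expect_equal(v3$coverage, got_cov)
  })
})

test_that("search with no off-targets returns one maximal fragment from position 1", {
  withr::with_seed(65, {
    fam <- gene_family("g1", rand_seq(500), role = "intended")
    cands <- search_fragments(fam)
    expect_equal(nrow(cands), 1)
    expect_equal(cands$start, 1)
    expect_equal(cands$length, 400)   # capped at max_fragment_len
  })
})

test_that("search recovers a planted qualifying region and re-verifies", {
  n_ok <- 0
  for (seed in 1:10) {
    fam <- generate_family(seed = seed)
    start <- withr::with_seed(1000 + seed, sample(450 - 80 + 1, 1))
    fam <- plant_region(fam, "m05", start = start, region_len = 80,
                        seed = 2000 + seed)
    fam <- set_roles(fam, intended = "m05")
    cands <- search_fragments(fam)
    expect_gt(nrow(cands), 0)
    top <- cands[1, ]
    reg <- planted_regions(fam)
    overlap <- max(0, min(top$end, reg$end) - max(top$start, reg$start) + 1)
    if (overlap / 80 >= 0.9) n_ok <- n_ok + 1
    # independent brute-force re-check of every returned candidate
    off_seqs <- fam$seq[fam$role == "offtarget"]
    for (k in seq_len(nrow(cands))) {
      expect_true(oracle_specific(cands$seq[k], off_seqs))
    }
  }
  expect_gte(n_ok, 9)
})

test_that("runs supporting under 70 nt are rejected with a diagnostic", {
  fam <- make_sharp_run_family(seed = 91)
  cons70 <- design_constraints(apply_mirna_rules = FALSE)
  out <- search_fragments(fam, constraints = cons70)
  expect_equal(nrow(out), 0)
  diag <- attr(out, "diagnostics")
  expect_match(diag$reason, "min_fragment_len not met", all = FALSE)
  expect_match(diag$reason, "69 nt", all = FALSE)

  cons69 <- design_constraints(min_fragment_len = 69,
                               apply_mirna_rules = FALSE)
  out69 <- search_fragments(fam, constraints = cons69)
  expect_equal(nrow(out69), 1)
  expect_equal(out69$length, 69)
  expect_equal(out69$start, 66)
})

test_that("subfragment closure and threshold monotonicity hold", {
  withr::with_seed(66, {
    fam <- generate_family(n_subgroups = 3, members_per_subgroup = 2,
                           ancestor_len = 250, between_divergence = 0.25,
                           seed = 660)
    fam <- plant_region(fam, "m01", region_len = 90, seed = 661)
    fam <- set_roles(fam, intended = "m01")
    cands <- search_fragments(fam)
    expect_gt(nrow(cands), 0)
    frag <- cands$seq[1]
    off <- fam[fam$role == "offtarget", ]
    cons <- design_constraints()
    expect_true(specificity_verdict(frag, off, cons)$pass)
    # every >= 21-nt subfragment of a passing fragment passes
    for (i in 1:5) {
      s <- sample(nchar(frag) - 21 + 1, 1)
      ends <- (s + 20):nchar(frag)
      e <- ends[sample.int(length(ends), 1)]
      expect_true(specificity_verdict(substr(frag, s, e), off, cons)$pass)
    }
    # valid windows at threshold t are a subset of those at t - 1
    src <- fam$seq[fam$id == "m01"]
    m3 <- validity_mask(src, off, design_constraints(min_mismatch = 3))
    m2 <- validity_mask(src, off, design_constraints(min_mismatch = 2))
    expect_true(all(!m3$valid | m2$valid))
  })
})

test_that("search is deterministic and errors on short sources", {
  fam <- generate_family(seed = 8) %>% set_roles(intended = "m01")
  a <- search_fragments(fam)
  b <- search_fragments(fam)
  expect_identical(as.data.frame(a), as.data.frame(b))
  short <- gene_family("s", strrep("ACGT", 15), role = "intended")
  expect_error(search_fragments(short), "shorter than min_fragment_len")
})
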