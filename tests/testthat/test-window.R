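test_that("aligned-mode windows count substitutions by brute enumeration", {
  frag <- strrep("ACGTA", 5)                    # 25 nt
  expect_equal(window_mismatches_aligned(frag, frag)$mismatches, rep(0, 5))

  # differ at fragment positions 6 and 13 (1-based)
  comp <- strsplit(frag, "")[[1]]
  comp[6] <- "T"; comp[13] <- "A"
  comp <- paste(comp, collapse = "")
  prof <- window_mismatches_aligned(frag, comp)
  # brute force: window i covers positions i..i+20
  expected <- vapply(1:5, function(i) {
    sum(c(6, 13) >= i & c(6, 13) <= i + 20)
  }, numeric(1))
  expect_equal(prof$mismatches, expected)   # all windows cover both -> 2,2,2,2,2
})

test_that("a comparator deletion adds one to every window covering the gap", {
  withr::with_seed(21, frag <- rand_seq(30))
  comp <- paste0(substr(frag, 1, 14), substr(frag, 16, 30))  # delete nt 15
  prof <- window_mismatches_aligned(frag, comp)
  # fragment position 15 is a gap column in the alignment; windows 1..10 all
  # cover it (window i spans i..i+20), and nothing else differs
  expect_equal(prof$mismatches, rep(1, 10))
})

test_that("short fragments give an empty aligned profile with a warning", {
  expect_warning(p <- window_mismatches_aligned("ACGTACGT", "ACGTACGT"),
                 "shorter than")
  expect_equal(nrow(p), 0)
})

test_that("scan mode equals the brute-force all-pairs minimum exactly", {
  withr::with_seed(101, {
    for (trial in 1:25) {
      f <- rand_seq(sample(70:120, 1))
      t <- rand_seq(sample(150:300, 1))
      for (bs in c(TRUE, FALSE)) {
        got <- min_distance_scan(f, t, both_strands = bs)$mismatches
        expect_identical(got, oracle_scan(f, t, 21L, bs))
      }
    }
  })
})

test_that("the lag-based oracle agrees with a naive triple loop", {
  withr::with_seed(77, {
    for (trial in 1:5) {
      f <- rand_seq(40); t <- rand_seq(60)
      expect_identical(oracle_scan(f, t, 21L, TRUE),
                       oracle_scan_naive(f, t, 21L, TRUE))
    }
  })
})

test_that("scan handles verbatim and reverse-complement containment", {
  withr::with_seed(13, {
    f <- rand_seq(60)
    t <- paste0(rand_seq(40), f, rand_seq(30))
    expect_true(all(min_distance_scan(f, t)$mismatches == 0))
    rt <- rc(t)
    expect_true(all(min_distance_scan(f, rt, both_strands = TRUE)$mismatches == 0))
    sense_only <- min_distance_scan(f, rt, both_strands = FALSE)$mismatches
    expect_identical(sense_only, oracle_scan(f, rt, 21L, FALSE))
  })
})

test_that("scan strand symmetry and transcript-extension monotonicity hold", {
  withr::with_seed(31, {
    f <- rand_seq(80)
    t <- rand_seq(200)
    both <- min_distance_scan(f, t, both_strands = TRUE)$mismatches
    sense <- min_distance_scan(f, t, both_strands = FALSE)$mismatches
    anti <- min_distance_scan(f, rc(t), both_strands = FALSE)$mismatches
    expect_identical(both, pmin(sense, anti))
    longer <- min_distance_scan(f, paste0(t, rand_seq(60)))$mismatches
    expect_true(all(longer <= both))
  })
})

test_that("scan counts never exceed aligned counts for the matched region", {
  withr::with_seed(41, {
    f <- rand_seq(90)
    region <- strsplit(f, "")[[1]]
    pos <- sample(90, 8)
    flip <- c(A = "G", C = "T", G = "A", T = "C")
    region[pos] <- flip[region[pos]]
    t <- paste(region, collapse = "")
    scan <- min_distance_scan(f, t)$mismatches
    aligned <- window_mismatches_aligned(f, t)$mismatches
    expect_true(all(scan <= aligned))
  })
})

test_that("a short transcript yields saturated counts with a warning", {
  expect_warning(p <- min_distance_scan(strrep("ACGT", 8), "ACGT"), "shorter")
  expect_true(all(p$mismatches == 21))
})

test_that("mismatch sites merge per the shared-column convention", {
  withr::with_seed(51, base <- rand_seq(60))
  expect_equal(tabulate_mismatch_sites(
    window_mismatches_aligned(base, base), 1), 0)
  expect_equal(tabulate_mismatch_sites(
    window_mismatches_aligned(base, base), 2), 0)

  # one substitution at position 30 of a 60-nt pair: windows 10..30 all have
  # count 1 and share that column -> one site at k=1, none at k=2
  one <- strsplit(base, "")[[1]]
  one[30] <- c(A = "C", C = "A", G = "T", T = "G")[one[30]]
  prof1 <- window_mismatches_aligned(base, paste(one, collapse = ""))
  expect_equal(tabulate_mismatch_sites(prof1, 1), 1)
  expect_equal(tabulate_mismatch_sites(prof1, 2), 0)

  # two substitutions 40 nt apart in an 80-nt pair: no window covers both
  withr::with_seed(52, base80 <- rand_seq(80))
  two <- strsplit(base80, "")[[1]]
  for (p in c(20, 60)) two[p] <- c(A = "C", C = "A", G = "T", T = "G")[two[p]]
  prof2 <- window_mismatches_aligned(base80, paste(two, collapse = ""))
  expect_equal(tabulate_mismatch_sites(prof2, 1), 2)

  expect_error(tabulate_mismatch_sites(prof2, -1), "between 0")
  expect_error(tabulate_mismatch_sites(prof2, 22), "between 0")
})

test_that("site tables tabulate per comparator", {
  withr::with_seed(53, src <- rand_seq(70))
  one <- strsplit(src, "")[[1]]
  one[35] <- c(A = "C", C = "A", G = "T", T = "G")[one[35]]
  fam <- gene_family(c("same", "one_mm"), c(src, paste(one, collapse = "")))
  tab <- mismatch_site_table(src, fam)
  expect_equal(tab$k1_sites, c(0, 1))
  expect_equal(tab$k2_sites, c(0, 0))
})

test_that("profiles export as TSV and render a text report", {
  withr::with_seed(54, a <- rand_seq(40))
  b <- strsplit(a, "")[[1]]
  b[20] <- c(A = "C", C = "A", G = "T", T = "G")[b[20]]
  prof <- window_mismatches_aligned(a, paste(b, collapse = ""),
                                    fragment_id = "fr", comparator_id = "cmp")
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_profile_tsv(prof, path)
  back <- read.delim(path)
  expect_equal(back$mismatches, prof$mismatches)
  expect_equal(back$fragment_id[1], "fr")
  lines <- profile_report(prof, print = FALSE)
  expect_true(any(grepl("1 mismatch", lines)))
})
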