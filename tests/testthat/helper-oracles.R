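# Independent reference implementations used to verify the package. These
# deliberately use different algorithms from the package internals.

BASES <- c("A", "C", "G", "T")

enc <- function(seq) match(strsplit(seq, "")[[1]], BASES) - 1L

rand_seq <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

rc <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# All-pairs minimum Hamming distance per fragment window, computed lag by
# lag with vectorised rolling sums (the package kernel iterates window
# pairs in C++ with early exit).
oracle_scan <- function(fragment, transcript, w = 21L, both_strands = TRUE) {
  f <- enc(fragment)
  scan1 <- function(t) {
    n <- length(f); m <- length(t)
    nw <- n - w + 1L
    mins <- rep(w, nw)
    if (m < w || nw < 1L) return(mins)
    for (d in seq(-(n - w), m - w)) {
      i0 <- max(0L, -d); i1 <- min(n, m - d) - 1L
      if (i1 - i0 + 1L < w) next
      mm <- as.integer(f[(i0 + 1L):(i1 + 1L)] != t[(i0 + 1L):(i1 + 1L) + d])
      sums <- cumsum(mm)
      k <- length(mm) - w + 1L
      win <- sums[w:(w + k - 1L)] - c(0L, sums[seq_len(k - 1L)])
      idx <- i0 + seq_len(k)          # 1-based fragment window starts
      keep <- idx <= nw
      mins[idx[keep]] <- pmin(mins[idx[keep]], win[keep])
    }
    mins
  }
  out <- scan1(enc(transcript))
  if (both_strands) out <- pmin(out, scan1(enc(rc(transcript))))
  as.integer(out)
}

# Tiny triple-loop scan used to sanity-check oracle_scan itself.
oracle_scan_naive <- function(fragment, transcript, w = 21L,
                              both_strands = TRUE) {
  f <- strsplit(fragment, "")[[1]]
  strands <- list(strsplit(transcript, "")[[1]])
  if (both_strands) strands <- c(strands, list(strsplit(rc(transcript), "")[[1]]))
  nw <- length(f) - w + 1L
  vapply(seq_len(nw), function(i) {
    best <- w
    for (t in strands) {
      if (length(t) < w) next
      for (j in seq_len(length(t) - w + 1L)) {
        d <- sum(f[i:(i + w - 1L)] != t[j:(j + w - 1L)])
        if (d < best) best <- d
      }
    }
    as.integer(best)
  }, integer(1))
}

# Rule-faithful single-duplex evaluator: enumerates every loop placement in
# plain loops and applies the stated rule. Position 1 ignored; 5' region
# 2..12; cleavage 10-11 strict; 3' region 13..w with target-side loops.
oracle_duplex_functional <- function(sirna, site, w = 21L,
                                     max5 = 1L, max5_relaxed = 2L,
                                     max3 = 2L, max_loop = 2L) {
  s <- strsplit(sirna, "")[[1]]
  t <- strsplit(site, "")[[1]]
  L <- length(t) - w
  if (L < 0L) stop("site too short")
  qs <- if (L == 0L) w else 12:(w - 1L)
  for (q in qs) {
    m5 <- sum(s[2:12] != t[2:12])
    cleav_ok <- s[10] == t[10] && s[11] == t[11]
    m3 <- 0L
    for (p in 13:w) {
      tp <- if (p <= q) p else p + L
      if (s[p] != t[tp]) m3 <- m3 + 1L
    }
    functional <- cleav_ok && L <= max_loop && m3 <= max3 &&
      (m5 <= max5 || (m5 <= max5_relaxed && m3 == 0L && L == 0L))
    if (functional) return(TRUE)
  }
  FALSE
}

# Any functional miRNA-like site of any fragment w-mer in target?
# Vectorised 5' prescreen per window, then plain-loop placement checks.
oracle_mirna_any <- function(fragment, target, w = 21L, both_strands = TRUE) {
  strands <- list(target)
  if (both_strands) strands <- c(strands, list(rc(target)))
  f <- strsplit(fragment, "")[[1]]
  nw <- length(f) - w + 1L
  for (tg in strands) {
    t <- strsplit(tg, "")[[1]]
    m <- length(t)
    if (m < w) next
    for (i in seq_len(nw)) {
      s <- f[i:(i + w - 1L)]
      js <- seq_len(m - w + 1L)
      mm <- matrix(vapply(1:12, function(p) s[p] != t[js + p - 1L],
                          logical(length(js))), nrow = length(js))
      m5 <- rowSums(mm[, 2:12, drop = FALSE])
      cleav <- !mm[, 10] & !mm[, 11]
      for (j in js[m5 <= 2L & cleav]) {
        for (L in 0:2) {
          if (j + w + L - 1L > m) next
          site <- paste(t[j:(j + w + L - 1L)], collapse = "")
          if (oracle_duplex_functional(paste(s, collapse = ""), site, w)) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

# Full brute-force specificity re-check of one fragment.
oracle_specific <- function(fragment, offtarget_seqs, w = 21L,
                            min_mismatch = 3L, mirna = TRUE,
                            both_strands = TRUE) {
  for (t in offtarget_seqs) {
    if (any(oracle_scan(fragment, t, w, both_strands) < min_mismatch)) {
      return(FALSE)
    }
    if (mirna && oracle_mirna_any(fragment, t, w, both_strands)) return(FALSE)
  }
  TRUE
}

# Build a site from a 21-mer by mutating the given 1-based positions and
# optionally inserting a loop after position `loop_after`.
make_site <- function(sirna, mm_at = integer(0), loop_len = 0L,
                      loop_after = 16L) {
  s <- strsplit(sirna, "")[[1]]
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  s[mm_at] <- flip[s[mm_at]]
  if (loop_len > 0L) {
    ins <- rep(ifelse(s[loop_after] == "G", "C", "G"), loop_len)
    s <- append(s, ins, after = loop_after)
  }
  paste(s, collapse = "")
}

# Family whose only qualifying run supports exactly `run_nt` nucleotides:
# one off-target identical to the source except a planted region carrying a
# period-7 mismatch pattern (exactly 3 mismatches in every interior 21-bp
# window, at most 2 in every window that straddles a region edge).
make_sharp_run_family <- function(seed, src_len = 200L, region_start = 66L,
                                  run_nt = 69L) {
  withr::with_seed(seed, {
    src <- rand_seq(src_len)
    off <- src
    chars <- strsplit(src, "")[[1]]
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    mut_pos <- region_start - 1L + seq(7L, run_nt - 6L, by = 7L)
    chars[mut_pos] <- flip[chars[mut_pos]]
    gene_family(c("src", "off"), c(paste(chars, collapse = ""), off),
                role = c("intended", "offtarget"))
  })
}
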