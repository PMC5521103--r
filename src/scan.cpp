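#include <Rcpp.h>
using namespace Rcpp;

// Sequences arrive encoded as integers A=0, C=1, G=2, T=3.

static inline bool base_match(int f, int t, bool gu_as_match) {
  if (f == t) return true;
  if (gu_as_match) {
    // Sense-strand bookkeeping: guide G:U wobble shows up as (C, T),
    // guide U:G as (A, G), fragment base first.
    if (f == 1 && t == 3) return true;
    if (f == 0 && t == 2) return true;
  }
  return false;
}

// Minimum Hamming distance of every fragment window against all same-length
// windows of one transcript strand, computed lag by lag with a rolling
// window sum (O(n*m) overall). Returns w for every window when the
// transcript is shorter than w (no placement exists).
// [[Rcpp::export]]
List cpp_scan_min(IntegerVector frag, IntegerVector txp, int w) {
  int n = frag.size(), m = txp.size();
  int nw = n - w + 1;
  if (nw < 1) return List::create(_["min"] = IntegerVector(0),
                                  _["argmin"] = IntegerVector(0));
  IntegerVector mins(nw, w);
  IntegerVector arg(nw, NA_INTEGER);
  if (m >= w) {
    std::vector<int> mism(n);
    for (int d = -(n - w); d <= m - w; ++d) {
      int ilo = std::max(0, -d);
      int ihi = std::min(n - w, m - w - d);
      if (ihi < ilo) continue;
      int khi = ihi + w - 1;
      for (int k = ilo; k <= khi; ++k) mism[k] = frag[k] != txp[k + d];
      int cnt = 0;
      for (int k = ilo; k < ilo + w; ++k) cnt += mism[k];
      for (int i = ilo; ; ++i) {
        if (cnt < mins[i]) { mins[i] = cnt; arg[i] = i + d + 1; } // 1-based
        if (i == ihi) break;
        cnt += mism[i + w] - mism[i];
      }
    }
  }
  return List::create(_["min"] = mins, _["argmin"] = arg);
}

// Scan every w-mer of `frag` against every site of one strand of `txp` under
// the miRNA target-recognition rules. Positions on the small RNA are 1-based;
// position 1 is never counted. The 5' region [five_lo, five_hi] and the
// cleavage positions pair without a loop; target-side loops of 1..max_loop nt
// may be inserted after small-RNA position q, q in [five_hi, w-1].
// A site is functional iff cleavage positions all pair, m3 <= max3,
// loop <= max_loop, and (m5 <= max5 or (m5 <= max5_relaxed and m3 == 0 and
// loop == 0)). The loop-free 5' statistics are shared by all loop
// placements, so they are computed once per lag via prefix sums and the
// (rare) surviving candidates get the full placement enumeration.
// [[Rcpp::export]]
DataFrame cpp_mirna_scan(IntegerVector frag, IntegerVector txp, int w,
                         int five_lo, int five_hi,
                         IntegerVector cleavage,
                         int max5, int max5_relaxed, int max3,
                         int max_loop, bool gu_as_match) {
  int n = frag.size(), m = txp.size();
  int nw = n - w + 1;
  std::vector<int> out_i, out_j, out_L, out_q, out_m5, out_m3;
  int m5_cap = std::max(max5, max5_relaxed);
  if (nw >= 1 && m >= w) {
    std::vector<int> mism(n);
    std::vector<int> pre(n + 1);
    for (int d = -(n - w); d <= m - w; ++d) {
      int ilo = std::max(0, -d);
      int ihi = std::min(n - w, m - w - d);
      if (ihi < ilo) continue;
      int khi = ihi + w - 1;
      pre[ilo] = 0;
      for (int k = ilo; k <= khi; ++k) {
        mism[k] = !base_match(frag[k], txp[k + d], gu_as_match);
        pre[k + 1] = pre[k] + mism[k];
      }
      for (int i = ilo; i <= ihi; ++i) {
        // 5' region occupies fragment indices i+five_lo-1 .. i+five_hi-1
        int m5 = pre[i + five_hi] - pre[i + five_lo - 1];
        if (m5 > m5_cap) continue;
        bool cleav_ok = true;
        for (int c = 0; c < cleavage.size(); ++c) {
          if (mism[i + cleavage[c] - 1]) { cleav_ok = false; break; }
        }
        if (!cleav_ok) continue;
        int j = i + d;
        for (int L = 0; L <= max_loop; ++L) {
          if (j + w + L > m) break;
          int best_m3, best_q;
          if (L == 0) {
            best_m3 = pre[i + w] - pre[i + five_hi];
            best_q = -1;
          } else {
            best_m3 = w + 1; best_q = -1;
            for (int q = five_hi; q <= w - 1; ++q) {
              int m3 = 0;
              for (int p = five_hi + 1; p <= w; ++p) {
                int tpos = (p <= q) ? (j + p - 1) : (j + p - 1 + L);
                if (!base_match(frag[i + p - 1], txp[tpos], gu_as_match)) ++m3;
              }
              if (m3 < best_m3) { best_m3 = m3; best_q = q; }
            }
          }
          bool functional = (best_m3 <= max3) &&
            ((m5 <= max5) || (m5 <= max5_relaxed && best_m3 == 0 && L == 0));
          if (functional) {
            out_i.push_back(i + 1);
            out_j.push_back(j + 1);
            out_L.push_back(L);
            out_q.push_back(L == 0 ? NA_INTEGER : best_q);
            out_m5.push_back(m5);
            out_m3.push_back(best_m3);
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["window_start"] = wrap(out_i),
    _["target_start"] = wrap(out_j),
    _["loop_len"] = wrap(out_L),
    _["loop_after"] = wrap(out_q),
    _["mismatches_5p"] = wrap(out_m5),
    _["mismatches_3p"] = wrap(out_m3));
}

// Length of the longest common substring of two encoded sequences.
// [[Rcpp::export]]
int cpp_lcs_len(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  int best = 0;
  // per-lag run scan: O(n * m) time, O(1) space
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i = std::max(0, -d);
    int run = 0;
    for (; i < n && i + d < m; ++i) {
      if (a[i] == b[i + d]) { if (++run > best) best = run; }
      else run = 0;
    }
  }
  return best;
}
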