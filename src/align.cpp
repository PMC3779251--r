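#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T=3 N=4, masked=5. N never matches; masked cells
// take a large negative score so repeated-HSP extraction cannot cross them.

static const int NEG = -100000000;

struct TraceResult {
  int score, qstart, qend, sstart, send;
  int matches, aln_len, mismatches, gap_opens;
};

// Affine-gap Smith-Waterman with traceback of the single best local alignment.
// q, s are 0-based code vectors. Costs are positive magnitudes; opening a gap
// of length k costs gap_open + k * gap_ext.
static TraceResult sw_best(const std::vector<int>& q, const std::vector<int>& s,
                           int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)s.size();
  // H = best ending in (i,j) with q[i-1] aligned to s[j-1] or gap states E/F
  std::vector<int> Hprev(n + 1, 0), H(n + 1, 0), Eprev(n + 1, NEG), E(n + 1, NEG);
  // full traceback matrices (bytes): 0 stop, 1 diag, 2 up(gap in s), 3 left(gap in q)
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = opened here
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Erow(n + 1, NEG); // E = gap in query (left moves) per cell, column-wise carries
  // We keep full DP with two rolling rows for scores but need full state for
  // traceback; store per-cell best-state scores compactly instead.
  std::vector<int> Fcol(n + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Fdiag; // unused placeholder
    (void)Fdiag;
    E[0] = NEG;
    H[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const bool masked = q[i - 1] == 5 || s[j - 1] == 5;
      const int sub = masked ? NEG
                             : ((q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : -mismatch);
      // E: gap in subject consumed along query? Convention:
      //   E(i,j): alignment ends with gap in QUERY (move left, consume s[j-1])
      int e_open = H[j - 1] - gap_open - gap_ext;
      int e_ext  = E[j - 1] - gap_ext;
      int e = std::max(e_open, e_ext);
      tbE[(size_t)i * (n + 1) + j] = (e_open >= e_ext) ? 1 : 0;
      E[j] = e;
      //   F(i,j): ends with gap in SUBJECT (move up, consume q[i-1])
      int f_open = Hprev[j] - gap_open - gap_ext;
      int f_ext  = Fcol[j] - gap_ext;
      int f = std::max(f_open, f_ext);
      tbF[(size_t)i * (n + 1) + j] = (f_open >= f_ext) ? 1 : 0;
      Fcol[j] = f;

      int diag = Hprev[j - 1] + sub;
      int h = 0; unsigned char dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (f > h)    { h = f;    dir = 2; }
      if (e > h)    { h = e;    dir = 3; }
      H[j] = h;
      tbH[(size_t)i * (n + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, H);
    std::swap(Eprev, E);
  }

  TraceResult r{0, 0, 0, 0, 0, 0, 0, 0, 0};
  r.score = best;
  if (best <= 0) return r;

  // Traceback from (bi, bj) through state machine H/E/F.
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E(left), 2 = F(up)
  r.qend = bi; r.send = bj;
  bool in_gap = false;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char d = tbH[(size_t)i * (n + 1) + j];
      if (d == 0) break;
      if (d == 1) {
        r.aln_len++;
        if (q[i - 1] == s[j - 1] && q[i - 1] < 4) r.matches++; else r.mismatches++;
        i--; j--; in_gap = false;
      } else if (d == 2) { state = 2; }
      else { state = 1; }
    } else if (state == 1) { // gap in query, consume s[j-1]
      r.aln_len++;
      if (!in_gap) { r.gap_opens++; in_gap = true; }
      unsigned char opened = tbE[(size_t)i * (n + 1) + j];
      j--;
      if (opened) { state = 0; in_gap = false; }
    } else { // gap in subject, consume q[i-1]
      r.aln_len++;
      if (!in_gap) { r.gap_opens++; in_gap = true; }
      unsigned char opened = tbF[(size_t)i * (n + 1) + j];
      i--;
      if (opened) { state = 0; in_gap = false; }
    }
  }
  r.qstart = i + 1; r.sstart = j + 1;
  return r;
}

// [[Rcpp::export(name = ".sw_hits_cpp")]]
DataFrame sw_hits_cpp(IntegerVector query, IntegerVector subject,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int score_floor, int max_hsps) {
  std::vector<int> q(query.begin(), query.end());
  std::vector<int> s(subject.begin(), subject.end());
  std::vector<int> score, qstart, qend, sstart, send, matches, aln_len, mism, gapo;
  for (int k = 0; k < max_hsps; ++k) {
    TraceResult r = sw_best(q, s, match, mismatch, gap_open, gap_ext);
    if (r.score < score_floor || r.score <= 0) break;
    score.push_back(r.score); qstart.push_back(r.qstart); qend.push_back(r.qend);
    sstart.push_back(r.sstart); send.push_back(r.send);
    matches.push_back(r.matches); aln_len.push_back(r.aln_len);
    mism.push_back(r.mismatches); gapo.push_back(r.gap_opens);
    for (int j = r.sstart - 1; j < r.send; ++j) s[j] = 5; // mask and re-scan
  }
  return DataFrame::create(
    _["score"] = score, _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send, _["matches"] = matches,
    _["aln_len"] = aln_len, _["mismatches"] = mism, _["gap_opens"] = gapo);
}

static inline bool wc_pair(int a, int b, bool allow_gu) {
  if (a > 3 || b > 3) return false;
  if (a + b == 3) return true;            // A(0)-T(3), C(1)-G(2)
  if (allow_gu && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true; // G-U wobble
  return false;
}

// Enumerate maximal inverted repeats (hairpin stems). A match is the triple
// (arm1_start i, stem L, loop g): positions i+t pair with j+L-1-t where
// j = i+L+g; all paired index sums equal c = 2i+2L+g-1, so stems are runs
// along anti-diagonals. Maximality ignores the loop floor (see vignette):
// a match is reported iff it cannot be extended outward or inward within the
// mismatch budget, its loop >= min_loop and stem >= min_stem.
// [[Rcpp::export(name = ".hairpins_cpp")]]
DataFrame hairpins_cpp(IntegerVector seq, int min_stem, int min_loop,
                       int max_mismatch, bool allow_gu) {
  const int n = seq.size();
  std::vector<int> a1, a2, stem, loop, mm;
  std::vector<int> pref; // prefix mismatch counts along one anti-diagonal
  for (int c = 1; c <= 2 * n - 3; ++c) {
    const int alo = std::max(0, c - (n - 1));   // smallest a with b = c - a <= n-1
    const int ahi = (c - 1) / 2;                // largest a with a < b
    if (ahi < alo) continue;
    const int len = ahi - alo + 1;
    pref.assign(len + 1, 0);
    for (int t = 0; t < len; ++t) {
      const int a = alo + t, b = c - a;
      pref[t + 1] = pref[t] + (wc_pair(seq[a], seq[b], allow_gu) ? 0 : 1);
    }
    // mism(i, L) for arm1 in [i, i+L): indices a = i .. i+L-1 must be <= ahi
    for (int i = alo; i + min_stem - 1 <= ahi; ++i) {
      const int Lmaxg = ahi - i + 1; // largest L with g = c+1-2i-2L >= 0 (or 1)
      for (int L = min_stem; L <= Lmaxg; ++L) {
        const int g = c + 1 - 2 * i - 2 * L;
        if (g < 0) break;
        const int m0 = pref[i - alo + L] - pref[i - alo];
        if (m0 > max_mismatch) continue;
        // outward extension: (i-1, L+1), same loop
        bool ext_out = false;
        if (i - 1 >= 0 && c - (i - 1) <= n - 1) {
          const int add = wc_pair(seq[i - 1], seq[c - i + 1], allow_gu) ? 0 : 1;
          if (m0 + add <= max_mismatch) ext_out = true;
        }
        // inward extension: (i, L+1, g-2), valid while g-2 >= 0
        bool ext_in = false;
        if (g >= 2) {
          const int add = wc_pair(seq[i + L], seq[c - i - L], allow_gu) ? 0 : 1;
          if (m0 + add <= max_mismatch) ext_in = true;
        }
        if (ext_out || ext_in) continue;
        if (g < min_loop) continue;
        a1.push_back(i); a2.push_back(i + L + g);
        stem.push_back(L); loop.push_back(g); mm.push_back(m0);
      }
    }
  }
  // order by arm1_start then arm2_start
  std::vector<int> idx(a1.size());
  for (size_t k = 0; k < idx.size(); ++k) idx[k] = (int)k;
  std::sort(idx.begin(), idx.end(), [&](int x, int y) {
    if (a1[x] != a1[y]) return a1[x] < a1[y];
    if (a2[x] != a2[y]) return a2[x] < a2[y];
    return stem[x] < stem[y];
  });
  IntegerVector o1(idx.size()), o2(idx.size()), os(idx.size()), ol(idx.size()), om(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    o1[k] = a1[idx[k]]; o2[k] = a2[idx[k]]; os[k] = stem[idx[k]];
    ol[k] = loop[idx[k]]; om[k] = mm[idx[k]];
  }
  return DataFrame::create(
    _["arm1_start"] = o1, _["arm2_start"] = o2, _["stem_len"] = os,
    _["loop_len"] = ol, _["mismatches"] = om);
}
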