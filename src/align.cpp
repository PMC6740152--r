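#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Affine-gap (Gotoh) Smith-Waterman local alignment with an optional
// diagonal band and deterministic tie-breaking. A gap of length L costs
// gap_open + L * gap_extend (both negative), i.e. the first gap character
// pays gap_open + gap_extend.
//
// Tie-breaking: among cells attaining the maximal score, the alignment with
// the lowest start on `a`, then lowest start on `b`, then lowest end, is
// returned; within the dynamic programme, predecessor preference is
// diagonal > gap-in-b > gap-in-a, and a fresh start is only taken when it
// strictly beats all extensions.

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return 4; // N or anything else: never matches
  }
}

// packed traceback decisions, one byte per banded cell
// bits 0-1: H state source (0 = start, 1 = diag, 2 = E, 3 = F)
// bit 2:    E source (0 = open from H, 1 = extend E)
// bit 3:    F source (0 = open from H, 1 = extend F)

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int band_lo = NA_INTEGER, int band_hi = NA_INTEGER) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const bool banded = (band_lo != NA_INTEGER && band_hi != NA_INTEGER);
  int blo = banded ? band_lo : -(m + 1);
  int bhi = banded ? band_hi : (n + 1);
  if (blo > bhi) stop("empty band");
  const long W = (long)bhi - blo + 1;

  const int NEG = INT32_MIN / 4;
  const int64_t NP1 = (int64_t)n + 1;
  // origins packed as oa * (n+1) + ob: ordering by packed value equals
  // ordering by (oa, ob)
  auto pack = [NP1](int oa, int ob) { return (int64_t)oa * NP1 + ob; };
  // rolling rows indexed by absolute j (1..n)
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<int64_t> HorigP(n + 1, 0), HorigC(n + 1, 0);
  std::vector<int64_t> ForigP(n + 1, 0), ForigC(n + 1, 0);
  std::vector<int> bidx(n);
  for (int j = 0; j < n; ++j) bidx[j] = base_idx(b[j]);

  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  int best = 0, bi = -1, bj = -1;
  int64_t borig = INT64_MAX;
  const int go_ge = gap_open + gap_extend;

  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + blo), jhi = std::min(n, i + bhi);
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
    std::swap(HorigP, HorigC);
    std::swap(ForigP, ForigC);
    // reset only the band range the row will touch (plus one flank cell)
    int rlo = std::max(0, jlo - 1), rhi = std::min(n, jhi + 1);
    if (jlo > jhi) continue;
    std::fill(Hcur.begin() + rlo, Hcur.begin() + rhi + 1, 0);
    std::fill(Fcur.begin() + rlo, Fcur.begin() + rhi + 1, NEG);
    int E = NEG;
    int64_t Eorig = 0;
    // the cell just left of the band is an unreachable fresh start
    HorigC[jlo - 1] = pack(i, jlo - 1);
    const int ai = base_idx(a[i - 1]);
    uint8_t *tbrow = tb.data() + (ptrdiff_t)i * W - i - blo;
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t cell;
      // E: gap in a (consumes b)
      int e_open = Hcur[j - 1] + go_ge;
      int e_ext = E + gap_extend;
      if (e_ext > e_open) { E = e_ext; cell = 4; /* Eorig inherited */ }
      else { E = e_open; Eorig = HorigC[j - 1]; cell = 0; }
      // F: gap in b (consumes a)
      int f_open = Hprev[j] + go_ge;
      int f_ext = Fprev[j] + gap_extend;
      int F; int64_t Forig;
      if (f_ext > f_open) { F = f_ext; Forig = ForigP[j]; cell |= 8; }
      else { F = f_open; Forig = HorigP[j]; }
      Fcur[j] = F; ForigC[j] = Forig;
      // H
      int hp = Hprev[j - 1];
      int h = hp + ((ai == bidx[j - 1] && ai != 4) ? match : mismatch);
      int src = 1;
      int64_t orig = (hp == 0) ? pack(i - 1, j - 1) : HorigP[j - 1];
      if (E > h) { h = E; src = 2; orig = Eorig; }
      if (F > h) { h = F; src = 3; orig = Forig; }
      if (h <= 0) { h = 0; src = 0; orig = pack(i, j); }
      cell |= (uint8_t)src;
      Hcur[j] = h; HorigC[j] = orig;
      tbrow[j] = cell;
      if (h >= best && h > 0 &&
          (h > best || orig < borig ||
           (orig == borig && (i < bi || (i == bi && j < bj))))) {
        best = h; bi = i; bj = j; borig = orig;
      }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["a_start"] = NA_INTEGER,
                        _["a_end"] = NA_INTEGER, _["b_start"] = NA_INTEGER,
                        _["b_end"] = NA_INTEGER, _["a_aln"] = "", _["b_aln"] = "",
                        _["n_match"] = 0, _["n_mismatch"] = 0, _["n_gapcols"] = 0);
  }
  const int boa = (int)(borig / NP1), bob = (int)(borig % NP1);

  // traceback from (bi, bj), state H
  std::string aa, ba;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  while (true) {
    long off = (long)j - i - blo;
    if (off < 0 || off >= W) break; // band edge: unreachable start
    uint8_t cell = tb[(size_t)i * W + off];
    if (state == 0) {
      int src = cell & 3;
      if (src == 0) break;
      if (src == 1) {
        aa.push_back(a[i - 1]); ba.push_back(b[j - 1]);
        int x = base_idx(a[i - 1]);
        if (x == base_idx(b[j - 1]) && x != 4) ++n_match; else ++n_mismatch;
        --i; --j;
        if (i == boa && j == bob) break;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap in a, consumed b[j-1]
      aa.push_back('-'); ba.push_back(b[j - 1]); ++n_gap;
      bool ext = (cell & 4) != 0;
      --j;
      state = ext ? 1 : 0;
    } else { // F: gap in b, consumed a[i-1]
      aa.push_back(a[i - 1]); ba.push_back('-'); ++n_gap;
      bool ext = (cell & 8) != 0;
      --i;
      state = ext ? 2 : 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ba.begin(), ba.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["a_aln"] = aa, _["b_aln"] = ba,
                      _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
                      _["n_gapcols"] = n_gap);
}

// Exact k-mer seed matches between query and subject (0-based positions).
// k <= 15; k-mers containing non-ACGT bases are skipped.
// [[Rcpp::export]]
IntegerMatrix seed_hits_cpp(std::string query, std::string subject, int k) {
  const int m = (int)query.size(), n = (int)subject.size();
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  if (m < k || n < k) return IntegerMatrix(0, 2);
  const uint32_t mask = (1u << (2 * k)) - 1u;

  // index query k-mers
  std::vector<int> head((size_t)1 << (2 * k), -1), nxt(m, -1);
  uint32_t code = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int b = base_idx(query[i]);
    if (b == 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++run >= k) {
      int pos = i - k + 1;
      nxt[pos] = head[code]; head[code] = pos;
    }
  }
  std::vector<int> qv, sv;
  code = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    int b = base_idx(subject[j]);
    if (b == 4) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++run >= k) {
      int spos = j - k + 1;
      for (int p = head[code]; p != -1; p = nxt[p]) { qv.push_back(p); sv.push_back(spos); }
    }
  }
  IntegerMatrix out((int)qv.size(), 2);
  for (size_t t = 0; t < qv.size(); ++t) { out((int)t, 0) = qv[t]; out((int)t, 1) = sv[t]; }
  colnames(out) = CharacterVector::create("qpos", "spos");
  return out;
}

// Group seeds into candidate alignment regions: seeds on nearby diagonals
// (|ddiag| <= max_diag_diff) with subject positions within max_spos_gap of
// the running cluster. Returns one row per cluster:
// smin, smax (subject span of seed starts), dmin, dmax (diagonal range), n.
// [[Rcpp::export]]
IntegerMatrix cluster_seeds_cpp(IntegerVector qpos, IntegerVector spos,
                                int max_diag_diff, int max_spos_gap) {
  const int N = qpos.size();
  if (N == 0) return IntegerMatrix(0, 5);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::vector<int> diag(N);
  for (int i = 0; i < N; ++i) diag[i] = spos[i] - qpos[i];
  std::sort(idx.begin(), idx.end(), [&](int x, int y) {
    if (diag[x] != diag[y]) return diag[x] < diag[y];
    return spos[x] < spos[y];
  });
  // pass 1: split on diagonal jumps; pass 2 (within): split on spos gaps
  std::vector<std::array<int, 5>> clusters; // smin smax dmin dmax n
  size_t g0 = 0;
  auto flush_group = [&](size_t lo, size_t hi) {
    // sort group members by spos, split on gaps
    std::vector<int> g(idx.begin() + lo, idx.begin() + hi);
    std::sort(g.begin(), g.end(), [&](int x, int y) { return spos[x] < spos[y]; });
    int cs = spos[g[0]], ce = spos[g[0]], dl = diag[g[0]], dh = diag[g[0]], cnt = 1;
    for (size_t t = 1; t < g.size(); ++t) {
      int s = spos[g[t]], d = diag[g[t]];
      if (s - ce > max_spos_gap) {
        clusters.push_back({cs, ce, dl, dh, cnt});
        cs = s; ce = s; dl = d; dh = d; cnt = 1;
      } else {
        ce = std::max(ce, s); dl = std::min(dl, d); dh = std::max(dh, d); ++cnt;
      }
    }
    clusters.push_back({cs, ce, dl, dh, cnt});
  };
  for (size_t t = 1; t <= (size_t)N; ++t) {
    if (t == (size_t)N || diag[idx[t]] - diag[idx[t - 1]] > max_diag_diff) {
      flush_group(g0, t);
      g0 = t;
    }
  }
  IntegerMatrix out((int)clusters.size(), 5);
  for (size_t t = 0; t < clusters.size(); ++t)
    for (int c = 0; c < 5; ++c) out((int)t, c) = clusters[t][c];
  colnames(out) = CharacterVector::create("smin", "smax", "dmin", "dmax", "n");
  return out;
}
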