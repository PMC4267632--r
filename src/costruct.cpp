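// Core dynamic programming engines.
//
// Two engines live here:
//   * single-sequence free-energy minimization (Zuker-style) producing the
//     V array, the multibranch-branch array (W_single), the exterior-loop
//     array (WE_single), prefix/suffix exterior arrays, and the
//     allowed-pair filter based on an interior+exterior decomposition;
//   * the joint fold-and-align DP over two sequences: 4D arrays V and W,
//     2D exterior arrays W5 and W3, with move sets selectable as
//     "original" (conserved motifs only), "no_insert" (adds stem extension
//     and motif insertion, the stackII terms) and "dynalign2" (adds
//     affine-penalty inserted domains routed through the single-sequence
//     arrays).
//
// All energies are integer tenths of kcal/mol.  Minima are recomputed
// during traceback through the same term-evaluation code used by the fill,
// with a fixed term priority, so ties break deterministically.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const int INF = 100000000;

// ---------------------------------------------------------------------------
// Energy parameters (integer tenths)

struct EP {
  int stack[6][6];
  int hairpin[31];   // index by loop size 3..30
  int bulge[31];     // 1..30
  int internal_[31]; // 2..30
  int aupen, mbl_a, mbl_b, mbl_u, gap, open_, elong;
  int asym_c, asym_m, logc;
  int max_int, max_ext, min_hp;
};

// base codes: A=0 C=1 G=2 U=3; pair codes AU=0 CG=1 GC=2 UA=3 GU=4 UG=5
static inline int paircode(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 1 && y == 2) return 1;
  if (x == 2 && y == 1) return 2;
  if (x == 3 && y == 0) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}
static inline bool is_augu(int pc) { return pc == 0 || pc == 3 || pc == 4 || pc == 5; }

static EP ep_from_list(List p) {
  EP e;
  IntegerMatrix st = p["stack"];
  for (int a = 0; a < 6; ++a) for (int b = 0; b < 6; ++b) e.stack[a][b] = st(a, b);
  IntegerVector hp = p["hairpin_init"], bu = p["bulge_init"], in = p["internal_init"];
  for (int n = 3; n <= 30; ++n) e.hairpin[n] = hp[n - 3];
  for (int n = 1; n <= 30; ++n) e.bulge[n] = bu[n - 1];
  for (int n = 2; n <= 30; ++n) e.internal_[n] = in[n - 2];
  e.aupen = as<int>(p["au_gu_end_penalty"]);
  e.mbl_a = as<int>(p["mbl_closure"]);
  e.mbl_b = as<int>(p["mbl_branch"]);
  e.mbl_u = as<int>(p["mbl_unpaired"]);
  e.gap = as<int>(p["gap_penalty"]);
  e.open_ = as<int>(p["domain_opening"]);
  e.elong = as<int>(p["domain_elongation"]);
  e.asym_c = as<int>(p["asymmetry_coef"]);
  e.asym_m = as<int>(p["asymmetry_max"]);
  e.logc = as<int>(p["log_extrapolation"]);
  e.max_int = as<int>(p["max_internal_side"]);
  e.max_ext = as<int>(p["max_stackII_extension"]);
  e.min_hp = as<int>(p["min_hairpin"]);
  return e;
}

static inline int loop_init(const int *tab, int nmin, int n, const EP &e) {
  if (n < nmin) return INF;
  if (n <= 30) return tab[n];
  return tab[30] + (int)std::lround(e.logc * std::log((double)n / 30.0));
}

struct Seq {
  std::vector<int> b; // 1-based codes
  int N;
  explicit Seq(IntegerVector v) : b(v.size() + 1), N(v.size()) {
    for (int i = 0; i < N; ++i) b[i + 1] = v[i];
  }
  int pc(int i, int j) const { return paircode(b[i], b[j]); }
};

static inline int endpen(const Seq &s, int i, int j, const EP &e) {
  int pc = s.pc(i, j);
  return (pc >= 0 && is_augu(pc)) ? e.aupen : 0;
}

static int hairpin_t(const Seq &s, int i, int j, const EP &e) {
  int size = j - i - 1;
  if (size < e.min_hp) return INF;
  int pc = s.pc(i, j);
  if (pc < 0) return INF;
  int init = loop_init(e.hairpin, 3, size, e);
  if (init >= INF) return INF;
  return init + endpen(s, i, j, e);
}

// motif closed by (m,p) outer and (n,q) inner, m < n < q < p
static int motif_t(const Seq &s, int m, int n, int p, int q, const EP &e) {
  int pco = s.pc(m, p), pci = s.pc(n, q);
  if (pco < 0 || pci < 0) return INF;
  int s5 = n - m - 1, s3 = p - q - 1;
  if (n - m > e.max_int || p - q > e.max_int) return INF;
  if (s5 == 0 && s3 == 0) return e.stack[pco][pci];
  if (s5 == 0 || s3 == 0) {
    int len = s5 + s3;
    int init = loop_init(e.bulge, 1, len, e);
    if (init >= INF) return INF;
    if (len == 1) return init + e.stack[pco][pci];
    return init + endpen(s, m, p, e) + endpen(s, n, q, e);
  }
  int init = loop_init(e.internal_, 2, s5 + s3, e);
  if (init >= INF) return INF;
  int asym = std::min(e.asym_m, std::abs(s5 - s3) * e.asym_c);
  return init + asym + endpen(s, m, p, e) + endpen(s, n, q, e);
}

// ---------------------------------------------------------------------------
// Single-sequence engine

struct SingleDP {
  const Seq &s;
  const EP &e;
  int N;
  std::vector<int> v, wb, we; // (N+1)x(N+1), index i*(N+1)+j (1-based pos)
  std::vector<int> w5, w3;    // 0..N and 1..N+1
  SingleDP(const Seq &sq, const EP &ee) : s(sq), e(ee), N(sq.N),
    v((N + 1) * (N + 1), INF), wb((N + 1) * (N + 1), INF),
    we((N + 1) * (N + 1), INF), w5(N + 1, 0), w3(N + 2, 0) {}

  int &V(int i, int j) { return v[i * (N + 1) + j]; }
  int &WB(int i, int j) { return wb[i * (N + 1) + j]; }
  int &WE(int i, int j) { return we[i * (N + 1) + j]; }
  int getWB(int i, int j) const { return (i >= 1 && j <= N && i <= j) ? wb[i * (N + 1) + j] : INF; }
  int getWE(int i, int j) const { return (i >= 1 && j <= N && i <= j) ? we[i * (N + 1) + j] : INF; }

  void fill() {
    for (int span = 0; span < N; ++span) {
      for (int i = 1; i + span <= N; ++i) {
        int j = i + span;
        // V
        int pc = s.pc(i, j);
        if (pc >= 0 && j - i - 1 >= e.min_hp) {
          int best = hairpin_t(s, i, j, e);
          int i2max = std::min(i + e.max_int, j - 1);
          for (int i2 = i + 1; i2 <= i2max; ++i2) {
            int j2min = std::max(i2 + 1, j - e.max_int);
            for (int j2 = j - 1; j2 >= j2min; --j2) {
              int inner = V(i2, j2);
              if (inner >= INF) continue;
              int m = motif_t(s, i, i2, j, j2, e);
              if (m >= INF) continue;
              best = std::min(best, inner + m);
            }
          }
          int penij = endpen(s, i, j, e);
          for (int m = i + 2; m <= j - 2; ++m) {
            int a = getWB(i + 1, m), b = getWB(m + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            best = std::min(best, a + b + e.mbl_a + e.mbl_b + penij);
          }
          V(i, j) = std::min(best, INF);
        }
        // WB
        {
          int best = INF;
          if (i < j) {
            if (getWB(i + 1, j) < INF) best = std::min(best, getWB(i + 1, j) + e.mbl_u);
            if (getWB(i, j - 1) < INF) best = std::min(best, getWB(i, j - 1) + e.mbl_u);
          }
          if (V(i, j) < INF) best = std::min(best, V(i, j) + e.mbl_b + endpen(s, i, j, e));
          for (int m = i + 1; m <= j - 1; ++m) {
            int a = getWB(i, m), b = getWB(m + 1, j);
            if (a >= INF || b >= INF) continue;
            best = std::min(best, a + b);
          }
          WB(i, j) = std::min(best, INF);
        }
        // WE
        {
          int best = INF;
          if (i < j) {
            best = std::min(best, getWE(i + 1, j));
            best = std::min(best, getWE(i, j - 1));
          }
          if (V(i, j) < INF) best = std::min(best, V(i, j) + endpen(s, i, j, e));
          for (int m = i + 1; m <= j - 1; ++m) {
            int a = getWE(i, m), b = getWE(m + 1, j);
            if (a >= INF || b >= INF) continue;
            best = std::min(best, a + b);
          }
          WE(i, j) = std::min(best, INF);
        }
      }
    }
    // prefix/suffix exterior arrays
    for (int i = 1; i <= N; ++i) {
      int best = w5[i - 1];
      for (int m = 1; m <= i; ++m) {
        int vv = V(m, i);
        if (vv >= INF) continue;
        best = std::min(best, w5[m - 1] + vv + endpen(s, m, i, e));
      }
      w5[i] = best;
    }
    w3[N + 1] = 0;
    for (int j = N; j >= 1; --j) {
      int best = w3[j + 1];
      for (int m = j; m <= N; ++m) {
        int vv = V(j, m);
        if (vv >= INF) continue;
        best = std::min(best, vv + endpen(s, j, m, e) + w3[m + 1]);
      }
      w3[j] = best;
    }
  }

  // exterior closure of the complement of (i,j): the outside algorithm.
  // vout(i,j) + V(i,j) = lowest free energy over whole-sequence structures
  // containing pair i-j.
  std::vector<int> vout_fill() {
    std::vector<int> vo((N + 1) * (N + 1), INF);
    for (int span = N - 1; span >= 0; --span) {
      for (int i = 1; i + span <= N; ++i) {
        int j = i + span;
        if (V(i, j) >= INF) continue;
        int best = w5[i - 1] + w3[j + 1] + endpen(s, i, j, e);
        // closed by an outer pair via a two-pair motif
        int mmin = std::max(1, i - e.max_int);
        for (int m = mmin; m <= i - 1; ++m) {
          int pmax = std::min(N, j + e.max_int);
          for (int p = j + 1; p <= pmax; ++p) {
            int oo = vo[m * (N + 1) + p];
            if (oo >= INF) continue;
            int mt = motif_t(s, m, i, p, j, e);
            if (mt >= INF) continue;
            best = std::min(best, oo + mt);
          }
        }
        // branch of a multibranch loop closed by outer pair (m,p)
        for (int m = 1; m <= i - 1; ++m) {
          for (int p = j + 1; p <= N; ++p) {
            int oo = vo[m * (N + 1) + p];
            if (oo >= INF) continue;
            int base = oo + e.mbl_a + 2 * e.mbl_b + endpen(s, m, p, e) + endpen(s, i, j, e);
            int u1 = (i - 1) - (m + 1) + 1, u2 = (p - 1) - (j + 1) + 1; // side lengths
            int un1 = u1 * e.mbl_u, un2 = u2 * e.mbl_u;
            int wb1 = getWB(m + 1, i - 1), wb2 = getWB(j + 1, p - 1);
            int extra = INF;
            if (wb1 < INF) extra = std::min(extra, wb1 + un2);
            if (wb2 < INF) extra = std::min(extra, un1 + wb2);
            if (wb1 < INF && wb2 < INF) extra = std::min(extra, wb1 + wb2);
            if (extra >= INF) continue;
            best = std::min(best, base + extra);
          }
        }
        vo[i * (N + 1) + j] = std::min(best, INF);
      }
    }
    return vo;
  }

  // traceback of V/WB/WE restricted structures (used for inserted domains).
  // Term priority: hairpin > internal/stack > multibranch; extensions first
  // in WB/WE, then branch, then bifurcation.
  void tb_v(int i, int j, std::vector<int> &pairof) {
    int target = V(i, j);
    if (target >= INF) stop("single traceback: V(%d,%d) infinite", i, j);
    pairof[i] = j; pairof[j] = i;
    if (target == hairpin_t(s, i, j, e)) return;
    int i2max = std::min(i + e.max_int, j - 1);
    for (int i2 = i + 1; i2 <= i2max; ++i2) {
      int j2min = std::max(i2 + 1, j - e.max_int);
      for (int j2 = j - 1; j2 >= j2min; --j2) {
        int inner = V(i2, j2);
        if (inner >= INF) continue;
        int m = motif_t(s, i, i2, j, j2, e);
        if (m < INF && inner + m == target) { tb_v(i2, j2, pairof); return; }
      }
    }
    int penij = endpen(s, i, j, e);
    for (int m = i + 2; m <= j - 2; ++m) {
      int a = getWB(i + 1, m), b = getWB(m + 1, j - 1);
      if (a < INF && b < INF && a + b + e.mbl_a + e.mbl_b + penij == target) {
        tb_wb(i + 1, m, pairof); tb_wb(m + 1, j - 1, pairof); return;
      }
    }
    stop("single traceback: no term reproduces V(%d,%d)", i, j);
  }
  void tb_wb(int i, int j, std::vector<int> &pairof) {
    int target = WB(i, j);
    if (target >= INF) stop("single traceback: WB(%d,%d) infinite", i, j);
    if (i < j && getWB(i + 1, j) < INF && getWB(i + 1, j) + e.mbl_u == target) { tb_wb(i + 1, j, pairof); return; }
    if (i < j && getWB(i, j - 1) < INF && getWB(i, j - 1) + e.mbl_u == target) { tb_wb(i, j - 1, pairof); return; }
    if (V(i, j) < INF && V(i, j) + e.mbl_b + endpen(s, i, j, e) == target) { tb_v(i, j, pairof); return; }
    for (int m = i + 1; m <= j - 1; ++m) {
      int a = getWB(i, m), b = getWB(m + 1, j);
      if (a < INF && b < INF && a + b == target) { tb_wb(i, m, pairof); tb_wb(m + 1, j, pairof); return; }
    }
    stop("single traceback: no term reproduces WB(%d,%d)", i, j);
  }
  void tb_we(int i, int j, std::vector<int> &pairof) {
    int target = WE(i, j);
    if (target >= INF) stop("single traceback: WE(%d,%d) infinite", i, j);
    if (i < j && getWE(i + 1, j) == target) { tb_we(i + 1, j, pairof); return; }
    if (i < j && getWE(i, j - 1) == target) { tb_we(i, j - 1, pairof); return; }
    if (V(i, j) < INF && V(i, j) + endpen(s, i, j, e) == target) { tb_v(i, j, pairof); return; }
    for (int m = i + 1; m <= j - 1; ++m) {
      int a = getWE(i, m), b = getWE(m + 1, j);
      if (a < INF && b < INF && a + b == target) { tb_we(i, m, pairof); tb_we(m + 1, j, pairof); return; }
    }
    stop("single traceback: no term reproduces WE(%d,%d)", i, j);
  }
};

// [[Rcpp::export(name = ".fold_single_cpp")]]
List fold_single_cpp(IntegerVector seq_codes, List params) {
  EP e = ep_from_list(params);
  Seq s(seq_codes);
  SingleDP dp(s, e);
  dp.fill();
  int N = s.N;
  IntegerMatrix v(N + 1, N + 1), wb(N + 1, N + 1), we(N + 1, N + 1);
  for (int i = 0; i <= N; ++i) for (int j = 0; j <= N; ++j) {
    v(i, j) = dp.v[i * (N + 1) + j];
    wb(i, j) = dp.wb[i * (N + 1) + j];
    we(i, j) = dp.we[i * (N + 1) + j];
  }
  return List::create(_["v"] = v, _["wb"] = wb, _["we"] = we,
                      _["w5"] = IntegerVector(dp.w5.begin(), dp.w5.end()),
                      _["w3"] = IntegerVector(dp.w3.begin(), dp.w3.end()),
                      _["mfe"] = dp.w5[N]);
}

// [[Rcpp::export(name = ".filter_pairs_cpp")]]
LogicalMatrix filter_pairs_cpp(IntegerVector seq_codes, List params, double window) {
  EP e = ep_from_list(params);
  Seq s(seq_codes);
  SingleDP dp(s, e);
  dp.fill();
  int N = s.N;
  LogicalMatrix allowed(N + 1, N + 1);
  if (window >= 1.0) {
    for (int i = 1; i <= N; ++i) for (int j = i + 1; j <= N; ++j)
      allowed(i, j) = dp.V(i, j) < INF;
    return allowed;
  }
  std::vector<int> vo = dp.vout_fill();
  int mfe = dp.w5[N];
  int thr = mfe + (int)std::floor(window * std::abs((double)mfe) + 1e-9);
  for (int i = 1; i <= N; ++i) for (int j = i + 1; j <= N; ++j) {
    if (dp.V(i, j) >= INF) continue;
    int oo = vo[i * (N + 1) + j];
    if (oo >= INF) continue;
    allowed(i, j) = (dp.V(i, j) + oo) <= thr;
  }
  return allowed;
}

// [[Rcpp::export(name = ".trace_single_cpp")]]
IntegerVector trace_single_cpp(IntegerVector seq_codes, List params) {
  // pairs of one MFE structure of the whole sequence (exterior trace)
  EP e = ep_from_list(params);
  Seq s(seq_codes);
  SingleDP dp(s, e);
  dp.fill();
  int N = s.N;
  std::vector<int> pairof(N + 1, 0);
  if (N > 0 && dp.WE(1, N) < INF && dp.WE(1, N) == dp.w5[N]) dp.tb_we(1, N, pairof);
  return IntegerVector(pairof.begin() + 1, pairof.end());
}

// ---------------------------------------------------------------------------
// Joint engine

struct Joint {
  const Seq &s1, &s2;
  const EP &e;
  int N1, N2, d, mode; // mode: 0 original, 1 no_insert, 2 dynalign2
  // singles (passed in): branch and exterior arrays + allowed masks
  const IntegerMatrix &wb1m, &wb2m, &we1m, &we2m;
  const LogicalMatrix &al1, &al2;
  std::vector<int> kmin1, kmax1; // band over cut points 0..N1 -> k range
  int K;                         // max band width (storage)
  std::vector<int> Varr, Warr;
  std::vector<int> w5arr, w3arr; // (N1+1)x(N2+1) and (N1+2)x(N2+2)
  std::vector<std::vector<std::pair<int,int> > > inner1, inner2; // allowed inner pairs per (i,j) key
  std::vector<std::vector<int> > ends1, ends2;     // allowed pair starts per end position
  std::vector<std::vector<int> > starts1, starts2; // allowed pair ends per start position
  std::vector<int> bestEnd1, bestEnd2; // min pair end over pairs starting >= i

  Joint(const Seq &a, const Seq &b, const EP &ee, int band_d, int md,
        const IntegerMatrix &wb1_, const IntegerMatrix &wb2_,
        const IntegerMatrix &we1_, const IntegerMatrix &we2_,
        const LogicalMatrix &a1_, const LogicalMatrix &a2_)
    : s1(a), s2(b), e(ee), N1(a.N), N2(b.N), d(band_d), mode(md),
      wb1m(wb1_), wb2m(wb2_), we1m(we1_), we2m(we2_), al1(a1_), al2(a2_) {
    kmin1.assign(N1 + 1, 0); kmax1.assign(N1 + 1, 0);
    K = 0;
    for (int i = 0; i <= N1; ++i) {
      // |2 (k N1 - i N2)| <= d N1, exact in integers
      int64_t lo = -1, hi = -2;
      for (int k = 0; k <= N2; ++k) {
        int64_t t = 2 * ((int64_t)k * N1 - (int64_t)i * N2);
        if (t < 0) t = -t;
        if (t <= (int64_t)d * N1) { if (lo < 0) lo = k; hi = k; }
      }
      if (lo < 0) stop("band is empty at i=%d", i);
      kmin1[i] = (int)lo; kmax1[i] = (int)hi;
      K = std::max(K, (int)(hi - lo + 1));
    }
    Varr.assign((size_t)(N1 + 1) * (N1 + 1) * K * K, INF);
    Warr.assign((size_t)(N1 + 1) * (N1 + 1) * K * K, INF);
    w5arr.assign((size_t)(N1 + 1) * (N2 + 1), INF);
    w3arr.assign((size_t)(N1 + 2) * (N2 + 2), INF);
  }

  bool inband(int i, int k) const {
    return i >= 0 && i <= N1 && k >= kmin1[i] && k <= kmax1[i];
  }
  size_t idx(int i, int j, int k, int l) const {
    return (((size_t)i * (N1 + 1) + j) * K + (k - kmin1[i])) * K + (l - kmin1[j]);
  }
  int getV(int i, int j, int k, int l) const {
    if (i < 1 || j > N1 || i >= j || k < 1 || l > N2 || k >= l) return INF;
    if (!inband(i, k) || !inband(j, l)) return INF;
    return Varr[idx(i, j, k, l)];
  }
  int getW(int i, int j, int k, int l) const {
    if (i < 1 || j > N1 || i > j || k < 1 || l > N2 || k > l) return INF;
    if (!inband(i, k) || !inband(j, l)) return INF;
    return Warr[idx(i, j, k, l)];
  }
  int getW5(int i, int k) const {
    if (i < 0 || k < 0 || i > N1 || k > N2 || !inband(i, k)) return INF;
    return w5arr[(size_t)i * (N2 + 1) + k];
  }
  int getW3(int j, int l) const {
    if (j < 1 || l < 1 || j > N1 + 1 || l > N2 + 1) return INF;
    if (!inband(j - 1, l - 1)) return INF;
    return w3arr[(size_t)j * (N2 + 2) + l];
  }
  int wb1(int i, int j) const { return (i >= 1 && j <= N1 && i <= j) ? wb1m(i, j) : INF; }
  int wb2(int k, int l) const { return (k >= 1 && l <= N2 && k <= l) ? wb2m(k, l) : INF; }
  int we1(int i, int j) const { return (i >= 1 && j <= N1 && i <= j) ? we1m(i, j) : INF; }
  int we2(int k, int l) const { return (k >= 1 && l <= N2 && k <= l) ? we2m(k, l) : INF; }
  bool ap1(int i, int j) const { return i >= 1 && j <= N1 && i < j && al1(i, j); }
  bool ap2(int k, int l) const { return k >= 1 && l <= N2 && k < l && al2(k, l); }
  int pen1(int i, int j) const { return endpen(s1, i, j, e); }
  int pen2(int k, int l) const { return endpen(s2, k, l, e); }

  void build_inner_lists() {
    inner1.assign((size_t)(N1 + 1) * (N1 + 1), std::vector<std::pair<int,int> >());
    inner2.assign((size_t)(N2 + 1) * (N2 + 1), std::vector<std::pair<int,int> >());
    for (int i = 1; i <= N1; ++i) for (int j = i + 1; j <= N1; ++j) {
      if (!ap1(i, j)) continue;
      std::vector<std::pair<int,int> > &L = inner1[(size_t)i * (N1 + 1) + j];
      int i2max = std::min(i + e.max_int, j - 1);
      for (int i2 = i + 1; i2 <= i2max; ++i2)
        for (int j2 = j - 1; j2 >= std::max(i2 + 1, j - e.max_int); --j2)
          if (ap1(i2, j2)) L.push_back(std::make_pair(i2, j2));
    }
    for (int k = 1; k <= N2; ++k) for (int l = k + 1; l <= N2; ++l) {
      if (!ap2(k, l)) continue;
      std::vector<std::pair<int,int> > &L = inner2[(size_t)k * (N2 + 1) + l];
      int k2max = std::min(k + e.max_int, l - 1);
      for (int k2 = k + 1; k2 <= k2max; ++k2)
        for (int l2 = l - 1; l2 >= std::max(k2 + 1, l - e.max_int); --l2)
          if (ap2(k2, l2)) L.push_back(std::make_pair(k2, l2));
    }
    ends1.assign(N1 + 1, std::vector<int>()); starts1.assign(N1 + 2, std::vector<int>());
    ends2.assign(N2 + 1, std::vector<int>()); starts2.assign(N2 + 2, std::vector<int>());
    bestEnd1.assign(N1 + 2, INF); bestEnd2.assign(N2 + 2, INF);
    for (int i = 1; i <= N1; ++i) for (int j = i + 1; j <= N1; ++j)
      if (ap1(i, j)) { ends1[j].push_back(i); starts1[i].push_back(j); }
    for (int k = 1; k <= N2; ++k) for (int l = k + 1; l <= N2; ++l)
      if (ap2(k, l)) { ends2[l].push_back(k); starts2[k].push_back(l); }
    for (int i = N1; i >= 1; --i) {
      bestEnd1[i] = bestEnd1[i + 1];
      for (size_t x = 0; x < starts1[i].size(); ++x)
        bestEnd1[i] = std::min(bestEnd1[i], starts1[i][x]);
    }
    for (int k = N2; k >= 1; --k) {
      bestEnd2[k] = bestEnd2[k + 1];
      for (size_t x = 0; x < starts2[k].size(); ++x)
        bestEnd2[k] = std::min(bestEnd2[k], starts2[k][x]);
    }
    maxb1.assign(N1 + 1, 0); maxb2.assign(N2 + 1, 0);
    for (int i = 1; i <= N1; ++i) {
      maxb1[i] = maxb1[i - 1];
      for (size_t x = 0; x < starts1[i].size(); ++x)
        maxb1[i] = std::max(maxb1[i], starts1[i][x]);
    }
    for (int k = 1; k <= N2; ++k) {
      maxb2[k] = maxb2[k - 1];
      for (size_t x = 0; x < starts2[k].size(); ++x)
        maxb2[k] = std::max(maxb2[k], starts2[k][x]);
    }
  }
  bool has_pair1(int i, int j) const { return i >= 1 && j <= N1 && bestEnd1[i] <= j; }
  bool has_pair2(int k, int l) const { return k >= 1 && l <= N2 && bestEnd2[k] <= l; }
  std::vector<int> maxb1, maxb2; // max pair end over allowed pairs starting <= x
  // W fragments are only consumed inside loops closed by an allowed pair:
  // skip cells with no enclosing candidate pair.
  bool encl1(int i, int j) const { return i >= 2 && maxb1[i - 1] > j; }
  bool encl2(int k, int l) const { return k >= 2 && maxb2[k - 1] > l; }

  // ---- V term evaluation.  If choice != NULL, find the first term (fixed
  // priority) matching `target` and record it; otherwise return the min.
  struct Choice { int term; int a, b, c, dd; };

  int evalV(int i, int j, int k, int l, int target, Choice *choice) {
    if (!ap1(i, j) || !ap2(k, l)) return INF;
    int best = INF;
    int penij = pen1(i, j), penkl = pen2(k, l);
    // 1. hairpin
    {
      int h1 = hairpin_t(s1, i, j, e), h2 = hairpin_t(s2, k, l, e);
      if (h1 < INF && h2 < INF) {
        int cand = h1 + h2 + e.gap * std::abs((j - i) - (l - k));
        if (choice && cand == target) { choice->term = 1; return cand; }
        best = std::min(best, cand);
      }
    }
    // 2. internal/stack (conserved motif on both sides)
    {
      const std::vector<std::pair<int,int> > &L1 = inner1[(size_t)i * (N1 + 1) + j];
      const std::vector<std::pair<int,int> > &L2 = inner2[(size_t)k * (N2 + 1) + l];
      for (size_t x = 0; x < L1.size(); ++x) {
        int i2 = L1[x].first, j2 = L1[x].second;
        int m1 = motif_t(s1, i, i2, j, j2, e);
        if (m1 >= INF) continue;
        for (size_t y = 0; y < L2.size(); ++y) {
          int k2 = L2[y].first, l2 = L2[y].second;
          int vv = getV(i2, j2, k2, l2);
          if (vv >= INF) continue;
          int m2 = motif_t(s2, k, k2, l, l2, e);
          if (m2 >= INF) continue;
          int cand = vv + m1 + m2 +
            e.gap * (std::abs((i2 - i) - (k2 - k)) + std::abs((j - j2) - (l - l2)));
          if (choice && cand == target) {
            choice->term = 2; choice->a = i2; choice->b = j2; choice->c = k2; choice->dd = l2;
            return cand;
          }
          best = std::min(best, cand);
        }
      }
    }
    if (mode >= 1) {
      // 3. stackII-1: internal loop in seq1 aligned with stacked pairs in seq2
      for (int dd = 2; dd <= e.max_ext; ++dd) {
        int vv = getV(i + dd, j - dd, k + dd, l - dd);
        if (vv >= INF) continue;
        if (!ap1(i + dd, j - dd) || !ap2(k + dd, l - dd)) continue;
        int m1 = motif_t(s1, i, i + dd, j, j - dd, e);
        if (m1 >= INF) continue;
        int stk = 0; bool ok = true;
        for (int c = 0; c < dd; ++c) {
          int po = s2.pc(k + c, l - c), pi = s2.pc(k + c + 1, l - c - 1);
          if (po < 0 || pi < 0) { ok = false; break; }
          stk += e.stack[po][pi];
        }
        if (!ok) continue;
        int cand = vv + m1 + stk;
        if (choice && cand == target) { choice->term = 3; choice->a = dd; return cand; }
        best = std::min(best, cand);
      }
      // 4. stackII-2: internal loop in seq2 aligned with stacked pairs in seq1
      for (int dd = 2; dd <= e.max_ext; ++dd) {
        int vv = getV(i + dd, j - dd, k + dd, l - dd);
        if (vv >= INF) continue;
        if (!ap1(i + dd, j - dd) || !ap2(k + dd, l - dd)) continue;
        int m2 = motif_t(s2, k, k + dd, l, l - dd, e);
        if (m2 >= INF) continue;
        int stk = 0; bool ok = true;
        for (int c = 0; c < dd; ++c) {
          int po = s1.pc(i + c, j - c), pi = s1.pc(i + c + 1, j - c - 1);
          if (po < 0 || pi < 0) { ok = false; break; }
          stk += e.stack[po][pi];
        }
        if (!ok) continue;
        int cand = vv + m2 + stk;
        if (choice && cand == target) { choice->term = 4; choice->a = dd; return cand; }
        best = std::min(best, cand);
      }
      // 5. stackII-3: motif inserted in seq2 (pair i-j carried through)
      for (int c = 1; c <= e.max_int; ++c) {
        for (int dd = 1; dd <= e.max_int; ++dd) {
          int k2 = k + c, l2 = l - dd;
          if (k2 >= l2) break;
          int vv = getV(i, j, k2, l2);
          if (vv >= INF) continue;
          int m2 = motif_t(s2, k, k2, l, l2, e);
          if (m2 >= INF) continue;
          int cand = vv + m2 + e.gap * (c + dd);
          if (choice && cand == target) { choice->term = 5; choice->a = c; choice->b = dd; return cand; }
          best = std::min(best, cand);
        }
      }
      // 6. stackII-4: motif inserted in seq1
      for (int c = 1; c <= e.max_int; ++c) {
        for (int dd = 1; dd <= e.max_int; ++dd) {
          int i2 = i + c, j2 = j - dd;
          if (i2 >= j2) break;
          int vv = getV(i2, j2, k, l);
          if (vv >= INF) continue;
          int m1 = motif_t(s1, i, i2, j, j2, e);
          if (m1 >= INF) continue;
          int cand = vv + m1 + e.gap * (c + dd);
          if (choice && cand == target) { choice->term = 6; choice->a = c; choice->b = dd; return cand; }
          best = std::min(best, cand);
        }
      }
    }
    // 7. multibranch
    {
      int base = 2 * e.mbl_b + 2 * e.mbl_a + penij + penkl;
      for (int i2 = i + 1; i2 <= j - 2; ++i2) {
        int klo = std::max(k + 1, kmin1[i2]), khi = std::min(l - 2, kmax1[i2]);
        for (int k2 = klo; k2 <= khi; ++k2) {
          int a = getW(i + 1, i2, k + 1, k2);
          if (a >= INF) continue;
          int b = getW(i2 + 1, j - 1, k2 + 1, l - 1);
          if (b >= INF) continue;
          int cand = a + b + base;
          if (choice && cand == target) { choice->term = 7; choice->a = i2; choice->b = k2; return cand; }
          best = std::min(best, cand);
        }
      }
    }
    if (mode >= 2) {
      int base = 2 * e.mbl_b + 2 * e.mbl_a + penij + penkl + e.open_;
      // 8. domain insertion, 3' side of seq2
      for (int k2 = k + 1; k2 <= l - 2; ++k2) {
        int w = getW(i + 1, j - 1, k + 1, k2);
        if (w >= INF) continue;
        int ins = wb2(k2 + 1, l - 1);
        if (ins >= INF) continue;
        int cand = w + ins + base + e.elong * (l - 1 - k2);
        if (choice && cand == target) { choice->term = 8; choice->a = k2; return cand; }
        best = std::min(best, cand);
      }
      // 9. domain insertion, 3' side of seq1
      for (int i2 = i + 1; i2 <= j - 2; ++i2) {
        int w = getW(i + 1, i2, k + 1, l - 1);
        if (w >= INF) continue;
        int ins = wb1(i2 + 1, j - 1);
        if (ins >= INF) continue;
        int cand = w + ins + base + e.elong * (j - 1 - i2);
        if (choice && cand == target) { choice->term = 9; choice->a = i2; return cand; }
        best = std::min(best, cand);
      }
      // 10. domain insertion, 5' side of seq1
      for (int i2 = i + 1; i2 <= j - 2; ++i2) {
        int w = getW(i2 + 1, j - 1, k + 1, l - 1);
        if (w >= INF) continue;
        int ins = wb1(i + 1, i2);
        if (ins >= INF) continue;
        int cand = w + ins + base + e.elong * (i2 - i);
        if (choice && cand == target) { choice->term = 10; choice->a = i2; return cand; }
        best = std::min(best, cand);
      }
      // 11. domain insertion, 5' side of seq2
      for (int k2 = k + 1; k2 <= l - 2; ++k2) {
        int w = getW(i + 1, j - 1, k2 + 1, l - 1);
        if (w >= INF) continue;
        int ins = wb2(k + 1, k2);
        if (ins >= INF) continue;
        int cand = w + ins + base + e.elong * (k2 - k);
        if (choice && cand == target) { choice->term = 11; choice->a = k2; return cand; }
        best = std::min(best, cand);
      }
    }
    if (choice) stop("traceback: no term reproduces V(%d,%d,%d,%d)", i, j, k, l);
    return std::min(best, INF);
  }

  int evalW(int i, int j, int k, int l, int target, Choice *choice) {
    if (!has_pair1(i, j) || !has_pair2(k, l)) {
      if (choice) stop("traceback: W(%d,%d,%d,%d) has no candidate branch", i, j, k, l);
      return INF;
    }
    int best = INF;
    // 1-6. unpaired terminal extensions (aligned double: no gap; single: one gap)
    {
      int w = getW(i, j - 1, k, l - 1);
      if (w < INF) {
        int cand = w + 2 * e.mbl_u;
        if (choice && cand == target) { choice->term = 1; return cand; }
        best = std::min(best, cand);
      }
      w = getW(i, j - 1, k, l);
      if (w < INF) {
        int cand = w + e.mbl_u + e.gap;
        if (choice && cand == target) { choice->term = 2; return cand; }
        best = std::min(best, cand);
      }
      w = getW(i, j, k, l - 1);
      if (w < INF) {
        int cand = w + e.mbl_u + e.gap;
        if (choice && cand == target) { choice->term = 3; return cand; }
        best = std::min(best, cand);
      }
      w = getW(i + 1, j, k + 1, l);
      if (w < INF) {
        int cand = w + 2 * e.mbl_u;
        if (choice && cand == target) { choice->term = 4; return cand; }
        best = std::min(best, cand);
      }
      w = getW(i + 1, j, k, l);
      if (w < INF) {
        int cand = w + e.mbl_u + e.gap;
        if (choice && cand == target) { choice->term = 5; return cand; }
        best = std::min(best, cand);
      }
      w = getW(i, j, k + 1, l);
      if (w < INF) {
        int cand = w + e.mbl_u + e.gap;
        if (choice && cand == target) { choice->term = 6; return cand; }
        best = std::min(best, cand);
      }
    }
    // 7-8. last conserved branch ends at (j, l); the remainder to its left
    // is either a smaller W fragment (bifurcation) or all unpaired
    if (inband(j, l)) {
      const std::vector<int> &E1 = ends1[j];
      const std::vector<int> &E2 = ends2[l];
      for (size_t x = 0; x < E1.size(); ++x) {
        int i2 = E1[x];
        if (i2 < i) continue;
        for (size_t y = 0; y < E2.size(); ++y) {
          int k2 = E2[y];
          if (k2 < k) continue;
          int vv = getV(i2, j, k2, l);
          if (vv >= INF) continue;
          int branch = vv + 2 * e.mbl_b + pen1(i2, j) + pen2(k2, l);
          if (i2 > i && k2 > k) {
            int a = getW(i, i2 - 1, k, k2 - 1);
            if (a < INF) {
              int cand = a + branch;
              if (choice && cand == target) { choice->term = 7; choice->a = i2; choice->b = k2; return cand; }
              best = std::min(best, cand);
            }
          }
          int di = i2 - i, dk = k2 - k;
          int cand = branch + e.mbl_u * (di + dk) + e.gap * std::abs(di - dk);
          if (choice && cand == target) { choice->term = 8; choice->a = i2; choice->b = k2; return cand; }
          best = std::min(best, cand);
        }
      }
    }
    if (mode >= 2) {
      // 9-12. domain insertion at the four positions
      for (int k2 = k + 1; k2 <= l - 1; ++k2) { // 3' side of seq2
        int w = getW(i, j, k, k2);
        if (w >= INF) continue;
        int ins = wb2(k2 + 1, l);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (l - k2);
        if (choice && cand == target) { choice->term = 9; choice->a = k2; return cand; }
        best = std::min(best, cand);
      }
      for (int i2 = i + 1; i2 <= j - 1; ++i2) { // 3' side of seq1
        int w = getW(i, i2, k, l);
        if (w >= INF) continue;
        int ins = wb1(i2 + 1, j);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (j - i2);
        if (choice && cand == target) { choice->term = 10; choice->a = i2; return cand; }
        best = std::min(best, cand);
      }
      for (int i2 = i; i2 <= j - 1; ++i2) { // 5' side of seq1
        int w = getW(i2 + 1, j, k, l);
        if (w >= INF) continue;
        int ins = wb1(i, i2);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (i2 - i + 1);
        if (choice && cand == target) { choice->term = 11; choice->a = i2; return cand; }
        best = std::min(best, cand);
      }
      for (int k2 = k; k2 <= l - 1; ++k2) { // 5' side of seq2
        int w = getW(i, j, k2 + 1, l);
        if (w >= INF) continue;
        int ins = wb2(k, k2);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (k2 - k + 1);
        if (choice && cand == target) { choice->term = 12; choice->a = k2; return cand; }
        best = std::min(best, cand);
      }
    }
    if (choice) stop("traceback: no term reproduces W(%d,%d,%d,%d)", i, j, k, l);
    return std::min(best, INF);
  }

  int evalW5(int i, int k, int target, Choice *choice) {
    if (i == 0 && k == 0) {
      if (choice) { choice->term = 0; }
      return 0;
    }
    int best = INF;
    // 1. diagonal extension (aligned unpaired, free)
    if (i >= 1 && k >= 1) {
      int w = getW5(i - 1, k - 1);
      if (w < INF) {
        if (choice && w == target) { choice->term = 1; return w; }
        best = std::min(best, w);
      }
    }
    // 2-3. single-side extensions (one gap)
    if (i >= 1) {
      int w = getW5(i - 1, k);
      if (w < INF) {
        int cand = w + e.gap;
        if (choice && cand == target) { choice->term = 2; return cand; }
        best = std::min(best, cand);
      }
    }
    if (k >= 1) {
      int w = getW5(i, k - 1);
      if (w < INF) {
        int cand = w + e.gap;
        if (choice && cand == target) { choice->term = 3; return cand; }
        best = std::min(best, cand);
      }
    }
    // 4. bifurcation: conserved branch ending at (i, k)
    if (i >= 1 && k >= 1 && i <= N1 && k <= N2) {
      const std::vector<int> &E1 = ends1[i];
      const std::vector<int> &E2 = ends2[k];
      for (size_t x = 0; x < E1.size(); ++x) {
        int a = E1[x];
        for (size_t y = 0; y < E2.size(); ++y) {
          int b = E2[y];
          int w = getW5(a - 1, b - 1);
          if (w >= INF) continue;
          int vv = getV(a, i, b, k);
          if (vv >= INF) continue;
          int cand = w + vv + pen1(a, i) + pen2(b, k);
          if (choice && cand == target) { choice->term = 4; choice->a = a; choice->b = b; return cand; }
          best = std::min(best, cand);
        }
      }
    }
    if (mode >= 2) {
      // 5. inserted domain at 3' end of seq1 prefix
      for (int i2 = 0; i2 <= i - 1; ++i2) {
        int w = getW5(i2, k);
        if (w >= INF) continue;
        int ins = we1(i2 + 1, i);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (i - i2);
        if (choice && cand == target) { choice->term = 5; choice->a = i2; return cand; }
        best = std::min(best, cand);
      }
      // 6. inserted domain at 3' end of seq2 prefix
      for (int k2 = 0; k2 <= k - 1; ++k2) {
        int w = getW5(i, k2);
        if (w >= INF) continue;
        int ins = we2(k2 + 1, k);
        if (ins >= INF) continue;
        int cand = w + ins + e.open_ + e.elong * (k - k2);
        if (choice && cand == target) { choice->term = 6; choice->a = k2; return cand; }
        best = std::min(best, cand);
      }
    }
    if (choice) stop("traceback: no term reproduces W5(%d,%d)", i, k);
    return std::min(best, INF);
  }

  int evalW3(int j, int l) {
    if (j == N1 + 1 && l == N2 + 1) return 0;
    int best = INF;
    if (j <= N1 && l <= N2) {
      int w = getW3(j + 1, l + 1);
      if (w < INF) best = std::min(best, w);
    }
    if (j <= N1) {
      int w = getW3(j + 1, l);
      if (w < INF) best = std::min(best, w + e.gap);
    }
    if (l <= N2) {
      int w = getW3(j, l + 1);
      if (w < INF) best = std::min(best, w + e.gap);
    }
    if (j <= N1 && l <= N2) {
      const std::vector<int> &S1 = starts1[j];
      const std::vector<int> &S2 = starts2[l];
      for (size_t x = 0; x < S1.size(); ++x) {
        int e1 = S1[x];
        for (size_t y = 0; y < S2.size(); ++y) {
          int e2 = S2[y];
          int w = getW3(e1 + 1, e2 + 1);
          if (w >= INF) continue;
          int vv = getV(j, e1, l, e2);
          if (vv >= INF) continue;
          best = std::min(best, w + vv + pen1(j, e1) + pen2(l, e2));
        }
      }
    }
    if (mode >= 2) {
      for (int j2 = j + 1; j2 <= N1 + 1; ++j2) {
        int w = getW3(j2, l);
        if (w >= INF) continue;
        int ins = we1(j, j2 - 1);
        if (ins >= INF) continue;
        best = std::min(best, w + ins + e.open_ + e.elong * (j2 - j));
      }
      for (int l2 = l + 1; l2 <= N2 + 1; ++l2) {
        int w = getW3(j, l2);
        if (w >= INF) continue;
        int ins = we2(l, l2 - 1);
        if (ins >= INF) continue;
        best = std::min(best, w + ins + e.open_ + e.elong * (l2 - l));
      }
    }
    return std::min(best, INF);
  }

  void fill() {
    build_inner_lists();
    for (int span1 = 0; span1 < N1; ++span1) {
      for (int span2 = 0; span2 < N2; ++span2) {
        for (int i = 1; i + span1 <= N1; ++i) {
          int j = i + span1;
          if (!has_pair1(i, j)) continue;
          int klo = std::max(1, kmin1[i]), khi = kmax1[i];
          for (int k = klo; k <= khi; ++k) {
            int l = k + span2;
            if (l > N2 || !inband(j, l)) continue;
            size_t id = idx(i, j, k, l);
            Varr[id] = evalV(i, j, k, l, -1, 0);
            if (encl1(i, j) && encl2(k, l))
              Warr[id] = evalW(i, j, k, l, -1, 0);
          }
        }
      }
    }
    for (int i = 0; i <= N1; ++i)
      for (int k = std::max(0, kmin1[i]); k <= kmax1[i]; ++k)
        if (k <= N2) w5arr[(size_t)i * (N2 + 1) + k] = evalW5(i, k, -1, 0);
    for (int j = N1 + 1; j >= 1; --j)
      for (int l = kmax1[j - 1] + 1; l >= std::max(1, kmin1[j - 1] + 1); --l)
        if (l <= N2 + 1) w3arr[(size_t)j * (N2 + 2) + l] = evalW3(j, l);
  }

  // ---- traceback state
  std::vector<int> p1of, p2of;       // pair partners, 0 = unpaired
  std::vector<int> aln1, aln2;       // aligned partner position, 0 = unaligned
  std::vector<std::array<int,4> > matched; // conserved quadruples i j k l
  std::vector<std::array<int,3> > domains; // host(1/2), start, end
  SingleDP *sdp1, *sdp2;             // for tracing inserted-domain content

  void align(int i, int k) { aln1[i] = k; aln2[k] = i; }
  void align_run(int fi, int ui, int fk, int uk) {
    // pair up to min(ui,uk) loop nucleotides from the 5' side
    int m = std::min(ui, uk);
    for (int t = 1; t <= m; ++t) align(fi + t, fk + t);
  }
  void align_run3(int ti, int ui, int tk, int uk) {
    int m = std::min(ui, uk);
    for (int t = 1; t <= m; ++t) align(ti - t, tk - t);
  }
  void add_domain(int host, int a, int b) {
    std::array<int,3> d3 = {{host, a, b}};
    domains.push_back(d3);
    if (host == 1) sdp1->tb_wb(a, b, p1of); else sdp2->tb_wb(a, b, p2of);
  }
  void add_domain_ext(int host, int a, int b) {
    std::array<int,3> d3 = {{host, a, b}};
    domains.push_back(d3);
    if (host == 1) sdp1->tb_we(a, b, p1of); else sdp2->tb_we(a, b, p2of);
  }

  void tb_V(int i, int j, int k, int l, bool emit) {
    int target = getV(i, j, k, l);
    if (target >= INF) stop("traceback: V(%d,%d,%d,%d) infinite", i, j, k, l);
    if (emit) {
      std::array<int,4> q = {{i, j, k, l}};
      matched.push_back(q);
      align(i, k); align(j, l);
    }
    p1of[i] = j; p1of[j] = i; p2of[k] = l; p2of[l] = k;
    Choice ch;
    evalV(i, j, k, l, target, &ch);
    switch (ch.term) {
      case 1: // hairpin
        align_run(i, j - i - 1, k, l - k - 1);
        return;
      case 2: { // conserved motif
        int i2 = ch.a, j2 = ch.b, k2 = ch.c, l2 = ch.dd;
        align_run(i, i2 - i - 1, k, k2 - k - 1);
        align_run3(j, j - j2 - 1, l, l - l2 - 1);
        tb_V(i2, j2, k2, l2, true);
        return;
      }
      case 3: { // stackII-1: stacked run in seq2
        int dd = ch.a;
        for (int t = 1; t <= dd - 1; ++t) {
          p2of[k + t] = l - t; p2of[l - t] = k + t;
          align(i + t, k + t); align(j - t, l - t);
        }
        tb_V(i + dd, j - dd, k + dd, l - dd, true);
        return;
      }
      case 4: { // stackII-2: stacked run in seq1
        int dd = ch.a;
        for (int t = 1; t <= dd - 1; ++t) {
          p1of[i + t] = j - t; p1of[j - t] = i + t;
          align(i + t, k + t); align(j - t, l - t);
        }
        tb_V(i + dd, j - dd, k + dd, l - dd, true);
        return;
      }
      case 5: // stackII-3: motif inserted in seq2; nucleotides unaligned
        tb_V(i, j, k + ch.a, l - ch.b, false);
        p1of[i] = j; p1of[j] = i; // keep outer seq1 pair (re-set by recursion)
        return;
      case 6: // stackII-4: motif inserted in seq1
        tb_V(i + ch.a, j - ch.b, k, l, false);
        p1of[i] = j; p1of[j] = i; p2of[k] = l; p2of[l] = k;
        return;
      case 7:
        tb_W(i + 1, ch.a, k + 1, ch.b);
        tb_W(ch.a + 1, j - 1, ch.b + 1, l - 1);
        return;
      case 8:
        tb_W(i + 1, j - 1, k + 1, ch.a);
        add_domain(2, ch.a + 1, l - 1);
        return;
      case 9:
        tb_W(i + 1, ch.a, k + 1, l - 1);
        add_domain(1, ch.a + 1, j - 1);
        return;
      case 10:
        add_domain(1, i + 1, ch.a);
        tb_W(ch.a + 1, j - 1, k + 1, l - 1);
        return;
      case 11:
        add_domain(2, k + 1, ch.a);
        tb_W(i + 1, j - 1, ch.a + 1, l - 1);
        return;
    }
    stop("traceback: unknown V term");
  }

  void tb_W(int i, int j, int k, int l) {
    int target = getW(i, j, k, l);
    if (target >= INF) stop("traceback: W(%d,%d,%d,%d) infinite", i, j, k, l);
    Choice ch;
    evalW(i, j, k, l, target, &ch);
    switch (ch.term) {
      case 1: align(j, l); tb_W(i, j - 1, k, l - 1); return;
      case 2: tb_W(i, j - 1, k, l); return;
      case 3: tb_W(i, j, k, l - 1); return;
      case 4: align(i, k); tb_W(i + 1, j, k + 1, l); return;
      case 5: tb_W(i + 1, j, k, l); return;
      case 6: tb_W(i, j, k + 1, l); return;
      case 7: tb_W(i, ch.a - 1, k, ch.b - 1); tb_V(ch.a, j, ch.b, l, true); return;
      case 8: {
        int m = std::min(ch.a - i, ch.b - k);
        for (int t = 0; t < m; ++t) align(i + t, k + t);
        tb_V(ch.a, j, ch.b, l, true);
        return;
      }
      case 9: tb_W(i, j, k, ch.a); add_domain(2, ch.a + 1, l); return;
      case 10: tb_W(i, ch.a, k, l); add_domain(1, ch.a + 1, j); return;
      case 11: add_domain(1, i, ch.a); tb_W(ch.a + 1, j, k, l); return;
      case 12: add_domain(2, k, ch.a); tb_W(i, j, ch.a + 1, l); return;
    }
    stop("traceback: unknown W term");
  }

  void tb_W5(int i, int k) {
    int target = getW5(i, k);
    if (target >= INF) stop("traceback: W5(%d,%d) infinite", i, k);
    Choice ch;
    evalW5(i, k, target, &ch);
    switch (ch.term) {
      case 0: return;
      case 1: align(i, k); tb_W5(i - 1, k - 1); return;
      case 2: tb_W5(i - 1, k); return;
      case 3: tb_W5(i, k - 1); return;
      case 4: tb_W5(ch.a - 1, ch.b - 1); tb_V(ch.a, i, ch.b, k, true); return;
      case 5: tb_W5(ch.a, k); add_domain_ext(1, ch.a + 1, i); return;
      case 6: tb_W5(i, ch.a); add_domain_ext(2, ch.a + 1, k); return;
    }
    stop("traceback: unknown W5 term");
  }

  List traceback(SingleDP &d1, SingleDP &d2) {
    sdp1 = &d1; sdp2 = &d2;
    p1of.assign(N1 + 1, 0); p2of.assign(N2 + 1, 0);
    aln1.assign(N1 + 1, 0); aln2.assign(N2 + 1, 0);
    matched.clear(); domains.clear();
    tb_W5(N1, N2);
    IntegerMatrix mm(matched.size(), 4), dm(domains.size(), 3);
    for (size_t x = 0; x < matched.size(); ++x)
      for (int c = 0; c < 4; ++c) mm(x, c) = matched[x][c];
    for (size_t x = 0; x < domains.size(); ++x)
      for (int c = 0; c < 3; ++c) dm(x, c) = domains[x][c];
    return List::create(
      _["pair1of"] = IntegerVector(p1of.begin() + 1, p1of.end()),
      _["pair2of"] = IntegerVector(p2of.begin() + 1, p2of.end()),
      _["aln1"] = IntegerVector(aln1.begin() + 1, aln1.end()),
      _["aln2"] = IntegerVector(aln2.begin() + 1, aln2.end()),
      _["matched"] = mm, _["domains"] = dm);
  }
};

// [[Rcpp::export(name = ".joint_fill_cpp")]]
List joint_fill_cpp(IntegerVector seq1_codes, IntegerVector seq2_codes,
                    List params, int band_d, int mode,
                    IntegerMatrix wb1, IntegerMatrix wb2,
                    IntegerMatrix we1, IntegerMatrix we2,
                    LogicalMatrix allowed1, LogicalMatrix allowed2,
                    bool trace) {
  EP e = ep_from_list(params);
  Seq s1(seq1_codes), s2(seq2_codes);
  Joint jt(s1, s2, e, band_d, mode, wb1, wb2, we1, we2, allowed1, allowed2);
  jt.fill();
  int opt = jt.getW5(s1.N, s2.N);
  int w311 = jt.getW3(1, 1);
  List out = List::create(_["energy"] = (opt >= INF) ? NA_INTEGER : opt,
                          _["w3_11"] = (w311 >= INF) ? NA_INTEGER : w311,
                          _["band_d"] = band_d, _["mode"] = mode);
  if (trace && opt < INF) {
    SingleDP d1(s1, e), d2(s2, e);
    d1.fill(); d2.fill();
    out["trace"] = jt.traceback(d1, d2);
  }
  return out;
}
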