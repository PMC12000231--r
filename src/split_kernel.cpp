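// Hot loops for permutation-based split-half reliability.
//
// Trials arrive sorted by (participant, condition cell, stimulus).
// Splitting follows the balanced pair-split scheme: trials are randomly
// paired within each bottom stratum, each pair feeds one trial to each
// half, odd leftovers are pooled and pair-split at the parent stratum,
// and a final odd trial per participant is assigned by a coin flip.
//
// The split loop runs millions of RNG draws, so it uses a local
// xoshiro256++ generator seeded from R's RNG at entry: results remain
// fully determined by set.seed() while avoiding the per-call overhead
// of unif_rand().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <stdint.h>
using namespace Rcpp;

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // Seed from R's RNG so the kernel is reproducible under set.seed().
  void seed_from_r() {
    uint64_t a = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t b = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t x = (a << 32) ^ b;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline int rand_int(int n) {  // uniform on 0..n-1
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
  inline bool coin() { return next() >> 63; }
};

// Pair-split trial indices idx[0..m-1] (shuffled in place), writing
// half labels (0/1); returns leftover trial index or -1.
static inline int pair_split_cpp(int* idx, int m,
                                 std::vector<unsigned char>& half,
                                 Xoshiro& rng) {
  if (m == 0) return -1;
  for (int i = m - 1; i > 0; --i) {
    int j = rng.rand_int(i + 1);
    std::swap(idx[i], idx[j]);
  }
  int npair = m / 2;
  for (int j = 0; j < npair; ++j) {
    unsigned char h = rng.coin();
    half[idx[2 * j]] = h;
    half[idx[2 * j + 1]] = 1 - h;
  }
  return (m % 2) ? idx[m - 1] : -1;
}

struct Run { int start, end; };

struct Layout {
  int T, n_parts, K;
  std::vector<int> pstart;
  std::vector<Run> cell_runs;
  std::vector<int> crstart;
  std::vector<Run> stim_runs;
  std::vector<int> srstart;
};

static Layout build_layout(const IntegerVector& part,
                           const IntegerVector& cell,
                           const IntegerVector& stim,
                           int n_parts, bool with_stim) {
  Layout L;
  L.T = part.size();
  L.n_parts = n_parts;
  L.pstart.assign(n_parts + 1, 0);
  for (int t = 0; t < L.T; ++t) L.pstart[part[t] + 1]++;
  for (int p = 0; p < n_parts; ++p) L.pstart[p + 1] += L.pstart[p];

  L.crstart.push_back(0);
  for (int p = 0; p < n_parts; ++p) {
    int s = L.pstart[p], e = L.pstart[p + 1];
    int t = s;
    while (t < e) {
      int c = cell[t], u = t;
      while (u < e && cell[u] == c) ++u;
      Run r = { t, u };
      L.cell_runs.push_back(r);
      t = u;
    }
    L.crstart.push_back((int)L.cell_runs.size());
  }
  if (with_stim) {
    L.srstart.push_back(0);
    for (size_t cr = 0; cr < L.cell_runs.size(); ++cr) {
      int t = L.cell_runs[cr].start, e = L.cell_runs[cr].end;
      while (t < e) {
        int sid = stim[t], u = t;
        while (u < e && stim[u] == sid) ++u;
        Run r = { t, u };
        L.stim_runs.push_back(r);
        t = u;
      }
      L.srstart.push_back((int)L.stim_runs.size());
    }
  }
  return L;
}

// Assign halves for one participant under the hierarchical pair-split.
static inline void assign_participant(const Layout& L, int p,
                                      bool stratify,
                                      std::vector<unsigned char>& half,
                                      std::vector<int>& tmp,
                                      std::vector<int>& cellbuf,
                                      std::vector<int>& partbuf,
                                      Xoshiro& rng) {
  partbuf.clear();
  for (int cr = L.crstart[p]; cr < L.crstart[p + 1]; ++cr) {
    if (stratify) {
      cellbuf.clear();
      for (int sr = L.srstart[cr]; sr < L.srstart[cr + 1]; ++sr) {
        int m = L.stim_runs[sr].end - L.stim_runs[sr].start;
        tmp.resize(m);
        for (int j = 0; j < m; ++j) tmp[j] = L.stim_runs[sr].start + j;
        int lo = pair_split_cpp(tmp.data(), m, half, rng);
        if (lo >= 0) cellbuf.push_back(lo);
      }
      int lo = pair_split_cpp(cellbuf.data(), (int)cellbuf.size(), half,
                              rng);
      if (lo >= 0) partbuf.push_back(lo);
    } else {
      int m = L.cell_runs[cr].end - L.cell_runs[cr].start;
      tmp.resize(m);
      for (int j = 0; j < m; ++j) tmp[j] = L.cell_runs[cr].start + j;
      int lo = pair_split_cpp(tmp.data(), m, half, rng);
      if (lo >= 0) partbuf.push_back(lo);
    }
  }
  int lo = pair_split_cpp(partbuf.data(), (int)partbuf.size(), half, rng);
  if (lo >= 0) half[lo] = rng.coin();
}

static inline double median_of(std::vector<double>& v) {
  size_t m = v.size();
  std::sort(v.begin(), v.end());
  return (m % 2) ? v[m / 2] : 0.5 * (v[m / 2 - 1] + v[m / 2]);
}

// Pearson correlation of pairs finite in both vectors.
static void correlate(const std::vector<double>& x,
                      const std::vector<double>& y,
                      double& r_out, int& n_out) {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int n = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    if (R_finite(x[i]) && R_finite(y[i])) {
      ++n;
      sx += x[i]; sy += y[i];
      sxx += x[i] * x[i]; syy += y[i] * y[i]; sxy += x[i] * y[i];
    }
  }
  n_out = n;
  if (n < 4) { r_out = NA_REAL; return; }
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  double cxy = sxy - sx * sy / n;
  if (vx <= 0 || vy <= 0) { r_out = NA_REAL; return; }
  r_out = cxy / std::sqrt(vx * vy);
}

// Shared per-participant scoring state for the general (median /
// d-score) path.
struct ScoreState {
  int K;
  bool want_median, want_dscore;
  std::vector<double> csum;
  std::vector<int> ccnt;
  std::vector<std::vector<double> > cvals;
  double psum[2], psumsq[2];
  int pcnt[2];

  void init(int K_, bool med, bool dsc) {
    K = K_; want_median = med; want_dscore = dsc;
    csum.assign(2 * K, 0.0);
    ccnt.assign(2 * K, 0);
    cvals.assign(2 * K, std::vector<double>());
  }
  inline void reset() {
    std::fill(csum.begin(), csum.end(), 0.0);
    std::fill(ccnt.begin(), ccnt.end(), 0);
    if (want_median)
      for (size_t i = 0; i < cvals.size(); ++i) cvals[i].clear();
    psum[0] = psum[1] = psumsq[0] = psumsq[1] = 0.0;
    pcnt[0] = pcnt[1] = 0;
  }
  inline void add(int h, int c, double v) {
    csum[h * K + c] += v;
    ccnt[h * K + c]++;
    if (want_median) cvals[h * K + c].push_back(v);
    if (want_dscore) {
      psum[h] += v; psumsq[h] += v * v; pcnt[h]++;
    }
  }
  void scores(const double* w, double out[3][2]) {
    for (int a = 0; a < 3; ++a) out[a][0] = out[a][1] = NA_REAL;
    for (int h = 0; h < 2; ++h) {
      bool complete = true;
      for (int c = 0; c < K; ++c)
        if (ccnt[h * K + c] == 0) { complete = false; break; }
      if (!complete) continue;
      double sm = 0.0;
      for (int c = 0; c < K; ++c)
        sm += w[c] * csum[h * K + c] / ccnt[h * K + c];
      out[0][h] = sm;
      if (want_median) {
        double smed = 0.0;
        for (int c = 0; c < K; ++c)
          smed += w[c] * median_of(cvals[h * K + c]);
        out[1][h] = smed;
      }
      if (want_dscore) {
        int n = pcnt[h];
        if (n >= 2) {
          double var = (psumsq[h] - psum[h] * psum[h] / n) / (n - 1);
          if (var > 0) out[2][h] = sm / std::sqrt(var);
        }
      }
    }
  }
};

static void finish_iter(int s, bool wants[3],
                        std::vector<std::vector<double> >& s1,
                        std::vector<std::vector<double> >& s2,
                        NumericMatrix& cors, IntegerMatrix& ns) {
  for (int a = 0; a < 3; ++a) {
    if (!wants[a]) { cors(s, a) = NA_REAL; ns(s, a) = 0; continue; }
    double r; int n;
    correlate(s1[a], s2[a], r, n);
    cors(s, a) = r;
    ns(s, a) = n;
  }
}

// [[Rcpp::export]]
List split_pool_kernel(NumericVector rt, IntegerVector part,
                       IntegerVector cell, IntegerVector stim,
                       int n_parts, int n_cells, NumericVector weights,
                       int n_splits, bool stratify,
                       bool want_mean, bool want_median,
                       bool want_dscore) {
  Layout L = build_layout(part, cell, stim, n_parts, stratify);
  Xoshiro rng;
  rng.seed_from_r();
  std::vector<unsigned char> half(L.T, 0);
  std::vector<int> tmp, cellbuf, partbuf;
  bool wants[3] = { want_mean, want_median, want_dscore };
  bool general = want_median || want_dscore;
  ScoreState st;
  st.init(n_cells, want_median, want_dscore);
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<std::vector<double> > s1(3), s2(3);
  for (int a = 0; a < 3; ++a) {
    s1[a].assign(n_parts, NA_REAL);
    s2[a].assign(n_parts, NA_REAL);
  }
  NumericMatrix cors(n_splits, 3);
  IntegerMatrix ns(n_splits, 3);
  std::vector<double> csum(2 * n_cells);
  std::vector<int> ccnt(2 * n_cells);

  for (int s = 0; s < n_splits; ++s) {
    for (int p = 0; p < n_parts; ++p) {
      assign_participant(L, p, stratify, half, tmp, cellbuf, partbuf,
                         rng);
      if (!general) {
        // mean-only fast path
        std::fill(csum.begin(), csum.end(), 0.0);
        std::fill(ccnt.begin(), ccnt.end(), 0);
        for (int t = L.pstart[p]; t < L.pstart[p + 1]; ++t) {
          int i = half[t] * n_cells + cell[t];
          csum[i] += rt[t];
          ccnt[i]++;
        }
        for (int h = 0; h < 2; ++h) {
          double sm = 0.0;
          bool complete = true;
          for (int c = 0; c < n_cells; ++c) {
            int i = h * n_cells + c;
            if (ccnt[i] == 0) { complete = false; break; }
            sm += w[c] * csum[i] / ccnt[i];
          }
          double v = complete ? sm : NA_REAL;
          if (h == 0) s1[0][p] = v; else s2[0][p] = v;
        }
      } else {
        st.reset();
        for (int t = L.pstart[p]; t < L.pstart[p + 1]; ++t)
          st.add(half[t], cell[t], rt[t]);
        double sc[3][2];
        st.scores(w.data(), sc);
        for (int a = 0; a < 3; ++a) {
          s1[a][p] = sc[a][0];
          s2[a][p] = sc[a][1];
        }
      }
    }
    finish_iter(s, wants, s1, s2, cors, ns);
    if ((s & 255) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(cors) = CharacterVector::create("mean", "median", "dscore");
  colnames(ns) = CharacterVector::create("mean", "median", "dscore");
  return List::create(_["cor"] = cors, _["n"] = ns);
}

// [[Rcpp::export]]
List mc_pool_kernel(NumericVector rt, IntegerVector part,
                    IntegerVector cell, int n_parts, int n_cells,
                    NumericVector weights, int n_draws,
                    bool want_mean, bool want_median, bool want_dscore) {
  IntegerVector dummy(0);
  Layout L = build_layout(part, cell, dummy, n_parts, false);
  Xoshiro rng;
  rng.seed_from_r();
  bool wants[3] = { want_mean, want_median, want_dscore };
  ScoreState st;
  st.init(n_cells, want_median, want_dscore);
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<std::vector<double> > s1(3), s2(3);
  for (int a = 0; a < 3; ++a) {
    s1[a].assign(n_parts, NA_REAL);
    s2[a].assign(n_parts, NA_REAL);
  }
  NumericMatrix cors(n_draws, 3);
  IntegerMatrix ns(n_draws, 3);

  for (int d = 0; d < n_draws; ++d) {
    for (int p = 0; p < n_parts; ++p) {
      int s0 = L.pstart[p], m = L.pstart[p + 1] - s0;
      // two independent with-replacement resamples of size m,
      // entered as the two "halves" of the accumulator
      st.reset();
      for (int h = 0; h < 2; ++h) {
        for (int j = 0; j < m; ++j) {
          int t = s0 + rng.rand_int(m);
          st.add(h, cell[t], rt[t]);
        }
      }
      double sc[3][2];
      st.scores(w.data(), sc);
      for (int a = 0; a < 3; ++a) {
        s1[a][p] = sc[a][0];
        s2[a][p] = sc[a][1];
      }
    }
    finish_iter(d, wants, s1, s2, cors, ns);
    if ((d & 255) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(cors) = CharacterVector::create("mean", "median", "dscore");
  colnames(ns) = CharacterVector::create("mean", "median", "dscore");
  return List::create(_["cor"] = cors, _["n"] = ns);
}
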