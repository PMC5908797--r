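// Thermodynamic RNA secondary-structure engine: Zuker-style MFE folding and
// McCaskill partition-function base-pair probabilities over a simplified
// nearest-neighbor parameter set (Watson-Crick + GU stacking table, loop
// initiation penalties, linear multiloop model). Pseudoknot-free, minimum
// hairpin loop of 3, interior loops capped at 30 unpaired bases.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF_E = 1e9;
static const double RT = 0.6163;      // kcal/mol at 37 C
static const int MIN_HP = 3;          // minimum hairpin loop size
static const int MAXLOOP = 30;        // interior/bulge unpaired cap

// pair types: 0 = none, 1..6 = CG GC GU UG AU UA
static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'U': return 3;
  }
  return -1;
}

static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 1; // CG
  if (a == 2 && b == 1) return 2; // GC
  if (a == 2 && b == 3) return 3; // GU
  if (a == 3 && b == 2) return 4; // UG
  if (a == 0 && b == 3) return 5; // AU
  if (a == 3 && b == 0) return 6; // UA
  return 0;
}

// stack[outer][inner], outer/inner in 1..6 (CG GC GU UG AU UA), kcal/mol
static const double STACK[7][7] = {
  {0, 0, 0, 0, 0, 0, 0},
  {0, -3.26, -2.36, -1.41, -2.11, -2.11, -2.08}, // outer CG
  {0, -3.42, -3.26, -1.53, -2.51, -2.35, -2.24}, // outer GC
  {0, -2.51, -2.11,  0.47,  1.29, -1.27, -1.36}, // outer GU
  {0, -1.53, -1.41,  0.30,  0.47, -1.00, -0.55}, // outer UG
  {0, -2.24, -2.08, -0.55, -1.36, -0.93, -1.10}, // outer AU
  {0, -2.35, -2.11, -1.00, -1.27, -1.33, -0.93}  // outer UA
};

static const double HP_INIT[10] = {INF_E, INF_E, INF_E, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
static const double BULGE_INIT[7] = {INF_E, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4};
static const double IL_INIT[7] = {INF_E, INF_E, 1.5, 1.6, 1.7, 2.0, 2.0};

static const double ML_CLOSE = 3.4;   // multiloop initiation (a)
static const double ML_BRANCH = 0.4;  // per branch, incl. closing pair (b)
static const double ML_UNPAIRED = 0.0; // per unpaired base (c)
static const double TERM_AU = 0.5;    // AU/GU hairpin closure penalty

static inline double hairpin_energy(int pt, int size) {
  double e = (size <= 9) ? HP_INIT[size] : HP_INIT[9] + 1.75 * RT * std::log((double)size / 9.0);
  if (pt >= 3) e += TERM_AU; // GU/UG/AU/UA closure
  return e;
}

static inline double loop_energy(int pt_out, int pt_in, int n1, int n2) {
  if (n1 == 0 && n2 == 0) return STACK[pt_out][pt_in];
  int n = n1 + n2;
  if (n1 == 0 || n2 == 0) {
    return (n <= 6) ? BULGE_INIT[n] : BULGE_INIT[6] + 1.75 * RT * std::log((double)n / 6.0);
  }
  double e = (n <= 6) ? IL_INIT[n] : IL_INIT[6] + 1.75 * RT * std::log((double)n / 6.0);
  double asym = 0.5 * std::abs(n1 - n2);
  if (asym > 3.0) asym = 3.0;
  return e + asym;
}

struct SeqCode {
  int n;
  std::vector<int> b;          // base indices
  std::vector<int> pt;         // pair type for (i,j), flattened i*n+j, 0 if not allowed
  SeqCode(const std::string &s, int max_span) {
    n = (int)s.size();
    b.resize(n);
    for (int i = 0; i < n; i++) b[i] = base_idx(s[i]);
    pt.assign((size_t)n * n, 0);
    for (int i = 0; i < n; i++)
      for (int j = i + MIN_HP + 1; j < n; j++) {
        if (max_span > 0 && (j - i + 1) > max_span) continue;
        pt[(size_t)i * n + j] = pair_type(b[i], b[j]);
      }
  }
  inline int P(int i, int j) const { return pt[(size_t)i * n + j]; }
};

// ---------------------------------------------------------------- MFE ------

struct MfeTables {
  int n;
  std::vector<double> V, WM;
  std::vector<double> W;
  inline double &v(int i, int j) { return V[(size_t)i * n + j]; }
  inline double &wm(int i, int j) { return WM[(size_t)i * n + j]; }
};

static void mfe_fill(const SeqCode &sc, MfeTables &t) {
  int n = sc.n;
  t.n = n;
  t.V.assign((size_t)n * n, INF_E);
  t.WM.assign((size_t)n * n, INF_E);
  t.W.assign(n + 1, 0.0);
  for (int d = MIN_HP + 1; d < n; d++) {
    for (int i = 0; i + d < n; i++) {
      int j = i + d;
      int pt = sc.P(i, j);
      if (pt) {
        double best = hairpin_energy(pt, j - i - 1);
        int kmax = std::min(j - MIN_HP - 2, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; k++) {
          int lmin = std::max(k + MIN_HP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = lmin; l < j; l++) {
            int pt2 = sc.P(k, l);
            if (!pt2) continue;
            double e = loop_energy(pt, pt2, k - i - 1, j - l - 1) + t.v(k, l);
            if (e < best) best = e;
          }
        }
        // multiloop closing: >= 2 inner branches
        for (int k = i + 2; k <= j - 2; k++) {
          double e1 = t.wm(i + 1, k), e2 = t.wm(k + 1, j - 1);
          if (e1 < INF_E / 2 && e2 < INF_E / 2) {
            double e = ML_CLOSE + ML_BRANCH + e1 + e2;
            if (e < best) best = e;
          }
        }
        t.v(i, j) = best;
      }
      // WM
      double w = INF_E;
      if (pt && t.v(i, j) < INF_E / 2) w = t.v(i, j) + ML_BRANCH;
      if (t.wm(i + 1, j) < INF_E / 2) w = std::min(w, t.wm(i + 1, j) + ML_UNPAIRED);
      if (j > 0 && t.wm(i, j - 1) < INF_E / 2) w = std::min(w, t.wm(i, j - 1) + ML_UNPAIRED);
      for (int k = i + 1; k < j; k++) {
        double e1 = t.wm(i, k), e2 = t.wm(k + 1, j);
        if (e1 < INF_E / 2 && e2 < INF_E / 2) w = std::min(w, e1 + e2);
      }
      t.wm(i, j) = w;
    }
  }
  // W[j+1]: optimal energy of prefix 0..j (W[0] = 0)
  for (int j = 0; j < n; j++) {
    double best = t.W[j]; // leave j unpaired
    for (int i = 0; i <= j - MIN_HP - 1; i++) {
      if (!sc.P(i, j)) continue;
      double e = t.W[i] + t.v(i, j);
      if (e < best) best = e;
    }
    t.W[j + 1] = best;
  }
}

static void mfe_traceback(const SeqCode &sc, MfeTables &t, std::string &db) {
  int n = sc.n;
  db.assign(n, '.');
  const double eps = 1e-7;
  std::vector<std::pair<std::pair<int,int>,int>> stack; // ((i,j), state) 0=ext j, 1=V, 2=WM
  stack.push_back({{0, n - 1}, 0});
  while (!stack.empty()) {
    auto top = stack.back(); stack.pop_back();
    int i = top.first.first, j = top.first.second, state = top.second;
    if (state == 0) { // external segment 0..j
      int jj = j;
      while (jj >= 0) {
        if (std::abs(t.W[jj + 1] - t.W[jj]) < eps) { jj--; continue; } // unpaired
        bool found = false;
        for (int i0 = 0; i0 <= jj - MIN_HP - 1 && !found; i0++) {
          if (!sc.P(i0, jj)) continue;
          double e = t.W[i0] + t.v(i0, jj);
          if (std::abs(e - t.W[jj + 1]) < eps) {
            stack.push_back({{i0, jj}, 1});
            jj = i0 - 1;
            found = true;
          }
        }
        if (!found) jj--; // numerical guard
      }
    } else if (state == 1) { // V(i,j): (i,j) pairs
      db[i] = '('; db[j] = ')';
      int pt = sc.P(i, j);
      double target = t.v(i, j);
      if (std::abs(hairpin_energy(pt, j - i - 1) - target) < eps) continue;
      bool found = false;
      int kmax = std::min(j - MIN_HP - 2, i + MAXLOOP + 1);
      for (int k = i + 1; k <= kmax && !found; k++) {
        int lmin = std::max(k + MIN_HP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
        for (int l = lmin; l < j && !found; l++) {
          int pt2 = sc.P(k, l);
          if (!pt2) continue;
          if (std::abs(loop_energy(pt, pt2, k - i - 1, j - l - 1) + t.v(k, l) - target) < eps) {
            stack.push_back({{k, l}, 1});
            found = true;
          }
        }
      }
      for (int k = i + 2; k <= j - 2 && !found; k++) {
        double e1 = t.wm(i + 1, k), e2 = t.wm(k + 1, j - 1);
        if (e1 < INF_E / 2 && e2 < INF_E / 2 &&
            std::abs(ML_CLOSE + ML_BRANCH + e1 + e2 - target) < eps) {
          stack.push_back({{i + 1, k}, 2});
          stack.push_back({{k + 1, j - 1}, 2});
          found = true;
        }
      }
    } else { // WM(i,j)
      double target = t.wm(i, j);
      if (target >= INF_E / 2) continue;
      if (sc.P(i, j) && std::abs(t.v(i, j) + ML_BRANCH - target) < eps) {
        stack.push_back({{i, j}, 1});
        continue;
      }
      if (t.wm(i + 1, j) < INF_E / 2 && std::abs(t.wm(i + 1, j) + ML_UNPAIRED - target) < eps) {
        stack.push_back({{i + 1, j}, 2});
        continue;
      }
      if (j > 0 && t.wm(i, j - 1) < INF_E / 2 && std::abs(t.wm(i, j - 1) + ML_UNPAIRED - target) < eps) {
        stack.push_back({{i, j - 1}, 2});
        continue;
      }
      for (int k = i + 1; k < j; k++) {
        double e1 = t.wm(i, k), e2 = t.wm(k + 1, j);
        if (e1 < INF_E / 2 && e2 < INF_E / 2 && std::abs(e1 + e2 - target) < eps) {
          stack.push_back({{i, k}, 2});
          stack.push_back({{k + 1, j}, 2});
          break;
        }
      }
    }
  }
}

static std::string fold_one(const std::string &seq) {
  int n = (int)seq.size();
  if (n <= MIN_HP + 1) return std::string(n, '.');
  SeqCode sc(seq, 0);
  MfeTables t;
  mfe_fill(sc, t);
  if (t.W[n] >= -1e-9) return std::string(n, '.'); // no stabilizing structure
  std::string db;
  mfe_traceback(sc, t, db);
  return db;
}

// [[Rcpp::export(name = ".fold_mfe_batch")]]
CharacterVector fold_mfe_batch(CharacterVector seqs) {
  int m = seqs.size();
  CharacterVector out(m);
  for (int s = 0; s < m; s++) {
    std::string seq = as<std::string>(seqs[s]);
    out[s] = fold_one(seq);
  }
  return out;
}

// ------------------------------------------------- partition function ------

struct PfTables {
  int n;
  std::vector<double> Qb, Qm, Qm1;
  std::vector<double> Qpre; // Qpre[i][j]: unconstrained Q on [i..j], flattened
  inline double &qb(int i, int j) { return Qb[(size_t)i * n + j]; }
  inline double &qm(int i, int j) { return Qm[(size_t)i * n + j]; }
  inline double &qm1(int i, int j) { return Qm1[(size_t)i * n + j]; }
  inline double q(int i, int j) const { // 1 for empty segment
    if (i > j) return 1.0;
    return Qpre[(size_t)i * n + j];
  }
};

static void pf_fill(const SeqCode &sc, PfTables &t) {
  int n = sc.n;
  double beta = 1.0 / RT;
  t.n = n;
  t.Qb.assign((size_t)n * n, 0.0);
  t.Qm.assign((size_t)n * n, 0.0);
  t.Qm1.assign((size_t)n * n, 0.0);
  t.Qpre.assign((size_t)n * n, 0.0);
  double eb = std::exp(-beta * ML_BRANCH);
  double ec = std::exp(-beta * ML_UNPAIRED);
  double ea = std::exp(-beta * ML_CLOSE);
  for (int d = 0; d < n; d++) {
    for (int i = 0; i + d < n; i++) {
      int j = i + d;
      int pt = (d > MIN_HP) ? sc.P(i, j) : 0;
      if (pt) {
        double q = std::exp(-beta * hairpin_energy(pt, j - i - 1));
        int kmax = std::min(j - MIN_HP - 2, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; k++) {
          int lmin = std::max(k + MIN_HP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = lmin; l < j; l++) {
            if (!sc.P(k, l)) continue;
            double qkl = t.qb(k, l);
            if (qkl > 0)
              q += std::exp(-beta * loop_energy(pt, sc.P(k, l), k - i - 1, j - l - 1)) * qkl;
          }
        }
        double qml = 0.0;
        for (int k = i + 2; k <= j - 2; k++) {
          double a = t.qm(i + 1, k - 1), b2 = t.qm1(k, j - 1);
          if (a > 0 && b2 > 0) qml += a * b2;
        }
        q += ea * eb * qml;
        t.qb(i, j) = q;
      }
      // Qm1[i][j]: one branch starting at i, unpaired tail to j
      double q1 = 0.0;
      for (int l = i + MIN_HP + 1; l <= j; l++) {
        double qb = t.qb(i, l);
        if (qb > 0) q1 += qb * eb * std::pow(ec, j - l);
      }
      t.qm1(i, j) = q1;
      // Qm[i][j]: >= 1 branch
      double qm = 0.0;
      for (int k = i; k <= j - MIN_HP - 1; k++) {
        double q1k = t.qm1(k, j);
        if (q1k <= 0) continue;
        qm += std::pow(ec, k - i) * q1k;       // first branch at k
        if (k > i) {
          double qmik = t.qm(i, k - 1);
          if (qmik > 0) qm += qmik * q1k;      // last branch at k
        }
      }
      t.qm(i, j) = qm;
      // unconstrained Q
      double q0 = (j > i) ? t.q(i, j - 1) : 1.0;
      for (int k = i; k <= j - MIN_HP - 1; k++) {
        double qb = t.qb(k, j);
        if (qb > 0) q0 += t.q(i, k - 1) * qb;
      }
      t.Qpre[(size_t)i * n + j] = q0;
    }
  }
}

// base-pair probability matrix (outside algorithm)
static void pf_probs(const SeqCode &sc, PfTables &t, std::vector<double> &P) {
  int n = sc.n;
  double beta = 1.0 / RT;
  double eb = std::exp(-beta * ML_BRANCH);
  double ec = std::exp(-beta * ML_UNPAIRED);
  double ea = std::exp(-beta * ML_CLOSE);
  double Qtot = t.q(0, n - 1);
  P.assign((size_t)n * n, 0.0);
  std::vector<double> acc((size_t)n * n, 0.0); // accumulated non-external outside terms
  for (int d = n - 1; d > MIN_HP; d--) {
    for (int k = 0; k + d < n; k++) {
      int l = k + d;
      double qb = t.qb(k, l);
      if (qb <= 0) continue;
      double p = qb * (t.q(0, k - 1) * t.q(l + 1, n - 1) / Qtot + acc[(size_t)k * n + l]);
      if (p <= 0) continue;
      P[(size_t)k * n + l] = p;
      double tmp = p / qb;
      // push interior-loop contributions to enclosed pairs
      int pt = sc.P(k, l);
      int imax = std::min(l - MIN_HP - 2, k + MAXLOOP + 1);
      for (int i = k + 1; i <= imax; i++) {
        int jmin = std::max(i + MIN_HP + 1, l - 1 - (MAXLOOP - (i - k - 1)));
        for (int j = jmin; j < l; j++) {
          if (!sc.P(i, j) || t.qb(i, j) <= 0) continue;
          acc[(size_t)i * n + j] +=
            tmp * std::exp(-beta * loop_energy(pt, sc.P(i, j), i - k - 1, l - j - 1));
        }
      }
      // push multiloop-branch contributions
      double w = tmp * ea * eb * eb;
      for (int i = k + 1; i < l - MIN_HP - 1; i++) {
        for (int j = i + MIN_HP + 1; j < l; j++) {
          if (!sc.P(i, j) || t.qb(i, j) <= 0) continue;
          double left_m = (i - 1 >= k + 1) ? t.qm(k + 1, i - 1) : 0.0;
          double right_m = (j + 1 <= l - 1) ? t.qm(j + 1, l - 1) : 0.0;
          double u_l = std::pow(ec, i - 1 - k);
          double u_r = std::pow(ec, l - 1 - j);
          double term = left_m * u_r + u_l * right_m + left_m * right_m;
          if (term > 0) acc[(size_t)i * n + j] += w * term;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".pair_prob_cpp")]]
NumericMatrix pair_prob_cpp(std::string seq, int max_span = 0) {
  int n = (int)seq.size();
  NumericMatrix out(n, n);
  if (n <= MIN_HP + 1) return out;
  SeqCode sc(seq, max_span);
  PfTables t;
  pf_fill(sc, t);
  std::vector<double> P;
  pf_probs(sc, t, P);
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double p = P[(size_t)i * n + j];
      if (p > 1.0) p = 1.0;
      if (p < 0.0) p = 0.0;
      out(i, j) = p; out(j, i) = p;
    }
  return out;
}

// distance-4 pairing profile p(i, i+4) for a batch of short sequences
// [[Rcpp::export(name = ".dist4_batch_cpp")]]
List dist4_batch_cpp(CharacterVector seqs) {
  int m = seqs.size();
  List out(m);
  for (int s = 0; s < m; s++) {
    std::string seq = as<std::string>(seqs[s]);
    int n = (int)seq.size();
    if (n < 5) { out[s] = NumericVector(0); continue; }
    NumericVector v(n - 4);
    SeqCode sc(seq, 0);
    PfTables t;
    pf_fill(sc, t);
    std::vector<double> P;
    pf_probs(sc, t, P);
    for (int i = 0; i + 4 < n; i++) {
      double p = P[(size_t)i * n + (i + 4)];
      v[i] = (p > 1.0) ? 1.0 : (p < 0.0 ? 0.0 : p);
    }
    out[s] = v;
  }
  return out;
}

// sliding-window averaged distance-4 profile over a long sequence
// [[Rcpp::export(name = ".windowed_dist4_cpp")]]
NumericVector windowed_dist4_cpp(std::string seq, int window, int span, int step) {
  int n = (int)seq.size();
  if (n < 5) return NumericVector(0);
  NumericVector sum(n - 4), cnt(n - 4);
  if (n <= window) {
    SeqCode sc(seq, span);
    PfTables t;
    pf_fill(sc, t);
    std::vector<double> P;
    pf_probs(sc, t, P);
    NumericVector v(n - 4);
    for (int i = 0; i + 4 < n; i++) {
      double p = P[(size_t)i * n + (i + 4)];
      v[i] = (p > 1.0) ? 1.0 : (p < 0.0 ? 0.0 : p);
    }
    return v;
  }
  int last_start = n - window;
  std::vector<int> starts;
  for (int s0 = 0; s0 <= last_start; s0 += step) starts.push_back(s0);
  if (starts.back() != last_start) starts.push_back(last_start);
  for (int start : starts) {
    std::string sub = seq.substr(start, window);
    SeqCode sc(sub, span);
    PfTables t;
    pf_fill(sc, t);
    std::vector<double> P;
    pf_probs(sc, t, P);
    int w = window;
    for (int i = 0; i + 4 < w; i++) {
      double p = P[(size_t)i * w + (i + 4)];
      if (p > 1.0) p = 1.0;
      if (p < 0.0) p = 0.0;
      sum[start + i] += p;
      cnt[start + i] += 1.0;
    }
  }
  NumericVector out(n - 4);
  for (int i = 0; i < n - 4; i++) out[i] = (cnt[i] > 0) ? sum[i] / cnt[i] : 0.0;
  return out;
}
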