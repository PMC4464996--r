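#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified base-pair energy model: each allowed pair contributes a fixed
// (negative) stacking-free energy; hairpin loops must enclose >= minloop
// unpaired bases. MFE by interval dynamic programming; ensemble base-pair
// probabilities by an inside-outside partition-function recursion over the
// same model. Sequences are expected over {A,C,G,U}.

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;
  }
}

struct EnergyModel {
  double e[4][4];  // pair energy, 0 = not pairable
  int minloop;
  EnergyModel(double eGC, double eAU, double eGU, int h) : minloop(h) {
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) e[a][b] = 0.0;
    e[2][1] = e[1][2] = eGC;  // G:C
    e[0][3] = e[3][0] = eAU;  // A:U
    e[2][3] = e[3][2] = eGU;  // G:U wobble
  }
  inline bool pairable(int a, int b) const { return e[a][b] < 0.0; }
};

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base_index(seq[i]);
    if (b < 0) stop("invalid character '%s' at position %d (expected A/C/G/U)",
                    std::string(1, seq[i]).c_str(), (int)(i + 1));
    s[i] = b;
  }
  return s;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, double eGC, double eAU, double eGU,
                  int minloop) {
  const std::vector<int> s = encode(seq);
  const int n = (int)s.size();
  const EnergyModel em(eGC, eAU, eGU, minloop);
  const double eps = 1e-9;

  // E[i][j]: minimum energy on [i, j]; P[i][j]: fewest pairs attaining it.
  std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<int> > P(n, std::vector<int>(n, 0));

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double bestE = E[i + 1][j];
      int bestP = P[i + 1][j];
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (!em.pairable(s[i], s[k])) continue;
        double inE = (k - i - 1 >= 2) ? E[i + 1][k - 1] : 0.0;
        int inP = (k - i - 1 >= 2) ? P[i + 1][k - 1] : 0;
        double outE = (k + 1 <= j - 1 + 1 && k + 1 <= j) ? E[k + 1][j] : 0.0;
        int outP = (k + 1 <= j) ? P[k + 1][j] : 0;
        double cand = em.e[s[i]][s[k]] + inE + outE;
        int candP = 1 + inP + outP;
        if (cand < bestE - eps ||
            (std::fabs(cand - bestE) <= eps && candP < bestP)) {
          bestE = cand;
          bestP = candP;
        }
      }
      E[i][j] = bestE;
      P[i][j] = bestP;
    }
  }

  // Traceback. Among (energy, pair-count) optima prefer pairing position i
  // (dot-bracket '(' sorts before '.') with the smallest partner k.
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack_;
  if (n > 1) stack_.push_back(std::make_pair(0, n - 1));
  while (!stack_.empty()) {
    int i = stack_.back().first, j = stack_.back().second;
    stack_.pop_back();
    if (i >= j) continue;
    double bestE = E[i][j];
    int bestP = P[i][j];
    bool done = false;
    for (int k = i + minloop + 1; k <= j && !done; ++k) {
      if (!em.pairable(s[i], s[k])) continue;
      double inE = (i + 1 <= k - 1) ? E[i + 1][k - 1] : 0.0;
      int inP = (i + 1 <= k - 1) ? P[i + 1][k - 1] : 0;
      double outE = (k + 1 <= j) ? E[k + 1][j] : 0.0;
      int outP = (k + 1 <= j) ? P[k + 1][j] : 0;
      if (std::fabs(em.e[s[i]][s[k]] + inE + outE - bestE) <= eps &&
          1 + inP + outP == bestP) {
        db[i] = '(';
        db[k] = ')';
        if (i + 1 <= k - 1) stack_.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack_.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
    if (!done) stack_.push_back(std::make_pair(i + 1, j));
  }

  return List::create(_["structure"] = db,
                      _["mfe"] = (n > 1) ? E[0][n - 1] : 0.0,
                      _["n_pairs"] = (n > 1) ? P[0][n - 1] : 0);
}

// [[Rcpp::export(name = ".pair_prob_cpp")]]
DataFrame pair_prob_cpp(std::string seq, double eGC, double eAU, double eGU,
                        int minloop, double RT, double prob_min) {
  const std::vector<int> s = encode(seq);
  const int n = (int)s.size();
  const EnergyModel em(eGC, eAU, eGU, minloop);

  // Per-base scaling keeps the scaled partition function near 1 for the
  // dominant structures; long double gives wide exponent headroom on top.
  double mfe = 0.0;
  {
    List r = fold_mfe_cpp(seq, eGC, eAU, eGU, minloop);
    mfe = as<double>(r["mfe"]);
  }
  const long double lnsb = (n > 0) ? (long double)(mfe / (RT * n)) : 0.0L;
  const long double sb = expl(lnsb);  // per-base scale factor (<= 1)

  // Qs[i][j]: scaled inside partition function on [i, j]; empty interval = 1.
  std::vector<std::vector<long double> > Qs(
      n, std::vector<long double>(n, 0.0L));
  std::vector<std::vector<long double> > qp(
      n, std::vector<long double>(n, 0.0L));
  for (int i = 0; i < n; ++i)
    for (int j = i + minloop + 1; j < n; ++j)
      if (em.pairable(s[i], s[j]))
        qp[i][j] = expl((long double)(-em.e[s[i]][s[j]] / RT));

  for (int i = 0; i < n; ++i) Qs[i][i] = sb;
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      long double q = sb * Qs[i + 1][j];
      for (int k = i + minloop + 1; k <= j; ++k) {
        if (qp[i][k] == 0.0L) continue;
        long double inside = (i + 1 <= k - 1) ? Qs[i + 1][k - 1] : 1.0L;
        long double outside = (k + 1 <= j) ? Qs[k + 1][j] : 1.0L;
        q += qp[i][k] * sb * sb * inside * outside;
      }
      Qs[i][j] = q;
    }
  }
  const long double Qtot = (n > 0) ? Qs[0][n - 1] : 1.0L;

  // Outside quantities Os[i][j] for pairable (i, j), spans descending; the
  // enclosing-pair sum runs over the innermost pair (p, q) around [i, j].
  std::vector<std::vector<long double> > Os(
      n, std::vector<long double>(n, 0.0L));
  std::vector<int> oi, oj;
  std::vector<double> op;
  for (int len = n; len >= minloop + 2; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (qp[i][j] == 0.0L) continue;
      long double leftQ = (i > 0) ? Qs[0][i - 1] : 1.0L;
      long double rightQ = (j < n - 1) ? Qs[j + 1][n - 1] : 1.0L;
      long double o = leftQ * rightQ;
      for (int p = 0; p < i; ++p) {
        for (int q = j + 1; q < n; ++q) {
          if (qp[p][q] == 0.0L || Os[p][q] == 0.0L) continue;
          long double midL = (p + 1 <= i - 1) ? Qs[p + 1][i - 1] : 1.0L;
          long double midR = (j + 1 <= q - 1) ? Qs[j + 1][q - 1] : 1.0L;
          o += qp[p][q] * sb * sb * Os[p][q] * midL * midR;
        }
      }
      Os[i][j] = o;
      long double inside = (i + 1 <= j - 1) ? Qs[i + 1][j - 1] : 1.0L;
      long double pij = qp[i][j] * sb * sb * inside * o / Qtot;
      if ((double)pij >= prob_min) {
        oi.push_back(i + 1);
        oj.push_back(j + 1);
        op.push_back((double)pij);
      }
    }
  }

  return DataFrame::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                           _["p"] = wrap(op));
}
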