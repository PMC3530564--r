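#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Single-hairpin (multibranch-free) minimum free energy folding.
//
// Structures are chains of nested base pairs (i1,j1) > (i2,j2) > ... closed
// by a terminal hairpin loop; consecutive pairs are joined by a stack, a
// bulge or an internal loop.  Energy parameters are supplied from R
// (fold_params()) so the R-side reference evaluator shares one model.

static const double INF = std::numeric_limits<double>::infinity();

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    case 'T': return 3;
    default: return -1;
  }
}

// pair type index into the 6x6 stacking table; -1 = not pairable
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

struct EnergyModel {
  NumericMatrix stack;  // [outer pair type, inner pair type]
  double hairpin_a, bulge_a, internal_a, loop_b, asym, asym_max;
  int min_loop, max_interior;

  double hairpinE(int n) const {
    if (n < min_loop) return INF;
    return hairpin_a + loop_b * std::log((double)n / 3.0);
  }
  // energy of joining outer pair (type po) to inner pair (type pi) across
  // g1 unpaired bases on the 5' side and g2 on the 3' side
  double loopE(int po, int pi, int g1, int g2) const {
    if (g1 == 0 && g2 == 0) return stack(po, pi);
    if (g1 + g2 > max_interior) return INF;
    if (g1 == 0 || g2 == 0)
      return bulge_a + loop_b * std::log((double)(g1 + g2));
    double asy = asym * std::abs(g1 - g2);
    if (asy > asym_max) asy = asym_max;
    return internal_a + loop_b * std::log((double)(g1 + g2) / 2.0) + asy;
  }
};

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, List params) {
  const int n = (int)seq.size();
  EnergyModel em;
  em.stack = as<NumericMatrix>(params["stack"]);
  em.hairpin_a = as<double>(params["hairpin_a"]);
  em.bulge_a = as<double>(params["bulge_a"]);
  em.internal_a = as<double>(params["internal_a"]);
  em.loop_b = as<double>(params["loop_b"]);
  em.asym = as<double>(params["asym"]);
  em.asym_max = as<double>(params["asym_max"]);
  em.min_loop = as<int>(params["min_loop"]);
  em.max_interior = as<int>(params["max_interior"]);

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_code(seq[i]);
    if (s[i] < 0) stop("sequence contains a non-ACGU character");
  }

  std::vector<std::vector<int> > pt(n, std::vector<int>(n, -1));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) pt[i][j] = pair_type(s[i], s[j]);

  // V[i][j]: MFE of a chain whose outermost pair is (i,j)
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  const double EPS = 1e-9;

  for (int span = em.min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (pt[i][j] < 0) continue;
      double best = em.hairpinE(j - i - 1);
      // inner pair (k,l); total unpaired g1+g2 bounded by max_interior
      int kmax = std::min(j - 1, i + 1 + em.max_interior);
      for (int k = i + 1; k <= kmax; ++k) {
        int g1 = k - i - 1;
        int lmin = std::max(k + em.min_loop + 1, j - 1 - (em.max_interior - g1));
        for (int l = j - 1; l >= lmin; --l) {
          if (pt[k][l] < 0 || V[k][l] == INF) continue;
          double e = V[k][l] + em.loopE(pt[i][j], pt[k][l], g1, j - l - 1);
          if (e < best - EPS) best = e;
        }
      }
      V[i][j] = best;
    }
  }

  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (V[i][j] < mfe - EPS) { mfe = V[i][j]; bi = i; bj = j; }

  std::string db(n, '.');
  std::vector<int> pi_out, pj_out;
  if (bi >= 0) {
    // traceback; at ties prefer closing the hairpin (fewer pairs), then the
    // first inner pair in fixed (k ascending, l descending) scan order
    int i = bi, j = bj;
    while (true) {
      db[i] = '(';
      db[j] = ')';
      pi_out.push_back(i + 1);
      pj_out.push_back(j + 1);
      double target = V[i][j];
      if (em.hairpinE(j - i - 1) <= target + EPS) break;
      bool found = false;
      int kmax = std::min(j - 1, i + 1 + em.max_interior);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int g1 = k - i - 1;
        int lmin = std::max(k + em.min_loop + 1, j - 1 - (em.max_interior - g1));
        for (int l = j - 1; l >= lmin; --l) {
          if (pt[k][l] < 0 || V[k][l] == INF) continue;
          double e = V[k][l] + em.loopE(pt[i][j], pt[k][l], g1, j - l - 1);
          if (e <= target + EPS) { i = k; j = l; found = true; break; }
        }
      }
      if (!found) break;  // defensive; cannot happen
    }
  }

  IntegerMatrix pairs(pi_out.size(), 2);
  for (int k = 0; k < (int)pi_out.size(); ++k) {
    pairs(k, 0) = pi_out[k];
    pairs(k, 1) = pj_out[k];
  }
  return List::create(_["dot_bracket"] = db, _["mfe"] = mfe,
                      _["pairs"] = pairs);
}
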