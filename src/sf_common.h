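#pragma once

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

namespace sf {

const double NEG_INF = -std::numeric_limits<double>::infinity();
const double POS_INF = std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without leaving the log domain
inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

// residue codes: 0=N 1=A 2=C 3=G 4=U
// pair-type codes: 0=none 1=AU 2=UA 3=CG 4=GC 5=GU 6=UG
inline int pair_code(int a, int b) {
  switch (a * 8 + b) {
    case 1 * 8 + 4: return 1;  // AU
    case 4 * 8 + 1: return 2;  // UA
    case 2 * 8 + 3: return 3;  // CG
    case 3 * 8 + 2: return 4;  // GC
    case 3 * 8 + 4: return 5;  // GU
    case 4 * 8 + 3: return 6;  // UG
    default: return 0;
  }
}

// Nearest-neighbour loop model. All tables hold free energies in kcal/mol;
// weights are exp(-dG / kT) handled in the log domain throughout.
struct Model {
  double kT;                    // R * T, kcal/mol
  double stack[7][7];           // dG, [outer pair type][inner pair type]
  std::vector<double> hairpin;  // dG indexed by loop length (entries < min_hp are +Inf)
  std::vector<double> bulge;    // dG indexed by bulge length (index 0 unused)
  std::vector<double> internal_;// dG indexed by total loop size l1+l2
  double ml_a, ml_b, ml_c;      // multiloop affine: closing, per-branch, per-unpaired
  double term_au;               // simplified terminal non-CG penalty
  bool use_term_au;
  int min_hp;                   // minimum unpaired bases in a hairpin
  int max_iloop;                // cap on l1+l2 for internal/bulge loops
  double lw_oo;                 // log t(Outer -> Outer), fixed at 0

  int min_span() const { return min_hp + 2; }
  double lw_term(int pt) const {
    return (use_term_au && pt != 3 && pt != 4) ? -term_au / kT : 0.0;
  }
  double lw_ext_branch(int pt) const { return lw_term(pt); }
  double lw_ml_branch(int pt) const { return -ml_b / kT + lw_term(pt); }
  double lw_ml_close() const { return -(ml_a + ml_b) / kT; }
  double lw_ml_up() const { return -ml_c / kT; }
  double lw_stack(int po, int pi) const { return -stack[po][pi] / kT; }

  double loop_extrap(double base_dg, int len, int base_len) const {
    // Jacobson-Stockmayer style logarithmic extension beyond the table
    return base_dg + 1.75 * kT * std::log((double)len / (double)base_len);
  }
  double hairpin_dg(int len) const {
    if (len < min_hp) return POS_INF;
    int m = (int)hairpin.size() - 1;
    if (len <= m) return hairpin[len];
    return loop_extrap(hairpin[m], len, m);
  }
  double lw_hairpin(int len) const {
    double dg = hairpin_dg(len);
    return std::isfinite(dg) ? -dg / kT : NEG_INF;
  }
  double iloop_dg(int l1, int l2) const {
    int tot = l1 + l2;
    if (tot < 1 || tot > max_iloop) return POS_INF;
    const std::vector<double>& tab = (l1 == 0 || l2 == 0) ? bulge : internal_;
    int m = (int)tab.size() - 1;
    if (tot <= m) return tab[tot];
    return loop_extrap(tab[m], tot, m);
  }
  double lw_iloop(int l1, int l2) const {
    double dg = iloop_dg(l1, l2);
    return std::isfinite(dg) ? -dg / kT : NEG_INF;
  }
};

Model model_from_list(Rcpp::List m);
std::vector<int> codes_from_r(Rcpp::IntegerVector s);

// Banded triangular array: cell (i, j) with 0 <= j - i <= W stored at (i, j - i).
struct Band {
  int N, W, width;
  std::vector<double> v;
  Band() : N(0), W(0), width(0) {}
  void init(int N_, int W_) {
    N = N_; W = W_; width = W + 1;
    v.assign((size_t)(N + 1) * width, NEG_INF);
  }
  inline double& at(int i, int d) { return v[(size_t)i * width + d]; }
  inline double cell(int i, int j) const {
    int d = j - i;
    if (i < 0 || j > N || d < 0 || d >= width) return NEG_INF;
    return v[(size_t)i * width + d];
  }
  inline void acc(int i, int j, double val) {
    double& r = v[(size_t)i * width + (j - i)];
    r = lse2(r, val);
  }
};

// Inside variables of the six-state grammar (Outer handled separately).
struct Inside {
  Band ST, SE, M, M1, M2;
};

void inside_fill(const std::vector<int>& x, int W, const Model& md, Inside& in);

void ratio_alpha(const std::vector<int>& x, int W, const Model& md,
                 const Band& ST, std::vector<double>& logda);
void ratio_beta(const std::vector<int>& x, int W, const Model& md,
                const Band& ST, std::vector<double>& logdb);
void r_diagonal(const std::vector<int>& x, int W, const Model& md,
                const Band& ST, const std::vector<double>& logda,
                const std::vector<double>& logdb, std::vector<double>& logr);

}  // namespace sf
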