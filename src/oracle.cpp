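// Ground-truth machinery: exhaustive enumeration of every span-constrained
// secondary structure of a short sequence, with per-structure energies
// obtained by geometric loop decomposition -- a summation path that shares
// nothing with the grammar DP except the loop free-energy tables.

#include "sf_common.h"

using namespace Rcpp;
using namespace sf;

namespace {

struct Enumerator {
  const std::vector<int>& x;
  int N, W, min_hp;
  long max_structs;
  std::vector<std::pair<int, int>> cur;
  std::vector<std::vector<std::pair<int, int>>> structs;
  std::vector<std::array<int, 2>> segs;

  Enumerator(const std::vector<int>& x_, int W_, int min_hp_, long cap)
      : x(x_), N((int)x_.size() - 1), W(W_), min_hp(min_hp_), max_structs(cap) {}

  void emit() {
    if ((long)structs.size() >= max_structs)
      stop("structure count exceeds enumeration cap");
    structs.push_back(cur);
  }

  void rec() {
    if (segs.empty()) { emit(); return; }
    std::array<int, 2> sg = segs.back();
    segs.pop_back();
    int i = sg[0], j = sg[1];
    if (i > j) {
      rec();
    } else {
      segs.push_back({i + 1, j});  // residue i unpaired
      rec();
      segs.pop_back();
      // residue i paired with l; span l-i+1 <= W, hairpin >= min_hp
      int lmax = std::min(j, i + W - 1);
      for (int l = i + min_hp + 1; l <= lmax; ++l) {
        if (!pair_code(x[i], x[l])) continue;
        cur.push_back({i, l});
        segs.push_back({l + 1, j});
        segs.push_back({i + 1, l - 1});
        rec();
        segs.pop_back(); segs.pop_back();
        cur.pop_back();
      }
    }
    segs.push_back(sg);
  }

  void run() {
    segs.push_back({1, N});
    rec();
  }
};

// Per-structure free energy by loop decomposition. Returns the log Boltzmann
// weight, or NEG_INF when the structure contains a loop outside the model's
// class (internal/bulge loop larger than the cap).
// Also fills per-position loop classes when cls != nullptr:
// 0 stem, 1 bulge, 2 exterior, 3 hairpin, 4 interior, 5 multi.
double structure_lw(const std::vector<int>& x,
                    const std::vector<std::pair<int, int>>& pairs,
                    const Model& md, std::vector<int>* cls) {
  int N = (int)x.size() - 1;
  std::vector<int> mate(N + 1, 0);
  for (auto& pr : pairs) { mate[pr.first] = pr.second; mate[pr.second] = pr.first; }
  if (cls) {
    cls->assign(N + 1, 2);  // default exterior
    for (auto& pr : pairs) { (*cls)[pr.first] = 0; (*cls)[pr.second] = 0; }
  }
  double dg = 0.0;

  // exterior branches: pairs not enclosed by any other pair
  for (auto& pr : pairs) {
    bool outermost = true;
    for (auto& q : pairs)
      if (q.first < pr.first && pr.second < q.second) { outermost = false; break; }
    if (outermost && md.use_term_au) {
      int pt = pair_code(x[pr.first], x[pr.second]);
      if (pt != 3 && pt != 4) dg += md.term_au;
    }
  }

  for (auto& pr : pairs) {
    int k = pr.first, l = pr.second;
    // direct children and unpaired count inside (k,l)
    std::vector<std::pair<int, int>> ch;
    int unp = 0;
    for (int m = k + 1; m < l;) {
      if (mate[m] > m) { ch.push_back({m, mate[m]}); m = mate[m] + 1; }
      else { ++unp; ++m; }
    }
    int pt = pair_code(x[k], x[l]);
    if (ch.empty()) {
      double h = md.hairpin_dg(l - k - 1);
      if (!std::isfinite(h)) return NEG_INF;
      dg += h;
      if (cls) for (int m = k + 1; m < l; ++m) (*cls)[m] = 3;
    } else if (ch.size() == 1) {
      int l1 = ch[0].first - k - 1, l2 = l - ch[0].second - 1;
      if (l1 == 0 && l2 == 0) {
        dg += md.stack[pt][pair_code(x[ch[0].first], x[ch[0].second])];
      } else {
        double g = md.iloop_dg(l1, l2);
        if (!std::isfinite(g)) return NEG_INF;
        dg += g;
        if (cls) {
          int code = (l1 == 0 || l2 == 0) ? 1 : 4;
          for (int m = k + 1; m < ch[0].first; ++m) (*cls)[m] = code;
          for (int m = ch[0].second + 1; m < l; ++m) (*cls)[m] = code;
        }
      }
    } else {
      dg += md.ml_a + md.ml_b * ((int)ch.size() + 1) + md.ml_c * unp;
      if (md.use_term_au) {
        for (auto& c : ch) {
          int cpt = pair_code(x[c.first], x[c.second]);
          if (cpt != 3 && cpt != 4) dg += md.term_au;
        }
      }
      if (cls) {
        for (int m = k + 1; m < l;) {
          if (mate[m] > m) m = mate[m] + 1;
          else { (*cls)[m] = 5; ++m; }
        }
      }
    }
  }
  return -dg / md.kT;
}

}  // namespace

// [[Rcpp::export]]
List cpp_enumerate(IntegerVector seq_codes, int W, List model,
                   int max_structs = 2000000, bool return_structures = false) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  int N = (int)x.size() - 1;
  Enumerator en(x, W, md.min_hp, max_structs);
  en.run();

  std::vector<double> lws;
  std::vector<int> keep;
  std::vector<std::vector<int>> classes;
  double mx = NEG_INF;
  for (size_t t = 0; t < en.structs.size(); ++t) {
    std::vector<int> cls;
    double lw = structure_lw(x, en.structs[t], md, &cls);
    if (lw == NEG_INF) continue;  // outside the model's structure class
    keep.push_back((int)t);
    lws.push_back(lw);
    classes.push_back(cls);
    if (lw > mx) mx = lw;
  }
  if (keep.empty()) stop("no admissible structure (cannot happen: open chain)");

  long double Zs = 0.0L;
  for (double lw : lws) Zs += std::exp((long double)(lw - mx));
  double logZ = mx + (double)std::log(Zs);

  NumericMatrix bpp(N, N);
  NumericMatrix prof(N, 6);  // stem bulge exterior hairpin interior multi
  for (size_t u = 0; u < keep.size(); ++u) {
    double w = std::exp(lws[u] - logZ);
    for (auto& pr : en.structs[keep[u]]) bpp(pr.first - 1, pr.second - 1) += w;
    const std::vector<int>& cls = classes[u];
    for (int i = 1; i <= N; ++i) {
      int c = cls[i];
      int col = (c == 0) ? 0 : (c == 1) ? 1 : (c == 2) ? 2
                : (c == 3) ? 3 : (c == 4) ? 4 : 5;
      prof(i - 1, col) += w;
    }
  }

  List res = List::create(_["n_structures"] = (int)keep.size(),
                          _["logZ"] = logZ, _["bpp"] = bpp,
                          _["profile"] = prof);
  if (return_structures) {
    List sl(keep.size());
    NumericVector lwv(keep.size());
    for (size_t u = 0; u < keep.size(); ++u) {
      const auto& st = en.structs[keep[u]];
      IntegerMatrix pm(st.size(), 2);
      for (size_t r = 0; r < st.size(); ++r) {
        pm(r, 0) = st[r].first; pm(r, 1) = st[r].second;
      }
      sl[u] = pm;
      lwv[u] = lws[u];
    }
    res["structures"] = sl;
    res["log_weights"] = lwv;
  }
  return res;
}

// [[Rcpp::export]]
double cpp_structure_log_weight(IntegerVector seq_codes, IntegerMatrix pairs,
                                List model) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  std::vector<std::pair<int, int>> pr;
  for (int r = 0; r < pairs.nrow(); ++r)
    pr.push_back({pairs(r, 0), pairs(r, 1)});
  return structure_lw(x, pr, md, nullptr);
}

// [[Rcpp::export]]
std::string cpp_digest(std::string s) {
  // FNV-1a 64-bit
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
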