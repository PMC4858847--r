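// Inside-outside dynamic programming over the six-state grammar
// (Outer, Stem, StemEnd, Multi, Multi1, Multi2) with a maximal base-pair
// span W, plus the ratio-form recursions that keep every stored quantity
// bounded in magnitude independent of sequence length.

#include "sf_common.h"

using namespace Rcpp;

namespace sf {

Model model_from_list(List m) {
  Model md;
  md.kT = as<double>(m["kT"]);
  NumericMatrix st = m["stack"];
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) md.stack[i][j] = POS_INF;
  for (int i = 1; i <= 6; ++i)
    for (int j = 1; j <= 6; ++j) md.stack[i][j] = st(i - 1, j - 1);
  md.hairpin = as<std::vector<double>>(m["hairpin"]);
  md.bulge = as<std::vector<double>>(m["bulge"]);
  md.internal_ = as<std::vector<double>>(m["internal"]);
  NumericVector ml = m["multi"];
  md.ml_a = ml[0]; md.ml_b = ml[1]; md.ml_c = ml[2];
  md.term_au = as<double>(m["term_au"]);
  md.use_term_au = as<bool>(m["use_term_au"]);
  md.min_hp = as<int>(m["min_hp"]);
  md.max_iloop = as<int>(m["max_iloop"]);
  md.lw_oo = 0.0;
  return md;
}

std::vector<int> codes_from_r(IntegerVector s) {
  // returns 1-based residue codes: x[0] unused
  std::vector<int> x(s.size() + 1, 0);
  for (int i = 0; i < s.size(); ++i) x[i + 1] = s[i];
  return x;
}

void inside_fill(const std::vector<int>& x, int W, const Model& md, Inside& in) {
  int N = (int)x.size() - 1;
  int Wb = std::min(W, N);
  in.ST.init(N, Wb); in.SE.init(N, Wb);
  in.M.init(N, Wb); in.M1.init(N, Wb); in.M2.init(N, Wb);
  const int ms = md.min_span();
  const double lw_c = md.lw_ml_up();
  const double lw_close = md.lw_ml_close();

  for (int d = 0; d <= Wb; ++d) {
    for (int i = 0; i + d <= N; ++i) {
      int j = i + d;

      // Stem(i,j): residues (i+1, j) paired; stack continuation or StemEnd
      if (d >= ms && d <= W) {
        int pt = pair_code(x[i + 1], x[j]);
        if (pt) {
          double v = NEG_INF;
          if (d - 2 >= ms) {
            int pti = pair_code(x[i + 2], x[j - 1]);
            if (pti) v = lse2(v, md.lw_stack(pt, pti) + in.ST.cell(i + 1, j - 1));
          }
          v = lse2(v, in.SE.cell(i + 1, j - 1));
          in.ST.at(i, d) = v;
        }
      }

      // Multi2(i,j): exactly one branch starting at i+1, trailing unpaired
      if (d >= 1) {
        double v = NEG_INF;
        double stv = in.ST.cell(i, j);
        if (stv != NEG_INF) v = md.lw_ml_branch(pair_code(x[i + 1], x[j])) + stv;
        double pre = in.M2.cell(i, j - 1);
        if (pre != NEG_INF) v = lse2(v, pre + lw_c);
        in.M2.at(i, d) = v;
      }

      // Multi1(i,j): >=1 branch, unpaired anywhere; decomposed by last branch
      if (d >= 1) {
        double v = NEG_INF;
        double pre = in.M1.cell(i, j - 1);
        if (pre != NEG_INF) v = lse2(v, pre + lw_c);
        for (int k = i; k <= j - ms; ++k) {
          double stv = in.ST.cell(k, j);
          if (stv == NEG_INF) continue;
          double prefix = lse2(lw_c * (k - i), in.M1.cell(i, k));
          v = lse2(v, prefix + md.lw_ml_branch(pair_code(x[k + 1], x[j])) + stv);
        }
        in.M1.at(i, d) = v;
      }

      // Multi(i,j): full multiloop interior (>=2 branches), split before the
      // last branch: Multi1 prefix * Multi2 suffix
      if (d >= 2 * ms) {
        double v = NEG_INF;
        for (int k = i + ms; k <= j - ms; ++k) {
          double a = in.M1.cell(i, k), b = in.M2.cell(k, j);
          if (a != NEG_INF && b != NEG_INF) v = lse2(v, a + b);
        }
        in.M.at(i, d) = v;
      }

      // StemEnd(i,j): loop closed by pair (i, j+1): hairpin, internal/bulge
      // (at least one unpaired base, so no overlap with the stack case), multi
      {
        double v = md.lw_hairpin(d);
        int maxl1 = std::min(md.max_iloop, d);
        for (int l1 = 0; l1 <= maxl1; ++l1) {
          int p = i + l1;
          int l2max = std::min(md.max_iloop - l1, d);
          for (int l2 = (l1 == 0 ? 1 : 0); l2 <= l2max; ++l2) {
            int q = j - l2;
            if (q - p < ms) break;
            double stv = in.ST.cell(p, q);
            if (stv == NEG_INF) continue;
            v = lse2(v, md.lw_iloop(l1, l2) + stv);
          }
        }
        double mv = in.M.cell(i, j);
        if (mv != NEG_INF) v = lse2(v, mv + lw_close);
        if (v != NEG_INF) in.SE.at(i, d) = v;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Exterior (Outer) recursions
// ---------------------------------------------------------------------------

static void outer_raw(const std::vector<int>& x, int W, const Model& md,
                      const Band& ST, std::vector<double>& la,
                      std::vector<double>& lb) {
  int N = (int)x.size() - 1;
  const int ms = md.min_span();
  la.assign(N + 1, NEG_INF);
  lb.assign(N + 1, NEG_INF);
  la[0] = 0.0;
  for (int j = 1; j <= N; ++j) {
    double v = la[j - 1] + md.lw_oo;
    for (int p = std::max(0, j - W); p <= j - ms; ++p) {
      double stv = ST.cell(p, j);
      if (stv == NEG_INF) continue;
      v = lse2(v, la[p] + md.lw_ext_branch(pair_code(x[p + 1], x[j])) + stv);
    }
    la[j] = v;
  }
  lb[N] = 0.0;
  for (int j = N - 1; j >= 0; --j) {
    double v = lb[j + 1] + md.lw_oo;
    for (int q = j + ms; q <= std::min(N, j + W); ++q) {
      double stv = ST.cell(j, q);
      if (stv == NEG_INF) continue;
      v = lse2(v, md.lw_ext_branch(pair_code(x[j + 1], x[q])) + stv + lb[q]);
    }
    lb[j] = v;
  }
}

// Direct-ratio recursion for Dalpha(h) = alpha_Outer(h+1)/alpha_Outer(h):
// every term is a product of at most W previously computed ratios, so no
// quantity of sequence-length scale is ever formed.
void ratio_alpha(const std::vector<int>& x, int W, const Model& md,
                 const Band& ST, std::vector<double>& logda) {
  int N = (int)x.size() - 1;
  const int ms = md.min_span();
  logda.assign(N, NEG_INF);
  for (int j = 1; j <= N; ++j) {
    double v = md.lw_oo;
    double S = 0.0;  // sum_{m=p}^{j-2} logda[m]
    int lo = std::max(0, j - W);
    for (int p = j - 1; p >= lo; --p) {
      if (p <= j - ms) {
        double stv = ST.cell(p, j);
        if (stv != NEG_INF)
          v = lse2(v, md.lw_ext_branch(pair_code(x[p + 1], x[j])) + stv - S);
      }
      if (p - 1 >= lo) S += logda[p - 1];
    }
    logda[j - 1] = v;
  }
}

void ratio_beta(const std::vector<int>& x, int W, const Model& md,
                const Band& ST, std::vector<double>& logdb) {
  int N = (int)x.size() - 1;
  const int ms = md.min_span();
  logdb.assign(N, NEG_INF);
  for (int j = N - 1; j >= 0; --j) {
    double v = md.lw_oo;
    double S = 0.0;  // sum_{m=j+1}^{l-1} logdb[m]
    int hi = std::min(N, j + W);
    for (int l = j + 1; l <= hi; ++l) {
      if (l >= j + ms) {
        double stv = ST.cell(j, l);
        if (stv != NEG_INF)
          v = lse2(v, md.lw_ext_branch(pair_code(x[j + 1], x[l])) + stv - S);
      }
      if (l < hi) S += logdb[l];
    }
    logdb[j] = v;
  }
}

// log r(i,i) = log Z / (alpha_Outer(i) beta_Outer(i)), reconstructed locally
// from the ratio database and exterior block weights u(p,q) over S(i).
void r_diagonal(const std::vector<int>& x, int W, const Model& md,
                const Band& ST, const std::vector<double>& logda,
                const std::vector<double>& logdb, std::vector<double>& logr) {
  int N = (int)x.size() - 1;
  const int ms = md.min_span();
  logr.assign(N + 1, 0.0);
  std::vector<double> SB(W + 2, 0.0);  // SB[t] = sum_{h=i}^{i+t-1} logdb[h]
  for (int i = 0; i < N; ++i) {
    int tmax = std::min(W, N - i);
    SB[0] = 0.0;
    for (int t = 1; t <= tmax; ++t) SB[t] = SB[t - 1] + logdb[i + t - 1];
    // degenerate unpaired step (i, i+1)
    double v = md.lw_oo - SB[1];
    // outermost pairs (p,q) in P with p <= i < q
    double SA = 0.0;  // sum_{h=p}^{i-1} logda[h]
    for (int p = i; p >= std::max(0, i - W + 1); --p) {
      if (p < i) SA += logda[p];
      int qhi = std::min(N, p + W);
      for (int q = std::max(i + 1, p + ms); q <= qhi; ++q) {
        double stv = ST.cell(p, q);
        if (stv == NEG_INF) continue;
        v = lse2(v, -SA - SB[q - i] +
                     md.lw_ext_branch(pair_code(x[p + 1], x[q])) + stv);
      }
    }
    logr[i] = v;
  }
  logr[N] = 0.0;  // r(N,N) = Z / (alpha_Outer(N) * 1) = 1
}

// ---------------------------------------------------------------------------
// Outside pass
// ---------------------------------------------------------------------------

struct Outside {
  Band ST, SE, M, M1, M2;
  void init(int N, int Wb) {
    ST.init(N, Wb); SE.init(N, Wb); M.init(N, Wb); M1.init(N, Wb); M2.init(N, Wb);
  }
};

struct FeatureAcc {
  std::vector<double> hair, bulge, inter, multi;  // range-update diff arrays
  std::vector<double> pstem;
  std::vector<int> bi, bj;
  std::vector<double> bp;
  void init(int N) {
    hair.assign(N + 2, 0.0); bulge.assign(N + 2, 0.0);
    inter.assign(N + 2, 0.0); multi.assign(N + 2, 0.0);
    pstem.assign(N + 1, 0.0);
  }
  void range(std::vector<double>& a, int from, int to, double p) {
    if (to < from) return;
    a[from] += p; a[to + 1] -= p;
  }
};

// Outside recursion over the band. `seed` holds the Outer-level contribution
// to beta_Stem (for the genome-scale path: t(Outer->Outer.Stem)/r(i,j) at
// every potential outermost pair; for a single-pair local outside: the bare
// transition weight at that pair only). If `acc` is non-null, base-pairing
// probabilities and loop-type occupancies are accumulated on the fly.
static void outside_pass(const std::vector<int>& x, int W, const Model& md,
                         const Inside& in, const Band& seed, Outside& out,
                         FeatureAcc* acc) {
  int N = (int)x.size() - 1;
  int Wb = std::min(W, N);
  out.init(N, Wb);
  const int ms = md.min_span();
  const double lw_c = md.lw_ml_up();
  const double lw_close = md.lw_ml_close();

  for (int d = Wb; d >= 0; --d) {
    for (int i = 0; i + d <= N; ++i) {
      int j = i + d;

      // StemEnd
      double bse = out.SE.cell(i, j);
      if (bse != NEG_INF) {
        double lhp = md.lw_hairpin(d);
        if (lhp != NEG_INF && acc)
          acc->range(acc->hair, i + 1, j, std::exp(bse + lhp));
        int maxl1 = std::min(md.max_iloop, d);
        for (int l1 = 0; l1 <= maxl1; ++l1) {
          int p = i + l1;
          int l2max = std::min(md.max_iloop - l1, d);
          for (int l2 = (l1 == 0 ? 1 : 0); l2 <= l2max; ++l2) {
            int q = j - l2;
            if (q - p < ms) break;
            double stv = in.ST.cell(p, q);
            if (stv == NEG_INF) continue;
            double lwil = md.lw_iloop(l1, l2);
            out.ST.acc(p, q, bse + lwil);
            if (acc) {
              double pr = std::exp(bse + lwil + stv);
              std::vector<double>& tgt =
                  (l1 == 0 || l2 == 0) ? acc->bulge : acc->inter;
              if (l1 > 0) acc->range(tgt, i + 1, p, pr);
              if (l2 > 0) acc->range(tgt, q + 1, j, pr);
            }
          }
        }
        if (in.M.cell(i, j) != NEG_INF) out.M.acc(i, j, bse + lw_close);
      }

      // Multi
      double bm = out.M.cell(i, j);
      if (bm != NEG_INF) {
        for (int k = i + ms; k <= j - ms; ++k) {
          double m1 = in.M1.cell(i, k), m2 = in.M2.cell(k, j);
          if (m1 != NEG_INF && m2 != NEG_INF) {
            out.M1.acc(i, k, bm + m2);
            out.M2.acc(k, j, bm + m1);
          }
        }
      }

      // Multi1
      double bm1 = out.M1.cell(i, j);
      if (bm1 != NEG_INF) {
        double prev = in.M1.cell(i, j - 1);
        if (d >= 1 && prev != NEG_INF) {
          out.M1.acc(i, j - 1, bm1 + lw_c);
          if (acc) acc->range(acc->multi, j, j, std::exp(bm1 + lw_c + prev));
        }
        for (int k = i; k <= j - ms; ++k) {
          double stv = in.ST.cell(k, j);
          if (stv == NEG_INF) continue;
          double lwb = md.lw_ml_branch(pair_code(x[k + 1], x[j]));
          double t_unp = bm1 + lw_c * (k - i) + lwb;
          out.ST.acc(k, j, t_unp);
          if (acc && k > i) acc->range(acc->multi, i + 1, k, std::exp(t_unp + stv));
          double m1k = in.M1.cell(i, k);
          if (m1k != NEG_INF) {
            out.ST.acc(k, j, bm1 + m1k + lwb);
            out.M1.acc(i, k, bm1 + lwb + stv);
          }
        }
      }

      // Multi2
      double bm2 = out.M2.cell(i, j);
      if (bm2 != NEG_INF) {
        double prev = in.M2.cell(i, j - 1);
        if (d >= 1 && prev != NEG_INF) {
          out.M2.acc(i, j - 1, bm2 + lw_c);
          if (acc) acc->range(acc->multi, j, j, std::exp(bm2 + lw_c + prev));
        }
        if (in.ST.cell(i, j) != NEG_INF)
          out.ST.acc(i, j, bm2 + md.lw_ml_branch(pair_code(x[i + 1], x[j])));
      }

      // Stem
      double stv = in.ST.cell(i, j);
      if (stv != NEG_INF) {
        double sd = seed.cell(i, j);
        if (sd != NEG_INF) out.ST.acc(i, j, sd);
        double bst = out.ST.cell(i, j);
        if (bst != NEG_INF) {
          if (acc) {
            double p = std::exp(bst + stv);
            acc->bi.push_back(i + 1); acc->bj.push_back(j); acc->bp.push_back(p);
            acc->pstem[i + 1] += p; acc->pstem[j] += p;
          }
          if (d - 2 >= ms) {
            int pti = pair_code(x[i + 2], x[j - 1]);
            if (pti && in.ST.cell(i + 1, j - 1) != NEG_INF)
              out.ST.acc(i + 1, j - 1,
                         bst + md.lw_stack(pair_code(x[i + 1], x[j]), pti));
          }
          if (in.SE.cell(i + 1, j - 1) != NEG_INF)
            out.SE.acc(i + 1, j - 1, bst);
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

static List band_to_r(const Band& b) {
  NumericMatrix m(b.N + 1, b.width);
  for (int i = 0; i <= b.N; ++i)
    for (int d = 0; d < b.width; ++d) m(i, d) = b.v[(size_t)i * b.width + d];
  return List::create(_["values"] = m, _["N"] = b.N, _["W"] = b.W);
}

}  // namespace sf

using namespace sf;

// [[Rcpp::export]]
List cpp_inside(IntegerVector seq_codes, int W, List model) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  Inside in;
  inside_fill(x, W, md, in);
  return List::create(
      _["Stem"] = band_to_r(in.ST), _["StemEnd"] = band_to_r(in.SE),
      _["Multi"] = band_to_r(in.M), _["Multi1"] = band_to_r(in.M1),
      _["Multi2"] = band_to_r(in.M2));
}

// [[Rcpp::export]]
List cpp_reference_fold(IntegerVector seq_codes, int W, List model) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  Inside in;
  inside_fill(x, W, md, in);
  std::vector<double> la, lb;
  outer_raw(x, W, md, in.ST, la, lb);
  return List::create(_["log_alpha_outer"] = la, _["log_beta_outer"] = lb,
                      _["logZ"] = la.back());
}

// [[Rcpp::export]]
List cpp_build_ratios(IntegerVector seq_codes, int W, List model) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  Inside in;
  inside_fill(x, W, md, in);
  std::vector<double> logda, logdb;
  ratio_alpha(x, W, md, in.ST, logda);
  ratio_beta(x, W, md, in.ST, logdb);
  return List::create(_["logda"] = logda, _["logdb"] = logdb);
}

// [[Rcpp::export]]
List cpp_fold_features(IntegerVector seq_codes, int W, List model,
                       NumericVector logda_r, NumericVector logdb_r,
                       bool return_outside = false) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  int N = (int)x.size() - 1;
  std::vector<double> logda(logda_r.begin(), logda_r.end());
  std::vector<double> logdb(logdb_r.begin(), logdb_r.end());
  Inside in;
  inside_fill(x, W, md, in);
  std::vector<double> logr;
  r_diagonal(x, W, md, in.ST, logda, logdb, logr);

  // cumulative log Dalpha in extended precision: A(i,j) = CA[j] - CA[i]
  std::vector<long double> CA(N + 1, 0.0L);
  for (int h = 0; h < N; ++h) CA[h + 1] = CA[h] + (long double)logda[h];

  int Wb = std::min(W, N);
  Band seed;
  seed.init(N, Wb);
  const int ms = md.min_span();
  for (int i = 0; i <= N; ++i) {
    for (int d = ms; d <= Wb && i + d <= N; ++d) {
      int j = i + d;
      if (in.ST.cell(i, j) == NEG_INF) continue;
      double logr_ij = (double)(CA[j] - CA[i]) + logr[j];
      seed.at(i, d) = md.lw_ext_branch(pair_code(x[i + 1], x[j])) - logr_ij;
    }
  }

  Outside out;
  FeatureAcc acc;
  acc.init(N);
  outside_pass(x, W, md, in, seed, out, &acc);

  // exterior occupancy: p_ext(i) = t(Outer->Outer) / r(i-1, i)
  NumericVector pext(N);
  for (int i = 1; i <= N; ++i)
    pext[i - 1] = std::exp(md.lw_oo - logda[i - 1] - logr[i]);

  NumericMatrix prof(N, 6);  // stem, bulge, exterior, hairpin, interior, multi
  double ch = 0, cb = 0, ci = 0, cm = 0;
  for (int i = 1; i <= N; ++i) {
    ch += acc.hair[i]; cb += acc.bulge[i]; ci += acc.inter[i]; cm += acc.multi[i];
    prof(i - 1, 0) = acc.pstem[i];
    prof(i - 1, 1) = cb;
    prof(i - 1, 2) = pext[i - 1];
    prof(i - 1, 3) = ch;
    prof(i - 1, 4) = ci;
    prof(i - 1, 5) = cm;
  }

  List res = List::create(
      _["bpp_i"] = acc.bi, _["bpp_j"] = acc.bj, _["bpp_p"] = acc.bp,
      _["pstem"] = NumericVector(acc.pstem.begin() + 1, acc.pstem.end()),
      _["profile"] = prof, _["log_r_diag"] = logr);
  if (return_outside) {
    res["outside"] = List::create(
        _["Stem"] = band_to_r(out.ST), _["StemEnd"] = band_to_r(out.SE),
        _["Multi"] = band_to_r(out.M), _["Multi1"] = band_to_r(out.M1),
        _["Multi2"] = band_to_r(out.M2));
  }
  return res;
}

// Outside variables beta_sigma(k,l; i,j) for a single outermost pair (i,j),
// computed on the enclosed window with the initial condition
// beta_Stem(i,j;i,j) = t(Outer,i,j -> Outer.Stem,i,j).
// [[Rcpp::export]]
List cpp_outside_local(IntegerVector seq_codes, int W, List model,
                       int i0, int j0) {
  Model md = model_from_list(model);
  std::vector<int> x = codes_from_r(seq_codes);
  Inside in;
  inside_fill(x, W, md, in);
  int N = (int)x.size() - 1;
  if (in.ST.cell(i0, j0) == NEG_INF)
    stop("(i,j) is not a potential outermost pair");
  Band seed;
  seed.init(N, std::min(W, N));
  seed.at(i0, j0 - i0) = md.lw_ext_branch(pair_code(x[i0 + 1], x[j0]));
  Outside out;
  outside_pass(x, W, md, in, seed, out, nullptr);
  return List::create(
      _["Stem"] = band_to_r(out.ST), _["StemEnd"] = band_to_r(out.SE),
      _["Multi"] = band_to_r(out.M), _["Multi1"] = band_to_r(out.M1),
      _["Multi2"] = band_to_r(out.M2));
}
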