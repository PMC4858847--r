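// Divide/Connect: per-segment partial inside tables d-alpha^h_k (and the
// mirrored d-beta partials), each computed independently with at most W of
// sequence context on either side, and the merge that recovers the exact
// full-sequence fold changes Delta-alpha / Delta-beta.

#include "sf_common.h"

using namespace Rcpp;
using namespace sf;

// Partial tables for segment (s, e] of a length-N sequence.
//   alpha^h_k: inside weight of x_{s-h+1..k} whose first outermost pair is
//              (s-h, j) with j > s (h >= 1); alpha^0_k = Z(x_{s+1..k}).
//   stored as ratios d-alpha^h_k = alpha^h_k / alpha^0_k together with the
//   segment-local fold change R_k = alpha^0_k / alpha^0_{k-1}.
// [[Rcpp::export]]
List cpp_segment_table(IntegerVector seq_codes, int W, List model,
                       int s, int e) {
  Model md = model_from_list(model);
  std::vector<int> xfull = codes_from_r(seq_codes);
  int N = (int)xfull.size() - 1;
  if (s < 0 || e <= s || e > N) stop("invalid segment range");
  const int ms = md.min_span();

  int lo = std::max(0, s - W), hi = std::min(N, e + W);
  // inside Stem values are local, so compute them on the context slice
  std::vector<int> x(xfull.begin() + lo, xfull.end() - (N - hi));
  // x now holds residues lo+1..hi at indices 1..hi-lo
  Inside in;
  inside_fill(x, W, md, in);
  // global gap coordinate t maps to slice coordinate t - lo
  auto ST = [&](int p, int q) { return in.ST.cell(p - lo, q - lo); };
  auto PT = [&](int a, int b) { return pair_code(xfull[a], xfull[b]); };

  int H = std::min(W, s);        // alpha context depth
  int Hb = std::min(W, N - e);   // beta context depth
  int len = e - s;

  // ---- alpha part: columns k = s..e (col k-s), rows h = 0..H ----
  std::vector<std::vector<double>> Da(H + 1, std::vector<double>(len + 1, NEG_INF));
  std::vector<double> logRa(len + 1, NEG_INF);  // index k-s, k = s+1..e
  Da[0].assign(len + 1, 0.0);                   // d-alpha^0 == 1 by definition
  double csRa = 0.0;                            // sum_{m=s+1}^{k-1} logRa
  std::vector<double> SS(W + 2, 0.0);
  std::vector<int> plist; std::vector<double> pbase;
  for (int k = s + 1; k <= e; ++k) {
    // candidate segment-internal pairs (p,k), p >= s, with
    // base(p) = t_os * Stem(p,k) / prod_{m=p+1}^{k-1} R_m
    plist.clear(); pbase.clear();
    double S = 0.0;
    for (int p = k - 1; p >= std::max(s, k - W); --p) {
      if (p <= k - ms) {
        double stv = ST(p, k);
        if (stv != NEG_INF) {
          plist.push_back(p);
          pbase.push_back(md.lw_ext_branch(PT(p + 1, k)) + stv - S);
        }
      }
      if (p - 1 >= std::max(s, k - W)) S += logRa[p - s];
    }
    double v0 = md.lw_oo;  // h = 0 numerator (previous d-alpha^0 = 1)
    for (double b : pbase) v0 = lse2(v0, b);
    logRa[k - s] = v0;
    for (int h = 1; h <= H; ++h) {
      double v = (Da[h][k - 1 - s] == NEG_INF) ? NEG_INF
                                               : md.lw_oo + Da[h][k - 1 - s];
      for (size_t t = 0; t < plist.size(); ++t) {
        double dp = Da[h][plist[t] - s];
        if (dp != NEG_INF) v = lse2(v, dp + pbase[t]);
      }
      if (k - (s - h) >= ms && k - (s - h) <= W) {
        double stv = ST(s - h, k);
        if (stv != NEG_INF)
          v = lse2(v, md.lw_ext_branch(PT(s - h + 1, k)) + stv - csRa);
      }
      Da[h][k - s] = (v == NEG_INF) ? NEG_INF : v - logRa[k - s];
    }
    csRa += logRa[k - s];
  }

  // ---- beta part: columns k = s..e, rows h = 0..Hb ----
  //   beta^h_k: weight of x_{k+1..e+h} whose crossing outermost pair ends at
  //   e+h (h >= 1); beta^0_k = Z(x_{k+1..e}); R'_k = beta^0_k / beta^0_{k+1}.
  std::vector<std::vector<double>> Db(Hb + 1, std::vector<double>(len + 1, NEG_INF));
  std::vector<double> logRb(len + 1, NEG_INF);  // index k-s, k = s..e-1
  Db[0].assign(len + 1, 0.0);
  double csRb = 0.0;  // sum_{m=k+1}^{e-1} logRb
  std::vector<int> llist; std::vector<double> lbase;
  for (int k = e - 1; k >= s; --k) {
    llist.clear(); lbase.clear();
    double S = 0.0;
    for (int l = k + 1; l <= std::min(e, k + W); ++l) {
      if (l >= k + ms) {
        double stv = ST(k, l);
        if (stv != NEG_INF) {
          llist.push_back(l);
          lbase.push_back(md.lw_ext_branch(PT(k + 1, l)) + stv - S);
        }
      }
      if (l < std::min(e, k + W)) S += logRb[l - s];
    }
    double v0 = md.lw_oo;
    for (double b : lbase) v0 = lse2(v0, b);
    logRb[k - s] = v0;
    for (int h = 1; h <= Hb; ++h) {
      double v = (Db[h][k + 1 - s] == NEG_INF) ? NEG_INF
                                               : md.lw_oo + Db[h][k + 1 - s];
      for (size_t t = 0; t < llist.size(); ++t) {
        double dl = Db[h][llist[t] - s];
        if (dl != NEG_INF) v = lse2(v, dl + lbase[t]);
      }
      if (e + h - k >= ms && e + h - k <= W && e + h <= N) {
        double stv = ST(k, e + h);
        if (stv != NEG_INF)
          v = lse2(v, md.lw_ext_branch(PT(k + 1, e + h)) + stv - csRb);
      }
      Db[h][k - s] = (v == NEG_INF) ? NEG_INF : v - logRb[k - s];
    }
    csRb += logRb[k - s];
  }

  NumericMatrix da(H, len), db(Hb, len);
  for (int h = 1; h <= H; ++h)
    for (int k = 1; k <= len; ++k) da(h - 1, k - 1) = Da[h][k];
  for (int h = 1; h <= Hb; ++h)
    for (int k = 0; k < len; ++k) db(h - 1, k) = Db[h][k];
  NumericVector Ra(len), Rb(len);
  for (int k = 1; k <= len; ++k) Ra[k - 1] = logRa[k];   // k = s+1..e
  for (int k = 0; k < len; ++k) Rb[k] = logRb[k];        // k = s..e-1
  return List::create(_["s"] = s, _["e"] = e, _["H"] = H, _["Hb"] = Hb,
                      _["log_Ra"] = Ra, _["da"] = da,
                      _["log_Rb"] = Rb, _["db"] = db);
}

// Merge alpha partials left to right:
//   alpha_Outer(k) = sum_h alpha_Outer(s-h) * alpha^h_k
// carried as the scale-free C_k = alpha_Outer(k) / (alpha_Outer(s) alpha^0_k),
// giving Delta-alpha(k-1) = (C_k / C_{k-1}) * R_k.
// [[Rcpp::export]]
NumericVector cpp_connect_alpha(List tables, int N) {
  NumericVector logda(N, NA_REAL);
  for (int t = 0; t < tables.size(); ++t) {
    List tb = tables[t];
    int s = as<int>(tb["s"]), e = as<int>(tb["e"]), H = as<int>(tb["H"]);
    NumericVector Ra = tb["log_Ra"];
    NumericMatrix da = tb["da"];
    std::vector<double> pre(H + 1, 0.0);  // sum_{m=s-h}^{s-1} log Dalpha(m)
    for (int h = 1; h <= H; ++h) pre[h] = pre[h - 1] + logda[s - h];
    double logCprev = 0.0;  // C_s = 1
    for (int k = s + 1; k <= e; ++k) {
      double logC = 0.0;    // h = 0 term: d-alpha^0 / 1
      for (int h = 1; h <= H; ++h) {
        double d = da(h - 1, k - s - 1);
        if (d != NEG_INF) logC = lse2(logC, d - pre[h]);
      }
      logda[k - 1] = logC - logCprev + Ra[k - s - 1];
      logCprev = logC;
    }
  }
  return logda;
}

// [[Rcpp::export]]
NumericVector cpp_connect_beta(List tables, int N) {
  NumericVector logdb(N, NA_REAL);
  for (int t = tables.size() - 1; t >= 0; --t) {
    List tb = tables[t];
    int s = as<int>(tb["s"]), e = as<int>(tb["e"]), Hb = as<int>(tb["Hb"]);
    NumericVector Rb = tb["log_Rb"];
    NumericMatrix db = tb["db"];
    std::vector<double> pre(Hb + 1, 0.0);  // sum_{m=e}^{e+h-1} log Dbeta(m)
    for (int h = 1; h <= Hb; ++h) pre[h] = pre[h - 1] + logdb[e + h - 1];
    double logCnext = 0.0;  // C'_e = 1
    for (int k = e - 1; k >= s; --k) {
      double logC = 0.0;
      for (int h = 1; h <= Hb; ++h) {
        double d = db(h - 1, k - s);
        if (d != NEG_INF) logC = lse2(logC, d - pre[h]);
      }
      logdb[k] = logC - logCnext + Rb[k - s];
      logCnext = logC;
    }
  }
  return logdb;
}
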