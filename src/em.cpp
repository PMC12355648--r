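#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Expected transition counts d[g,h,k] and at-risk totals Y[g,k] for the
// EM E-step, summed over subjects.
//
// The data enter as observation intervals: subject observed in state a at
// time l and next in state b at time r, spanning bins klo..khi (0-based,
// inclusive; bin k is (tau[k-1], tau[k]] and tau[khi] == r).  For ordinary
// (interval-censored) intervals the conditional expectations are
//   d_ghk += P(a,g; l,tau[k-1]) * alpha[g,h,k] * P(h,b; tau[k],r) / P(a,b; l,r)
//   Y_gk  += P(a,g; l,tau[k-1]) * P(g,b; tau[k-1],r)              / P(a,b; l,r)
// computed with one forward sweep (row products from l) and one backward
// sweep (column products to r) per interval, so the whole E-step costs
// O(sum_i K_i * H^2) per iteration.
//
// For intervals flagged exact (entry into an exactly observed state b at
// time r = tau[khi]) the backward vector is seeded with
// v[h] = alpha[h,b,khi] at tau[khi-1] and the normaliser is
// D = sum_{m<-b} alpha[m,b,khi] * P(a,m; l,tau[khi-1]).  The terminal bin
// routes all mass through the direct predecessors of b:
//   d[m,b,khi] += P(a,m; l,tau[khi-1]) * alpha[m,b,khi] / D, and the same
// quantity is the probability of being at risk in m just before entry.
//
// alpha is an H*H*K column-major array; states/bins 0-based throughout.
// Returns err = 1-based index of the first interval whose normaliser
// underflows (observed pair impossible under alpha), or 0.
// [[Rcpp::export]]
List estep_cpp(NumericVector alpha, int H, int K,
               IntegerVector a, IntegerVector b,
               IntegerVector klo, IntegerVector khi,
               LogicalVector exact,
               IntegerVector edge_from, IntegerVector edge_to) {
  const int nIv = a.size(), nE = edge_from.size();
  std::vector< std::vector<int> > out(H), in(H);
  for (int e = 0; e < nE; ++e) {
    out[edge_from[e]].push_back(edge_to[e]);
    in[edge_to[e]].push_back(edge_from[e]);
  }
  NumericVector d(H * H * K);
  NumericMatrix Y(H, K);
  const double *al = alpha.begin();
  const int HH = H * H;

  int maxnb = 1;
  for (int i = 0; i < nIv; ++i)
    if (khi[i] - klo[i] + 1 > maxnb) maxnb = khi[i] - klo[i] + 1;
  std::vector<double> B((size_t)(maxnb + 1) * H);
  std::vector<double> f(H), fn(H);

  for (int i = 0; i < nIv; ++i) {
    const int aa = a[i], bb = b[i], kl = klo[i], kh = khi[i];
    const int nb = kh - kl + 1;

    if (!exact[i]) {
      // backward sweep: B[m][.] = P(., b; tau[kl-1+m], r), m = 0..nb
      double *Bn = &B[(size_t)nb * H];
      for (int g = 0; g < H; ++g) Bn[g] = (g == bb) ? 1.0 : 0.0;
      for (int m = nb; m >= 1; --m) {
        const int k = kl + m - 1;
        const double *ak = al + (size_t)HH * k;
        const double *Bm = &B[(size_t)m * H];
        double *Bp = &B[(size_t)(m - 1) * H];
        for (int g = 0; g < H; ++g) {
          double stay = 1.0, acc = 0.0;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            const double av = ak[g + H * h];
            stay -= av;
            acc += av * Bm[h];
          }
          Bp[g] = stay * Bm[g] + acc;
        }
      }
      const double den = B[aa];  // P(a,b; l,r)
      if (den < 1e-300)
        return List::create(_["d"] = d, _["Y"] = Y, _["err"] = i + 1);
      for (int g = 0; g < H; ++g) f[g] = (g == aa) ? 1.0 : 0.0;
      for (int m = 1; m <= nb; ++m) {
        const int k = kl + m - 1;
        const double *ak = al + (size_t)HH * k;
        const double *Bm = &B[(size_t)m * H];
        const double *Bp = &B[(size_t)(m - 1) * H];
        double *dk = d.begin() + (size_t)HH * k;
        for (int g = 0; g < H; ++g) {
          const double fg = f[g];
          if (fg <= 0.0) { fn[g] = 0.0; continue; }
          double stay = 1.0;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            const double av = ak[g + H * h];
            stay -= av;
            if (av > 0.0) dk[g + H * h] += fg * av * Bm[h] / den;
          }
          Y(g, k) += fg * Bp[g] / den;
          fn[g] = fg * stay;
        }
        // complete the forward update f <- f (I + dA_k)
        for (int g = 0; g < H; ++g) {
          const double fg = f[g];
          if (fg <= 0.0) continue;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            fn[h] += fg * ak[g + H * h];
          }
        }
        std::swap(f, fn);
      }
    } else {
      // exact entry into bb at r = tau[kh]
      double *Bn = &B[(size_t)(nb - 1) * H];
      const double *akh = al + (size_t)HH * kh;
      for (int g = 0; g < H; ++g) Bn[g] = 0.0;
      for (size_t u = 0; u < in[bb].size(); ++u) {
        const int m = in[bb][u];
        Bn[m] = akh[m + H * bb];
      }
      for (int m = nb - 1; m >= 1; --m) {
        const int k = kl + m - 1;
        const double *ak = al + (size_t)HH * k;
        const double *Bm = &B[(size_t)m * H];
        double *Bp = &B[(size_t)(m - 1) * H];
        for (int g = 0; g < H; ++g) {
          double stay = 1.0, acc = 0.0;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            const double av = ak[g + H * h];
            stay -= av;
            acc += av * Bm[h];
          }
          Bp[g] = stay * Bm[g] + acc;
        }
      }
      const double D = B[aa];
      if (D < 1e-300)
        return List::create(_["d"] = d, _["Y"] = Y, _["err"] = i + 1);
      for (int g = 0; g < H; ++g) f[g] = (g == aa) ? 1.0 : 0.0;
      for (int m = 1; m <= nb - 1; ++m) {
        const int k = kl + m - 1;
        const double *ak = al + (size_t)HH * k;
        const double *Bm = &B[(size_t)m * H];
        const double *Bp = &B[(size_t)(m - 1) * H];
        double *dk = d.begin() + (size_t)HH * k;
        for (int g = 0; g < H; ++g) {
          const double fg = f[g];
          if (fg <= 0.0) { fn[g] = 0.0; continue; }
          double stay = 1.0;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            const double av = ak[g + H * h];
            stay -= av;
            if (av > 0.0) dk[g + H * h] += fg * av * Bm[h] / D;
          }
          Y(g, k) += fg * Bp[g] / D;
          fn[g] = fg * stay;
        }
        for (int g = 0; g < H; ++g) {
          const double fg = f[g];
          if (fg <= 0.0) continue;
          for (size_t u = 0; u < out[g].size(); ++u) {
            const int h = out[g][u];
            fn[h] += fg * ak[g + H * h];
          }
        }
        std::swap(f, fn);
      }
      // terminal bin: f = P(a,.; l, tau[kh-1])
      double *dk = d.begin() + (size_t)HH * kh;
      for (size_t u = 0; u < in[bb].size(); ++u) {
        const int m = in[bb][u];
        const double w = f[m] * akh[m + H * bb] / D;
        dk[m + H * bb] += w;
        Y(m, kh) += w;
      }
    }
  }
  return List::create(_["d"] = d, _["Y"] = Y, _["err"] = 0);
}

// Observed-data log-likelihood: sum over intervals of
// log P(a,b; l,r), or for exact entries log of
// sum_{m<-b} P(a,m; l,tau[khi-1]) * alpha[m,b,khi].
// Returns the log-likelihood and the 1-based index of the first interval
// with a zero factor (log-likelihood is then -Inf).
// [[Rcpp::export]]
List obsloglik_cpp(NumericVector alpha, int H, int K,
                   IntegerVector a, IntegerVector b,
                   IntegerVector klo, IntegerVector khi,
                   LogicalVector exact,
                   IntegerVector edge_from, IntegerVector edge_to) {
  const int nIv = a.size(), nE = edge_from.size();
  std::vector< std::vector<int> > out(H), in(H);
  for (int e = 0; e < nE; ++e) {
    out[edge_from[e]].push_back(edge_to[e]);
    in[edge_to[e]].push_back(edge_from[e]);
  }
  const double *al = alpha.begin();
  const int HH = H * H;
  std::vector<double> f(H), fn(H);
  double ll = 0.0;
  int zero_at = 0;

  for (int i = 0; i < nIv; ++i) {
    const int aa = a[i], bb = b[i], kl = klo[i], kh = khi[i];
    const int last = exact[i] ? kh - 1 : kh;
    for (int g = 0; g < H; ++g) f[g] = (g == aa) ? 1.0 : 0.0;
    for (int k = kl; k <= last; ++k) {
      const double *ak = al + (size_t)HH * k;
      for (int g = 0; g < H; ++g) {
        double stay = 1.0;
        for (size_t u = 0; u < out[g].size(); ++u)
          stay -= ak[g + H * out[g][u]];
        fn[g] = f[g] * stay;
      }
      for (int g = 0; g < H; ++g) {
        const double fg = f[g];
        if (fg <= 0.0) continue;
        for (size_t u = 0; u < out[g].size(); ++u) {
          const int h = out[g][u];
          fn[h] += fg * ak[g + H * h];
        }
      }
      std::swap(f, fn);
    }
    double factor;
    if (!exact[i]) {
      factor = f[bb];
    } else {
      const double *akh = al + (size_t)HH * kh;
      factor = 0.0;
      for (size_t u = 0; u < in[bb].size(); ++u) {
        const int m = in[bb][u];
        factor += f[m] * akh[m + H * bb];
      }
    }
    if (factor <= 0.0) {
      if (zero_at == 0) zero_at = i + 1;
      ll = R_NegInf;
    } else if (ll != R_NegInf) {
      ll += std::log(factor);
    }
  }
  return List::create(_["loglik"] = ll, _["zero_at"] = zero_at);
}
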