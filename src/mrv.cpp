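#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Self-contained RNG (splitmix64 seeding an xorshift128+ stream) so that
// validation splits depend only on the integer seed passed in, never on
// R's global RNG state.
namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 to expand the seed into two state words
    auto next = [&seed]() {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = next();
    s1 = next();
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t nextu() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform on [0, 1)
  double unif() { return (nextu() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(unif() * n); }
};

// partial Fisher-Yates: after the call, idx[0..k-1] is a uniform random
// k-subset of the original contents
void draw_subset(std::vector<int>& idx, int k, Rng& rng) {
  const int n = (int)idx.size();
  for (int i = 0; i < k; ++i) {
    int j = i + rng.below(n - i);
    std::swap(idx[i], idx[j]);
  }
}

}  // namespace

// Multiple random validation core for the nearest-centroid classifier.
// X: genes x samples (standardization happens per split inside).
// y: 1 = positive class (nonresponder), 0 = negative class (responder).
// Returns per-sample held-out score sums and hold-out counts; the R side
// aggregates to mean scores, ROC, AUC and test statistics.
// Two RNG streams, one per class (seeded from the class *names* on the R
// side), so that swapping which class plays the positive role reproduces
// the same splits and the label-flip duality (z -> -z, AUC -> 1 - AUC)
// holds exactly.
// [[Rcpp::export]]
List cpp_mrv(NumericMatrix X, IntegerVector y, int n_rep, double train_frac,
             int seed_pos, int seed_neg) {
  const int p = X.nrow(), n = X.ncol();
  std::vector<int> pos, neg;
  for (int j = 0; j < n; ++j) (y[j] == 1 ? pos : neg).push_back(j);
  const int n1 = (int)pos.size(), n0 = (int)neg.size();
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 samples");

  int k1 = (int)std::lround(train_frac * n1);
  int k0 = (int)std::lround(train_frac * n0);
  if (k1 < 1) k1 = 1; if (k1 > n1 - 1) k1 = n1 - 1;
  if (k0 < 1) k0 = 1; if (k0 > n0 - 1) k0 = n0 - 1;

  NumericVector zsum(n);
  IntegerVector zcnt(n);
  const double* x = REAL(X);  // column-major: gene index runs fastest
  std::vector<double> sum1(p), sum0(p), sumsq(p), mean(p), isd(p), dc(p), mc(p);
  std::vector<int> train1(pos), train0(neg);
  Rng rng1((uint64_t)(uint32_t)seed_pos * 0x9E3779B97f4A7C15ULL + 12345u);
  Rng rng0((uint64_t)(uint32_t)seed_neg * 0x9E3779B97f4A7C15ULL + 12345u);

  for (int rep = 0; rep < n_rep; ++rep) {
    train1.assign(pos.begin(), pos.end());
    train0.assign(neg.begin(), neg.end());
    draw_subset(train1, k1, rng1);
    draw_subset(train0, k0, rng0);
    const int ntr = k1 + k0;

    // one contiguous pass per training sample: per-class sums and sum of
    // squares for every gene
    std::fill(sum1.begin(), sum1.end(), 0.0);
    std::fill(sum0.begin(), sum0.end(), 0.0);
    std::fill(sumsq.begin(), sumsq.end(), 0.0);
    for (int i = 0; i < k1; ++i) {
      const double* col = x + (size_t)train1[i] * p;
      for (int g = 0; g < p; ++g) {
        sum1[g] += col[g];
        sumsq[g] += col[g] * col[g];
      }
    }
    for (int i = 0; i < k0; ++i) {
      const double* col = x + (size_t)train0[i] * p;
      for (int g = 0; g < p; ++g) {
        sum0[g] += col[g];
        sumsq[g] += col[g] * col[g];
      }
    }

    // training mean/sd per gene; class centroids in standardized space.
    // zero-variance genes are dropped (isd = 0 removes them from distances)
    for (int g = 0; g < p; ++g) {
      const double s = sum1[g] + sum0[g];
      const double m = s / ntr;
      double var = (sumsq[g] - ntr * m * m) / (ntr - 1);
      if (var < 1e-24) { isd[g] = 0.0; dc[g] = mc[g] = 0.0; mean[g] = m; continue; }
      const double sdg = std::sqrt(var);
      mean[g] = m;
      isd[g] = 1.0 / sdg;
      const double cpos = (sum1[g] / k1 - m) / sdg;
      const double cneg = (sum0[g] / k0 - m) / sdg;
      // cache the two combinations used when expanding the distances
      dc[g] = cpos - cneg;                 // difference
      mc[g] = 0.5 * (cpos + cneg);         // midpoint
    }

    // score held-out samples: z = d(x, centroid_neg) - d(x, centroid_pos)
    auto score = [&](int j) {
      const double* col = x + (size_t)j * p;
      double dpos = 0.0, dneg = 0.0;
      for (int g = 0; g < p; ++g) {
        if (isd[g] == 0.0) continue;
        const double v = (col[g] - mean[g]) * isd[g];
        const double a = v - (mc[g] + 0.5 * dc[g]);  // v - cpos
        const double b = v - (mc[g] - 0.5 * dc[g]);  // v - cneg
        dpos += a * a;
        dneg += b * b;
      }
      zsum[j] += std::sqrt(dneg) - std::sqrt(dpos);
      zcnt[j] += 1;
    };
    for (int i = k1; i < n1; ++i) score(train1[i]);
    for (int i = k0; i < n0; ++i) score(train0[i]);
  }

  return List::create(_["zsum"] = zsum, _["zcnt"] = zcnt,
                      _["n_train_pos"] = k1, _["n_train_neg"] = k0);
}

// Gaussian-kernel cumulative density across observations, per gene:
// out(g, j) = mean_k Phi((x_gj - x_gk) / h_g), with bandwidth h_g = sd_g / 4.
// Rows with zero variance are returned as NA (excluded upstream).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_cdf(NumericMatrix X) {
  const int p = X.nrow(), n = X.ncol();
  NumericMatrix out(p, n);
  const double inv_sqrt2 = 0.7071067811865475244;
  for (int g = 0; g < p; ++g) {
    double s = 0.0, ss = 0.0;
    for (int j = 0; j < n; ++j) s += X(g, j);
    const double m = s / n;
    for (int j = 0; j < n; ++j) { double d = X(g, j) - m; ss += d * d; }
    const double sd = (n > 1) ? std::sqrt(ss / (n - 1)) : 0.0;
    if (sd < 1e-12) {
      for (int j = 0; j < n; ++j) out(g, j) = NA_REAL;
      continue;
    }
    const double h = sd / 4.0;
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        acc += 0.5 * std::erfc(-(X(g, j) - X(g, k)) / h * inv_sqrt2);
      }
      out(g, j) = acc / n;
    }
  }
  return out;
}
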