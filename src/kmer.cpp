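#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequences are passed as integer code vectors: A=0, C=1, G=2, T=3,
// any negative value = ambiguity code (never counted, but permuted
// with the rest of the letters).

static int table_size(int k) {
  if (k <= 0) stop("k must be >= 1");
  if (k > 12) stop("k must be <= 12 for dense k-mer counting");
  int nb = 1;
  for (int i = 0; i < k; ++i) nb *= 4;
  return nb;
}

// rolling-code count of overlapping k-mers on the given strand;
// k-mers containing an ambiguous letter are skipped
// [[Rcpp::export]]
IntegerVector kmer_count_codes(const IntegerVector& x, int k) {
  const int nb = table_size(k);
  const int mask = nb - 1;
  const int n = x.size();
  IntegerVector out(nb);
  int code = 0, run = 0;
  for (int i = 0; i < n; ++i) {
    const int xi = x[i];
    if (xi < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | xi) & mask;
    if (++run >= k) out[code]++;
  }
  return out;
}

// one Fisher-Yates pass over y, consuming one unif_rand() per position
// from n-1 down to 1 (the R-side oracle replays this stream exactly)
static void fy_shuffle(std::vector<int>& y) {
  const int n = (int) y.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    if (j > i) j = i; // guard against unif_rand() == 1.0
    std::swap(y[i], y[(size_t) j]);
  }
}

// permutation-null moments of k-mer counts: mean and sample sd
// (denominator n-1) of each k-mer count across n_shuffles random
// permutations of the letters of x. Uses R's RNG; callers set.seed.
// [[Rcpp::export]]
List shuffle_null_codes(const IntegerVector& x, int k, int n_shuffles) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2");
  const int nb = table_size(k);
  const int mask = nb - 1;
  const int n = x.size();
  std::vector<int> y(x.begin(), x.end());
  std::vector<double> s((size_t) nb, 0.0), ss((size_t) nb, 0.0);
  std::vector<int> cnt((size_t) nb, 0);
  for (int t = 0; t < n_shuffles; ++t) {
    fy_shuffle(y);
    std::fill(cnt.begin(), cnt.end(), 0);
    int code = 0, run = 0;
    for (int i = 0; i < n; ++i) {
      const int xi = y[(size_t) i];
      if (xi < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | xi) & mask;
      if (++run >= k) cnt[(size_t) code]++;
    }
    for (int c = 0; c < nb; ++c) {
      const double v = (double) cnt[(size_t) c];
      s[(size_t) c] += v;
      ss[(size_t) c] += v * v;
    }
  }
  NumericVector mean(nb), sdv(nb);
  const double nn = (double) n_shuffles;
  for (int c = 0; c < nb; ++c) {
    const double m = s[(size_t) c] / nn;
    double v = (ss[(size_t) c] - nn * m * m) / (nn - 1.0);
    if (v < 0) v = 0; // numerical guard
    mean[c] = m;
    sdv[c] = std::sqrt(v);
  }
  return List::create(_["mean"] = mean, _["sd"] = sdv);
}

// a single random permutation of the codes (same RNG stream as the
// null above), exposed for composition-preservation tests
// [[Rcpp::export]]
IntegerVector shuffle_codes(const IntegerVector& x) {
  std::vector<int> y(x.begin(), x.end());
  fy_shuffle(y);
  return IntegerVector(y.begin(), y.end());
}
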