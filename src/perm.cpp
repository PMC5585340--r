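#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double median_of(std::vector<double> &v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.begin() + n / 2);
  return 0.5 * (v[n / 2 - 1] + hi);
}

// Label-permutation null for |median(A) - median(B)|. x holds group A
// followed by group B (nA + nB values). Uses R's RNG so results follow
// set.seed(). Returns the observed statistic and the number of permuted
// statistics >= observed.
// [[Rcpp::export]]
List perm_median_count(NumericVector x, int nA, int n_perm) {
  const int n = x.size(), nB = n - nA;
  std::vector<double> pool(x.begin(), x.end());
  std::vector<double> a(pool.begin(), pool.begin() + nA);
  std::vector<double> b(pool.begin() + nA, pool.end());
  const double obs = std::fabs(median_of(a) - median_of(b));

  int count = 0;
  std::vector<double> work(pool);
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates: the first nA entries become a random subset
    for (int i = 0; i < nA; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(work[i], work[j]);
    }
    std::vector<double> pa(work.begin(), work.begin() + nA);
    std::vector<double> pb(work.begin() + nA, work.end());
    double stat = std::fabs(median_of(pa) - median_of(pb));
    if (stat >= obs) ++count;
    (void)nB;
  }
  return List::create(_["observed"] = obs, _["n_ge"] = count);
}
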