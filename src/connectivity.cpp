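// Connectivity-shift permutation machinery.
//
// The per-feature statistic is sum_j |atanh(rho_A(i,j)) - atanh(rho_B(i,j))|
// with rho the within-group Spearman correlation (average ranks, clipped at
// |rho| <= 0.999). The label-permutation null recomputes it for every
// shuffled label vector; this file keeps that O(n_perm * p^2 * n) loop off
// the R heap.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// average ranks of each row of X restricted to columns `cols`
static arma::mat rank_rows(const arma::mat& X, const arma::uvec& cols) {
  const arma::uword p = X.n_rows, n = cols.n_elem;
  arma::mat R(p, n);
  std::vector<std::pair<double, arma::uword>> v(n);
  for (arma::uword i = 0; i < p; ++i) {
    for (arma::uword k = 0; k < n; ++k)
      v[k] = std::make_pair(X(i, cols[k]), k);
    std::sort(v.begin(), v.end());
    arma::uword k = 0;
    while (k < n) {
      arma::uword j = k;
      while (j + 1 < n && v[j + 1].first == v[k].first) ++j;
      const double avg = 0.5 * static_cast<double>(k + j) + 1.0;
      for (arma::uword t = k; t <= j; ++t) R(i, v[t].second) = avg;
      k = j + 1;
    }
  }
  return R;
}

// Pearson correlation of the rows of R (ranks -> Spearman); zero-variance
// rows correlate 0 with everything
static arma::mat corr_rows(arma::mat R) {
  const arma::vec m = arma::mean(R, 1);
  R.each_col() -= m;
  arma::vec s = arma::sqrt(arma::sum(arma::square(R), 1));
  for (arma::uword i = 0; i < R.n_rows; ++i) {
    if (s[i] > 0.0) R.row(i) /= s[i]; else R.row(i).zeros();
  }
  return R * R.t();
}

static inline double zclip(double r) {
  if (r > 0.999) r = 0.999;
  if (r < -0.999) r = -0.999;
  return std::atanh(r);
}

static arma::vec scores_from_groups(const arma::mat& X,
                                    const arma::uvec& ia,
                                    const arma::uvec& ib) {
  const arma::uword p = X.n_rows;
  const arma::mat CA = corr_rows(rank_rows(X, ia));
  const arma::mat CB = corr_rows(rank_rows(X, ib));
  arma::vec score(p, arma::fill::zeros);
  for (arma::uword j = 1; j < p; ++j) {
    for (arma::uword i = 0; i < j; ++i) {
      const double d = std::fabs(zclip(CA(i, j)) - zclip(CB(i, j)));
      score[i] += d;
      score[j] += d;
    }
  }
  return score;
}

static arma::uvec which_group(const LogicalVector& in_a, bool want) {
  std::vector<arma::uword> idx;
  for (int k = 0; k < in_a.size(); ++k)
    if ((in_a[k] == TRUE) == want) idx.push_back(k);
  return arma::uvec(idx);
}

// [[Rcpp::export(name = ".cpp_shift_scores")]]
NumericVector cpp_shift_scores(const arma::mat& X,
                               const LogicalVector& in_a) {
  const arma::vec s = scores_from_groups(X, which_group(in_a, true),
                                         which_group(in_a, false));
  return NumericVector(s.begin(), s.end());
}

// standardize rank rows (center, unit norm; zero-variance rows -> 0)
static arma::mat standardize_rows(arma::mat R) {
  const arma::vec m = arma::mean(R, 1);
  R.each_col() -= m;
  arma::vec s = arma::sqrt(arma::sum(arma::square(R), 1));
  for (arma::uword i = 0; i < R.n_rows; ++i) {
    if (s[i] > 0.0) R.row(i) /= s[i]; else R.row(i).zeros();
  }
  return R;
}

// Counts, per feature, of permutations whose score >= the observed score;
// perms holds one shuffled 0/1 label vector per row. Features whose count
// exceeds count_cap can no longer reach an unadjusted p below the
// significance level (the count is non-decreasing), so they stop being
// scored; `done` records how many permutations each feature saw.
// count_cap < 0 disables pruning.
// [[Rcpp::export(name = ".cpp_perm_counts")]]
List cpp_perm_counts(const arma::mat& X,
                     const IntegerMatrix& perms,
                     const NumericVector& obs,
                     const double count_cap) {
  const arma::uword p = X.n_rows;
  arma::vec count(p, arma::fill::zeros);
  arma::vec done(p, arma::fill::zeros);
  std::vector<arma::uword> active(p);
  for (arma::uword i = 0; i < p; ++i) active[i] = i;

  for (int b = 0; b < perms.nrow(); ++b) {
    if (active.empty()) break;
    std::vector<arma::uword> a_idx, b_idx;
    for (int k = 0; k < perms.ncol(); ++k) {
      if (perms(b, k) == 1) a_idx.push_back(k); else b_idx.push_back(k);
    }
    const arma::mat SA = standardize_rows(rank_rows(X, arma::uvec(a_idx)));
    const arma::mat SB = standardize_rows(rank_rows(X, arma::uvec(b_idx)));
    const arma::uvec act(active);
    // correlations of active features against every feature; the
    // self-column contributes 0 (both correlations are 1)
    const arma::mat CA = SA.rows(act) * SA.t();
    const arma::mat CB = SB.rows(act) * SB.t();
    std::vector<arma::uword> still;
    still.reserve(active.size());
    for (arma::uword r = 0; r < act.n_elem; ++r) {
      double s = 0.0;
      for (arma::uword j = 0; j < p; ++j)
        s += std::fabs(zclip(CA(r, j)) - zclip(CB(r, j)));
      const arma::uword g = act[r];
      if (s >= obs[g]) count[g] += 1.0;
      done[g] += 1.0;
      if (count_cap < 0.0 || count[g] <= count_cap) still.push_back(g);
    }
    active.swap(still);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["count"] = NumericVector(count.begin(), count.end()),
                      _["done"] = NumericVector(done.begin(), done.end()));
}
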