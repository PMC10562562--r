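#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Dual coordinate descent for the L1-loss linear soft-margin SVM
// (Hsieh et al. 2008), run in Gram form: with n training samples the per
// update cost is O(n) regardless of feature count, which is what makes
// dense searchlight decoding tractable. The bias is a regularized
// augmented constant feature (the +1 added to every Gram entry).
// Deterministic: fixed sweep order, no shrinking.
static arma::vec dcd_alpha(const arma::mat& Q, const arma::vec& y, double C,
                           double tol = 1e-3, int max_pass = 200) {
  const arma::uword n = Q.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::zeros);
  G -= 1.0;  // y_i * f(x_i) - 1 at alpha = 0
  for (int pass = 0; pass < max_pass; ++pass) {
    double max_pg = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double g = G(i);
      double pg = g;
      if (alpha(i) <= 0.0 && g >= 0.0) pg = 0.0;
      if (alpha(i) >= C && g <= 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double qii = std::max(Q(i, i), 1e-12);
        double a_new = std::min(std::max(alpha(i) - g / qii, 0.0), C);
        double d = a_new - alpha(i);
        if (d != 0.0) {
          for (arma::uword j = 0; j < n; ++j)
            G(j) += d * y(i) * y(j) * Q(i, j);
          alpha(i) = a_new;
        }
      }
    }
    if (max_pg < tol) break;
  }
  return alpha;
}

// [[Rcpp::export]]
List cpp_svm_train(const arma::mat& X, const arma::vec& y, double C) {
  arma::mat Q = X * X.t() + 1.0;
  arma::vec alpha = dcd_alpha(Q, y, C);
  arma::vec w = X.t() * (alpha % y);
  double b = arma::dot(alpha, y);
  return List::create(_["w"] = w, _["b"] = b, _["alpha"] = alpha);
}

// [[Rcpp::export]]
arma::vec cpp_svm_decision(const arma::mat& X, const arma::vec& w, double b) {
  return X * w + b;
}

// Mean accuracy of one train/test job on given feature rows.
static double job_accuracy(const arma::mat& feat, const arma::uvec& members,
                           const arma::uvec& train_idx, const arma::vec& train_y,
                           const arma::uvec& test_idx, const arma::vec& test_y,
                           double C, bool center) {
  const arma::uword k = members.n_elem;
  arma::mat Xtr(train_idx.n_elem, k);
  arma::mat Xte(test_idx.n_elem, k);
  for (arma::uword j = 0; j < k; ++j) {
    for (arma::uword i = 0; i < train_idx.n_elem; ++i)
      Xtr(i, j) = feat(members(j), train_idx(i));
    for (arma::uword i = 0; i < test_idx.n_elem; ++i)
      Xte(i, j) = feat(members(j), test_idx(i));
  }
  if (center) {
    arma::rowvec mu = arma::mean(Xtr, 0);
    Xtr.each_row() -= mu;
    Xte.each_row() -= mu;
  }
  arma::mat Q = Xtr * Xtr.t() + 1.0;
  arma::vec alpha = dcd_alpha(Q, train_y, C);
  arma::vec coef = alpha % train_y;
  arma::vec dec = Xte * (Xtr.t() * coef) + arma::accu(coef);
  double correct = 0.0;
  for (arma::uword i = 0; i < test_y.n_elem; ++i)
    if ((dec(i) >= 0 ? 1.0 : -1.0) == test_y(i)) correct += 1.0;
  return correct / test_y.n_elem;
}

// Searchlight decoding: feat is n_vox x n_samples; members is an n_vox x K
// 0-padded matrix of 1-based in-mask row indices per sphere; jobs is a list
// of lists with fields train, train_y, test, test_y (1-based sample
// indices, labels in {-1, +1}). Returns per-sphere mean accuracy over jobs.
// [[Rcpp::export]]
arma::vec cpp_searchlight(const arma::mat& feat, const IntegerMatrix& members,
                          const List& jobs, double C, bool center) {
  const int V = members.nrow(), K = members.ncol();
  const int J = jobs.size();
  std::vector<arma::uvec> tr_idx(J), te_idx(J);
  std::vector<arma::vec> tr_y(J), te_y(J);
  for (int j = 0; j < J; ++j) {
    List jb = jobs[j];
    IntegerVector tr = jb["train"], te = jb["test"];
    NumericVector try_ = jb["train_y"], tey = jb["test_y"];
    tr_idx[j] = as<arma::uvec>(tr) - 1;
    te_idx[j] = as<arma::uvec>(te) - 1;
    tr_y[j] = as<arma::vec>(try_);
    te_y[j] = as<arma::vec>(tey);
  }
  arma::vec acc(V, arma::fill::zeros);
  arma::uvec mem(K);
  for (int v = 0; v < V; ++v) {
    int k = 0;
    for (int c = 0; c < K; ++c) {
      int m = members(v, c);
      if (m > 0) mem(k++) = m - 1;
    }
    if (k == 0) { acc(v) = NA_REAL; continue; }
    arma::uvec mv = mem.head(k);
    double a = 0.0;
    for (int j = 0; j < J; ++j)
      a += job_accuracy(feat, mv, tr_idx[j], tr_y[j], te_idx[j], te_y[j],
                        C, center);
    acc(v) = a / J;
  }
  return acc;
}
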