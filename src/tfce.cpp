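#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Union-find with path compression and size tracking.
struct UF {
  std::vector<int> parent, size;
  UF(int n) : parent(n), size(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

// 26-connected neighbor lists among the in-mask voxels, built from their
// 1-based linear indices within a dims grid.
static std::vector<std::vector<int>> build_neighbors(
    const arma::ivec& vox_index, int dx, int dy, int dz) {
  const int V = vox_index.n_elem;
  std::vector<int> lookup((size_t)dx * dy * dz, -1);
  std::vector<int> xs(V), ys(V), zs(V);
  for (int v = 0; v < V; ++v) {
    int lin = vox_index(v) - 1;
    xs[v] = lin % dx;
    ys[v] = (lin / dx) % dy;
    zs[v] = lin / (dx * dy);
    lookup[lin] = v;
  }
  std::vector<std::vector<int>> nb(V);
  for (int v = 0; v < V; ++v) {
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          if (ox == 0 && oy == 0 && oz == 0) continue;
          int x = xs[v] + ox, y = ys[v] + oy, z = zs[v] + oz;
          if (x < 0 || x >= dx || y < 0 || y >= dy || z < 0 || z >= dz)
            continue;
          int u = lookup[(size_t)z * dx * dy + (size_t)y * dx + x];
          if (u >= 0) nb[v].push_back(u);
        }
  }
  return nb;
}

// TFCE on a sparse voxel set: descending-threshold sweep with incremental
// union-find; only the positive branch is enhanced.
static arma::vec tfce_sparse(const arma::vec& stat,
                             const std::vector<std::vector<int>>& nb,
                             double E, double H, int n_steps, double dh_in) {
  const int V = stat.n_elem;
  arma::vec out(V, arma::fill::zeros);
  double hmax = stat.max();
  if (hmax <= 0) return out;
  double dh = dh_in > 0 ? dh_in : hmax / n_steps;
  int nh = (int)std::floor(hmax / dh + 1e-12);
  if (nh < 1) return out;
  arma::uvec ord = arma::sort_index(stat, "descend");
  UF uf(V);
  std::vector<bool> active(V, false);
  std::vector<int> active_list;
  active_list.reserve(V);
  arma::uword next = 0;
  for (int s = nh; s >= 1; --s) {
    double h = s * dh;
    while (next < (arma::uword)V && stat(ord(next)) >= h) {
      int v = ord(next);
      active[v] = true;
      uf.size[v] = 1;
      active_list.push_back(v);
      for (int u : nb[v]) if (active[u]) uf.unite(v, u);
      ++next;
    }
    double hH = std::pow(h, H) * dh;
    for (int v : active_list)
      out(v) += std::pow((double)uf.size[uf.find(v)], E) * hH;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_tfce(const arma::vec& stat, const arma::ivec& vox_index,
                   const IntegerVector& dims, double E, double H,
                   int n_steps, double dh) {
  if (dh <= 0 && n_steps < 1) stop("dh (or n_steps) must be positive");
  auto nb = build_neighbors(vox_index, dims[0], dims[1], dims[2]);
  return tfce_sparse(stat, nb, E, H, n_steps, dh);
}

// Voxelwise one-sided t statistics for one tested column of a fixed design,
// computed for many permuted datasets. Used by the permutation engine.
static arma::rowvec tstat_rows(const arma::mat& Y, const arma::mat& X,
                               const arma::mat& P, const arma::rowvec& crow,
                               double g, int df) {
  arma::mat B = P * Y;                       // k x V
  arma::mat res = Y - X * B;                 // n x V
  arma::rowvec s2 = arma::sum(arma::square(res), 0) / df;
  arma::rowvec denom = arma::sqrt(s2 * g);
  denom.for_each([](double& x) { if (x < 1e-300) x = 1e-300; });
  return (crow * B) / denom;
}

// Max-statistic permutation engine with optional TFCE. Y: n x V maps;
// X: n x k design; test_col: 0-based tested column; perm: n_perm x n matrix
// of sign flips (scheme = 0) or 1-based row permutations (scheme = 1),
// applied to the reduced-model residuals (Freedman-Lane; for an
// intercept-only design the residuals are the data themselves).
// [[Rcpp::export]]
List cpp_perm_maxstat(const arma::mat& Y, const arma::mat& X, int test_col,
                      const arma::mat& perm, int scheme, bool use_tfce,
                      const arma::ivec& vox_index, const IntegerVector& dims,
                      double E, double H, int n_steps) {
  const int n = Y.n_rows;
  const int k = X.n_cols;
  const int n_perm = perm.n_rows;
  arma::mat XtXi = arma::inv_sympd(X.t() * X);
  arma::mat P = XtXi * X.t();
  double g = XtXi(test_col, test_col);
  arma::rowvec crow(k, arma::fill::zeros);
  crow(test_col) = 1.0;
  int df = n - k;
  if (df < 1) stop("not enough subjects for the design");

  // reduced model (design without the tested column)
  arma::mat fitted_red(n, Y.n_cols, arma::fill::zeros);
  arma::mat resid_red = Y;
  if (k > 1) {
    arma::mat Z = X;
    Z.shed_col(test_col);
    arma::mat Pz = Z * arma::solve(Z.t() * Z, Z.t());
    fitted_red = Pz * Y;
    resid_red = Y - fitted_red;
  }

  std::vector<std::vector<int>> nb;
  if (use_tfce) nb = build_neighbors(vox_index, dims[0], dims[1], dims[2]);

  arma::rowvec t_obs = tstat_rows(Y, X, P, crow, g, df);
  arma::vec stat_obs;
  // one step height, fixed from the observed map, shared by every
  // permutation so that enhanced values are comparable across the null
  double dh_fix = -1.0;
  if (use_tfce) {
    double hmax = t_obs.max();
    dh_fix = (hmax > 0) ? hmax / n_steps : 1.0;
    stat_obs = tfce_sparse(t_obs.t(), nb, E, H, n_steps, dh_fix);
  } else {
    stat_obs = t_obs.t();
  }

  arma::vec max_dist(n_perm);
  arma::mat Yp(n, Y.n_cols);
  for (int pi = 0; pi < n_perm; ++pi) {
    if (scheme == 0) {
      for (int i = 0; i < n; ++i)
        Yp.row(i) = fitted_red.row(i) + perm(pi, i) * resid_red.row(i);
    } else {
      for (int i = 0; i < n; ++i)
        Yp.row(i) = fitted_red.row(i) + resid_red.row((int)perm(pi, i) - 1);
    }
    arma::rowvec tp = tstat_rows(Yp, X, P, crow, g, df);
    if (use_tfce) {
      arma::vec sp = tfce_sparse(tp.t(), nb, E, H, n_steps, dh_fix);
      max_dist(pi) = sp.max();
    } else {
      max_dist(pi) = tp.max();
    }
  }
  arma::vec p_fwe(Y.n_cols);
  for (arma::uword v = 0; v < Y.n_cols; ++v) {
    double count = 0;
    for (int pi = 0; pi < n_perm; ++pi)
      if (max_dist(pi) >= stat_obs(v)) count += 1.0;
    p_fwe(v) = (1.0 + count) / (1.0 + n_perm);
  }
  return List::create(_["t"] = t_obs.t(), _["stat"] = stat_obs,
                      _["max_dist"] = max_dist, _["p_fwe"] = p_fwe);
}
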