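#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Periodized two-channel analysis step:
//   a[i] = sum_k h[k] * x[(2i + L/2 - k) mod n]
// with x extended by repeating its last sample when its length is odd.
// For even n the analysis rows are orthonormal for any Daubechies pair
// (all even-lag autocorrelations vanish), so the transpose is the exact
// inverse and Parseval holds.
static void split_node(const arma::vec& x0, const arma::vec& h,
                       const arma::vec& g, arma::vec& a, arma::vec& d) {
  arma::vec x = x0;
  if (x.n_elem % 2u) {
    x.resize(x.n_elem + 1);
    x(x.n_elem - 1) = x0(x0.n_elem - 1);
  }
  const int n = (int)x.n_elem, L = (int)h.n_elem, half = n / 2, off = L / 2;
  a.zeros(half);
  d.zeros(half);
  for (int i = 0; i < half; ++i) {
    double sa = 0.0, sd = 0.0;
    for (int k = 0; k < L; ++k) {
      int m = (2 * i + off - k) % n;
      if (m < 0) m += n;
      sa += h[k] * x[m];
      sd += g[k] * x[m];
    }
    a[i] = sa;
    d[i] = sd;
  }
}

// Transpose of the analysis step; reconstructs a parent of length
// len_parent (dropping the sample appended for odd parents).
static arma::vec merge_node(const arma::vec& a, const arma::vec& d,
                            const arma::vec& h, const arma::vec& g,
                            int len_parent) {
  const int half = (int)a.n_elem, n = 2 * half, L = (int)h.n_elem, off = L / 2;
  arma::vec x(n, arma::fill::zeros);
  for (int i = 0; i < half; ++i) {
    for (int k = 0; k < L; ++k) {
      int m = (2 * i + off - k) % n;
      if (m < 0) m += n;
      x[m] += h[k] * a[i] + g[k] * d[i];
    }
  }
  return x.head(len_parent);
}

static void decompose_all(const arma::vec& x, int level, const arma::vec& h,
                          const arma::vec& g,
                          std::vector<std::vector<arma::vec> >& lev,
                          arma::ivec& lens) {
  lev.assign(level + 1, std::vector<arma::vec>());
  lev[0].push_back(x);
  lens.set_size(level + 1);
  lens[0] = (int)x.n_elem;
  for (int j = 1; j <= level; ++j) {
    lev[j].resize((size_t)1 << j);
    for (int i = 0; i < (1 << (j - 1)); ++i)
      split_node(lev[j - 1][i], h, g, lev[j][2 * i], lev[j][2 * i + 1]);
    lens[j] = (int)lev[j][0].n_elem;
  }
}

static arma::vec reconstruct_masked(const std::vector<arma::vec>& leaves,
                                    int level, const arma::ivec& lens,
                                    const std::vector<bool>& keep,
                                    const arma::vec& h, const arma::vec& g) {
  int nn = 1 << level;
  std::vector<arma::vec> cur(nn);
  for (int i = 0; i < nn; ++i) {
    if (keep[i]) cur[i] = leaves[i];
    else cur[i] = arma::vec((size_t)lens[level], arma::fill::zeros);
  }
  for (int j = level; j >= 1; --j) {
    int np = 1 << (j - 1);
    std::vector<arma::vec> par(np);
    for (int i = 0; i < np; ++i)
      par[i] = merge_node(cur[2 * i], cur[2 * i + 1], h, g, (int)lens[j - 1]);
    cur.swap(par);
  }
  return cur[0];
}

// [[Rcpp::export]]
List cpp_wpt_decompose(const arma::vec& x, int level, const arma::vec& h,
                       const arma::vec& g) {
  std::vector<std::vector<arma::vec> > lev;
  arma::ivec lens;
  decompose_all(x, level, h, g, lev, lens);
  int nn = 1 << level;
  List nodes(nn);
  for (int i = 0; i < nn; ++i)
    nodes[i] = NumericVector(lev[level][i].begin(), lev[level][i].end());
  return List::create(_["nodes"] = nodes,
                      _["lens"] = IntegerVector(lens.begin(), lens.end()));
}

// [[Rcpp::export]]
arma::vec cpp_wpt_reconstruct(List nodes, int level, IntegerVector lens,
                              LogicalVector keep, const arma::vec& h,
                              const arma::vec& g) {
  int nn = 1 << level;
  std::vector<arma::vec> leaves(nn);
  std::vector<bool> km(nn);
  for (int i = 0; i < nn; ++i) {
    leaves[i] = as<arma::vec>(nodes[i]);
    km[i] = keep[i];
  }
  arma::ivec lv(level + 1);
  for (int j = 0; j <= level; ++j) lv[j] = lens[j];
  return reconstruct_masked(leaves, level, lv, km, h, g);
}

// Decompose once, reconstruct one signal per row of `keep` (bands x nodes).
// Returns an n x n_bands matrix.
// [[Rcpp::export]]
arma::mat cpp_wpt_band_signals(const arma::vec& x, int level,
                               const arma::vec& h, const arma::vec& g,
                               const LogicalMatrix& keep) {
  std::vector<std::vector<arma::vec> > lev;
  arma::ivec lens;
  decompose_all(x, level, h, g, lev, lens);
  int nb = keep.nrow();
  arma::mat out(x.n_elem, nb);
  for (int b = 0; b < nb; ++b) {
    std::vector<bool> km(1 << level);
    for (int i = 0; i < (1 << level); ++i) km[i] = keep(b, i);
    out.col(b) = reconstruct_masked(lev[level], level, lens, km, h, g);
  }
  return out;
}
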