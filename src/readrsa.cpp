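// Compiled kernels: online backprop training for the feedforward
// orthography->phonology network, the spherical-searchlight sweep
// (per-sphere correlation-distance RDM + rank-based comparison), and
// connected-component labelling for cluster-extent thresholding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Single-sample forward + gradient of the summed cross-entropy loss.
// ext is the scalar external input added to the pre-activation of every
// output unit whose target is 1.
static void ann_sample_grad(const arma::mat& W1, const arma::vec& b1,
                            const arma::mat& W2, const arma::vec& b2,
                            const arma::vec& x, const arma::vec& t,
                            double ext,
                            arma::vec& h, arma::vec& y,
                            arma::mat& gW1, arma::vec& gb1,
                            arma::mat& gW2, arma::vec& gb2,
                            double& loss) {
  h = W1 * x + b1;
  h.transform([](double v) { return logistic(v); });
  arma::vec a2 = W2 * h + b2 + ext * t;
  y = a2;
  y.transform([](double v) { return logistic(v); });
  loss = 0.0;
  const double eps = 1e-12;
  for (arma::uword k = 0; k < y.n_elem; ++k) {
    loss -= t(k) * std::log(y(k) + eps) + (1.0 - t(k)) * std::log(1.0 - y(k) + eps);
  }
  arma::vec d2 = y - t;                       // dL/da2 for logistic + CE
  gW2 = d2 * h.t();
  gb2 = d2;
  arma::vec d1 = (W2.t() * d2) % h % (1.0 - h);
  gW1 = d1 * x.t();
  gb1 = d1;
}

// [[Rcpp::export]]
List cpp_ann_grad(const arma::mat& W1, const arma::vec& b1,
                  const arma::mat& W2, const arma::vec& b2,
                  const arma::vec& x, const arma::vec& t, double ext) {
  arma::vec h, y;
  arma::mat gW1, gW2;
  arma::vec gb1, gb2;
  double loss;
  ann_sample_grad(W1, b1, W2, b2, x, t, ext, h, y, gW1, gb1, gW2, gb2, loss);
  return List::create(_["loss"] = loss, _["hidden"] = h, _["output"] = y,
                      _["gW1"] = gW1, _["gb1"] = gb1,
                      _["gW2"] = gW2, _["gb2"] = gb2);
}

// [[Rcpp::export]]
List cpp_ann_forward(const arma::mat& W1, const arma::vec& b1,
                     const arma::mat& W2, const arma::vec& b2,
                     const arma::mat& X, const arma::vec& ext_scale,
                     const arma::mat& Tmat) {
  // X: n_stim x n_input; ext added as ext_scale(i) * target row i.
  arma::mat H = X * W1.t();
  H.each_row() += b1.t();
  H.transform([](double v) { return logistic(v); });
  arma::mat A2 = H * W2.t();
  A2.each_row() += b2.t();
  A2 += Tmat.each_col() % ext_scale;
  A2.transform([](double v) { return logistic(v); });
  return List::create(_["hidden"] = H, _["output"] = A2);
}

// Online SGD over the word set, one pass per epoch, order shuffled each
// epoch with R's RNG (reproducible from set.seed). Returns final weights
// plus per-epoch mean loss and training accuracy (rounded-output match,
// scored with that epoch's external input).
// [[Rcpp::export]]
List cpp_ann_train(arma::mat W1, arma::vec b1, arma::mat W2, arma::vec b2,
                   const arma::mat& X, const arma::mat& Tmat,
                   const arma::vec& comp_freq, int epochs, double lr,
                   double ramp_gain, double ramp_halflife) {
  const arma::uword n = X.n_rows;
  arma::vec h, y, gb1, gb2;
  arma::mat gW1, gW2;
  arma::vec mean_loss(epochs), acc(epochs);
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;
  GetRNGstate();
  for (int e = 0; e < epochs; ++e) {
    // epoch numbering: pass e+1 uses ramp((e+1)-1)?  The ramp is evaluated
    // at the epoch index starting at 0 so that the very first pass has no
    // external input (ramp(0) = 0) and later passes approach 1.
    double ramp = (double)e / ((double)e + ramp_halflife);
    // Fisher-Yates with R uniforms
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(unif_rand() * (double)(i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double tot = 0.0;
    for (arma::uword ii = 0; ii < n; ++ii) {
      arma::uword w = order[ii];
      double ext = ramp_gain * ramp * comp_freq(w);
      double loss;
      ann_sample_grad(W1, b1, W2, b2, X.row(w).t(), Tmat.row(w).t(), ext,
                      h, y, gW1, gb1, gW2, gb2, loss);
      if (!std::isfinite(loss)) {
        PutRNGstate();
        stop("non-finite loss at epoch %d, word %d", e + 1, (int)w + 1);
      }
      W1 -= lr * gW1; b1 -= lr * gb1;
      W2 -= lr * gW2; b2 -= lr * gb2;
      tot += loss;
    }
    mean_loss(e) = tot / (double)n;
    // accuracy at this epoch's external-input level
    int ncorr = 0;
    for (arma::uword w = 0; w < n; ++w) {
      double ext = ramp_gain * ramp * comp_freq(w);
      arma::vec hh = W1 * X.row(w).t() + b1;
      hh.transform([](double v) { return logistic(v); });
      arma::vec a2 = W2 * hh + b2 + ext * Tmat.row(w).t();
      bool ok = true;
      for (arma::uword k = 0; k < a2.n_elem; ++k) {
        double out = logistic(a2(k));
        double r = (out >= 0.5) ? 1.0 : 0.0;
        if (r != Tmat(w, k)) { ok = false; break; }
      }
      if (ok) ++ncorr;
    }
    acc(e) = (double)ncorr / (double)n;
  }
  PutRNGstate();
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["mean_loss"] = mean_loss, _["accuracy"] = acc);
}

// average ranks with ties (1-based, like R's rank(ties.method="average"))
static void avg_rank(const arma::vec& v, arma::vec& r, arma::uvec& idx) {
  idx = arma::sort_index(v);
  const arma::uword n = v.n_elem;
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && v(idx(j + 1)) == v(idx(i))) ++j;
    double rk = 0.5 * ((double)i + (double)j) + 1.0;
    for (arma::uword k = i; k <= j; ++k) r(idx(k)) = rk;
    i = j + 1;
  }
}

static double pearson(const arma::vec& a, const arma::vec& b) {
  double ma = arma::mean(a), mb = arma::mean(b);
  arma::vec da = a - ma, db = b - mb;
  double den = std::sqrt(arma::dot(da, da) * arma::dot(db, db));
  if (den <= 0.0) return NA_REAL;
  return arma::dot(da, db) / den;
}

// Searchlight sweep.  betas: n_stim x n_mask (columns follow mask_index
// order).  vox_lin: linear index (0-based) into the grid for each mask
// column.  lookup: length nx*ny*nz, mask column (0-based) or -1.
// centers: indices into mask columns at which to evaluate.
// model_ranks: P x n_models matrix of pre-ranked model RDM upper triangles;
// control_of: per-model 0-based column of its control in model_ranks, or -1
// for a plain Spearman comparison.
// Returns n_centers x n_models rho matrix (NaN where skipped) and sphere
// occupancy per center.
// [[Rcpp::export]]
List cpp_searchlight(const arma::mat& betas,
                     const arma::ivec& vox_x, const arma::ivec& vox_y,
                     const arma::ivec& vox_z,
                     const arma::ivec& lookup,
                     int nx, int ny, int nz,
                     const arma::imat& offsets,
                     const arma::ivec& centers,
                     const arma::mat& model_ranks,
                     const arma::ivec& control_of,
                     int min_vox, double min_frac) {
  const arma::uword n_stim = betas.n_rows;
  const arma::uword P = n_stim * (n_stim - 1) / 2;
  const arma::uword n_models = model_ranks.n_cols;
  const arma::uword n_centers = centers.n_elem;
  const arma::uword n_off = offsets.n_rows;
  arma::mat rho(n_centers, n_models);
  rho.fill(arma::datum::nan);
  arma::ivec occ(n_centers, arma::fill::zeros);

  // precompute model rank stats and control cross-correlations
  arma::vec m_mean(n_models), m_ss(n_models);
  for (arma::uword m = 0; m < n_models; ++m) {
    m_mean(m) = arma::mean(model_ranks.col(m));
    arma::vec d = model_ranks.col(m) - m_mean(m);
    m_ss(m) = arma::dot(d, d);
  }
  arma::vec r_mc(n_models, arma::fill::zeros);
  for (arma::uword m = 0; m < n_models; ++m) {
    if (control_of(m) >= 0) {
      r_mc(m) = pearson(model_ranks.col(m),
                        model_ranks.col((arma::uword)control_of(m)));
      if (std::abs(r_mc(m)) >= 1.0 - 1e-12)
        stop("model and control RDMs are rank-identical; partial correlation undefined");
    }
  }

  arma::uvec sphere(n_off);
  arma::vec dvec(P), drank(P), tmp;
  arma::uvec sidx;
  arma::mat sub;
  int thr = std::max(min_vox, (int)std::ceil(min_frac * (double)n_off));

  for (arma::uword c = 0; c < n_centers; ++c) {
    int ci = centers(c);
    int cx = vox_x(ci), cy = vox_y(ci), cz = vox_z(ci);
    arma::uword k = 0;
    for (arma::uword o = 0; o < n_off; ++o) {
      int x = cx + offsets(o, 0), y = cy + offsets(o, 1), z = cz + offsets(o, 2);
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
      int col = lookup(x + nx * (y + ny * z));
      if (col >= 0) sphere(k++) = (arma::uword)col;
    }
    occ(c) = (int)k;
    if ((int)k < thr || k < 2) continue;  // pairwise correlation needs >= 2 voxels
    sub = betas.cols(sphere.head(k));     // n_stim x k
    // standardize rows, then crossprod gives pairwise Pearson
    arma::vec rm = arma::mean(sub, 1);
    sub.each_col() -= rm;
    arma::vec sd = arma::sqrt(arma::sum(arma::square(sub), 1));
    bool degenerate = false;
    for (arma::uword i = 0; i < n_stim; ++i) {
      if (sd(i) <= 0.0) { degenerate = true; break; }
    }
    if (degenerate) continue;             // flat pattern: distance undefined, skip
    sub.each_col() /= sd;
    arma::mat C = sub * sub.t();          // n_stim x n_stim correlations
    arma::uword p = 0;
    for (arma::uword j = 1; j < n_stim; ++j)
      for (arma::uword i = 0; i < j; ++i) dvec(p++) = 1.0 - C(i, j);
    avg_rank(dvec, drank, sidx);
    double n_mean = arma::mean(drank);
    arma::vec nd = drank - n_mean;
    double n_ss = arma::dot(nd, nd);
    if (n_ss <= 0.0) continue;            // all distances tied
    for (arma::uword m = 0; m < n_models; ++m) {
      arma::vec md = model_ranks.col(m) - m_mean(m);
      double r_tm = arma::dot(nd, md) / std::sqrt(n_ss * m_ss(m));
      if (control_of(m) < 0) {
        rho(c, m) = r_tm;
      } else {
        arma::uword cc = (arma::uword)control_of(m);
        arma::vec cd = model_ranks.col(cc) - m_mean(cc);
        double r_tc = arma::dot(nd, cd) / std::sqrt(n_ss * m_ss(cc));
        double den = std::sqrt((1.0 - r_tc * r_tc) * (1.0 - r_mc(m) * r_mc(m)));
        rho(c, m) = (den > 0.0) ? (r_tm - r_tc * r_mc(m)) / den : NA_REAL;
      }
    }
  }
  return List::create(_["rho"] = rho, _["occupancy"] = occ);
}

// Connected components of a binary volume. connectivity: 6 (faces),
// 18 (faces+edges) or 26 (faces+edges+corners). Returns integer labels
// (0 = background), components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(const LogicalVector& vol, int nx, int ny, int nz,
                                 int connectivity) {
  IntegerVector lab(vol.size(), 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz_ = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz_ == 0) continue;
        if (connectivity == 6 && nz_ > 1) continue;
        if (connectivity == 18 && nz_ > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < vol.size(); ++idx) {
    if (!vol[idx] || lab[idx] != 0) continue;
    ++next;
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny), rem = cur % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (auto& d : nb) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = xx + nx * (yy + ny * zz);
        if (vol[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("n_clusters") = next;
  return lab;
}
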