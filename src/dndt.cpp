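// Differentiable decision-tree ensemble: soft binning of each feature
// (temperature-scaled softmax over learned cut points), Kronecker-product
// leaf routing, linear leaf classifiers, trained jointly by minibatch SGD
// on the cross-entropy of the ensemble-averaged class distribution.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft binning of scalar x with `ncuts` cut points beta:
//   logits a_k = ((k+1) * x + b_k) / tau,  b_0 = 0, b_k = -(beta_0+...+beta_{k-1})
// f = softmax(a). Writes nb = ncuts+1 values into f (and raw logits into a).
static inline void soft_bin_fwd(double x, const double* beta, int ncuts,
                                double tau, double* f, double* a) {
  const int nb = ncuts + 1;
  double bsum = 0.0, amax = -1e300;
  for (int k = 0; k < nb; ++k) {
    if (k > 0) bsum -= beta[k - 1];
    a[k] = ((k + 1.0) * x + bsum) / tau;
    if (a[k] > amax) amax = a[k];
  }
  double s = 0.0;
  for (int k = 0; k < nb; ++k) {
    f[k] = std::exp(a[k] - amax);
    s += f[k];
  }
  for (int k = 0; k < nb; ++k) f[k] /= s;
}

static inline void softmax_inplace(std::vector<double>& u) {
  double m = u[0];
  for (size_t c = 1; c < u.size(); ++c) if (u[c] > m) m = u[c];
  double s = 0.0;
  for (size_t c = 0; c < u.size(); ++c) { u[c] = std::exp(u[c] - m); s += u[c]; }
  for (size_t c = 0; c < u.size(); ++c) u[c] /= s;
}

// bin index of subset-feature d at leaf l, for nb bins per feature and m
// features, with z = f_0 (x) f_1 (x) ... (x) f_{m-1} (first factor slowest).
static inline int leaf_bin(int l, int d, int m, int nb) {
  int stride = 1;
  for (int t = 0; t < m - 1 - d; ++t) stride *= nb;
  return (l / stride) % nb;
}

// [[Rcpp::export]]
List dndt_fit_cpp(NumericMatrix X, IntegerVector y, IntegerMatrix subsets,
                  int n_cuts, int n_class, NumericVector tau_sched,
                  double lr, int batch_size, IntegerMatrix order,
                  List beta_init, List leaf_init) {
  const int n = X.nrow();
  const int T = subsets.nrow();
  const int m = subsets.ncol();
  const int nb = n_cuts + 1;
  int L = 1;
  for (int d = 0; d < m; ++d) L *= nb;
  const int epochs = order.nrow();

  // parameters (copied from the seeded initializers)
  std::vector<std::vector<double>> beta(T), leaf(T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix b0 = beta_init[t]; // m x n_cuts
    NumericMatrix l0 = leaf_init[t]; // L x n_class
    beta[t].assign(b0.begin(), b0.end());
    leaf[t].assign(l0.begin(), l0.end());
  }
  // gradients
  std::vector<std::vector<double>> gbeta(T, std::vector<double>(m * n_cuts));
  std::vector<std::vector<double>> gleaf(T, std::vector<double>(L * n_class));

  // leaf -> per-feature bin table
  std::vector<int> binmap(L * m);
  for (int l = 0; l < L; ++l)
    for (int d = 0; d < m; ++d) binmap[l * m + d] = leaf_bin(l, d, m, nb);

  // per-sample stores
  std::vector<std::vector<double>> f_all(T, std::vector<double>(m * nb));
  std::vector<std::vector<double>> z_all(T, std::vector<double>(L));
  std::vector<std::vector<double>> p_all(T, std::vector<double>(n_class));
  std::vector<double> a_buf(nb), gz(L), gf(m * nb), ga(nb), p_ens(n_class);
  std::vector<double> u(n_class);

  NumericVector loss_hist(epochs);
  int bad_epoch = -1;

  for (int e = 0; e < epochs && bad_epoch < 0; ++e) {
    const double tau = tau_sched[e];
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bsz = std::min(batch_size, n - start);
      for (int t = 0; t < T; ++t) {
        std::fill(gbeta[t].begin(), gbeta[t].end(), 0.0);
        std::fill(gleaf[t].begin(), gleaf[t].end(), 0.0);
      }
      double batch_loss = 0.0;
      for (int bi = 0; bi < bsz; ++bi) {
        const int i = order(e, start + bi);
        const int yi = y[i];
        std::fill(p_ens.begin(), p_ens.end(), 0.0);
        // forward
        for (int t = 0; t < T; ++t) {
          double* f = f_all[t].data();
          for (int d = 0; d < m; ++d) {
            soft_bin_fwd(X(i, subsets(t, d)), beta[t].data() + d * n_cuts,
                         n_cuts, tau, f + d * nb, a_buf.data());
          }
          double* z = z_all[t].data();
          for (int l = 0; l < L; ++l) {
            double prod = 1.0;
            for (int d = 0; d < m; ++d) prod *= f[d * nb + binmap[l * m + d]];
            z[l] = prod;
          }
          for (int c = 0; c < n_class; ++c) {
            double s = 0.0;
            for (int l = 0; l < L; ++l) s += z[l] * leaf[t][l + c * L];
            u[c] = s;
          }
          softmax_inplace(u);
          for (int c = 0; c < n_class; ++c) p_all[t][c] = u[c];
          for (int c = 0; c < n_class; ++c) p_ens[c] += u[c] / T;
        }
        // loss reported unclamped: exact-zero probability of the true class
        // (or NaN parameters) surfaces as a non-finite epoch loss
        batch_loss += -std::log(p_ens[yi]);
        const double py = std::max(p_ens[yi], 1e-300);
        // backward
        for (int t = 0; t < T; ++t) {
          const double* pt = p_all[t].data();
          const double coef = -(1.0 / T) * (pt[yi] / py) / bsz;
          // g_u = coef * (e_y - p_t)
          const double* z = z_all[t].data();
          const double* f = f_all[t].data();
          // leaf gradient and g_z
          for (int l = 0; l < L; ++l) gz[l] = 0.0;
          for (int c = 0; c < n_class; ++c) {
            const double gu = coef * ((c == yi ? 1.0 : 0.0) - pt[c]);
            if (gu == 0.0) continue;
            double* gl = gleaf[t].data() + c * L;
            const double* lf = leaf[t].data() + c * L;
            for (int l = 0; l < L; ++l) {
              gl[l] += z[l] * gu;
              gz[l] += lf[l] * gu;
            }
          }
          // g_f via leave-one-out products
          std::fill(gf.begin(), gf.end(), 0.0);
          for (int l = 0; l < L; ++l) {
            if (gz[l] == 0.0) continue;
            for (int d = 0; d < m; ++d) {
              double prod = 1.0;
              for (int d2 = 0; d2 < m; ++d2) {
                if (d2 != d) prod *= f[d2 * nb + binmap[l * m + d2]];
              }
              gf[d * nb + binmap[l * m + d]] += gz[l] * prod;
            }
          }
          // back through softmax and cut points
          for (int d = 0; d < m; ++d) {
            const double* fd = f + d * nb;
            const double* gfd = gf.data() + d * nb;
            double dot = 0.0;
            for (int k = 0; k < nb; ++k) dot += gfd[k] * fd[k];
            for (int k = 0; k < nb; ++k) ga[k] = fd[k] * (gfd[k] - dot);
            // a_k depends on beta_j (j <= k-1) with coefficient -1/tau
            double tail = 0.0;
            for (int j = n_cuts - 1; j >= 0; --j) {
              tail += ga[j + 1];
              gbeta[t][d * n_cuts + j] += -tail / tau;
            }
          }
        }
      }
      // SGD update
      for (int t = 0; t < T; ++t) {
        for (size_t q = 0; q < beta[t].size(); ++q) beta[t][q] -= lr * gbeta[t][q];
        for (size_t q = 0; q < leaf[t].size(); ++q) leaf[t][q] -= lr * gleaf[t][q];
      }
      epoch_loss += batch_loss / bsz;
      ++n_batches;
    }
    loss_hist[e] = epoch_loss / n_batches;
    if (!R_finite(loss_hist[e])) bad_epoch = e;
  }

  List beta_out(T), leaf_out(T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix bm(m, n_cuts);
    std::copy(beta[t].begin(), beta[t].end(), bm.begin());
    NumericMatrix lm(L, n_class);
    std::copy(leaf[t].begin(), leaf[t].end(), lm.begin());
    beta_out[t] = bm;
    leaf_out[t] = lm;
  }
  return List::create(_["beta"] = beta_out, _["leaf"] = leaf_out,
                      _["loss"] = loss_hist,
                      _["diverged_epoch"] = bad_epoch + 1);
}

// [[Rcpp::export]]
NumericMatrix dndt_predict_cpp(NumericMatrix X, IntegerMatrix subsets,
                               int n_cuts, int n_class, double tau,
                               List beta, List leaf) {
  const int n = X.nrow();
  const int T = subsets.nrow();
  const int m = subsets.ncol();
  const int nb = n_cuts + 1;
  int L = 1;
  for (int d = 0; d < m; ++d) L *= nb;

  std::vector<int> binmap(L * m);
  for (int l = 0; l < L; ++l)
    for (int d = 0; d < m; ++d) binmap[l * m + d] = leaf_bin(l, d, m, nb);

  NumericMatrix out(n, n_class);
  std::vector<double> f(m * nb), a(nb), z(L), u(n_class);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      NumericMatrix bt = beta[t];
      NumericMatrix lt = leaf[t];
      for (int d = 0; d < m; ++d) {
        std::vector<double> bd(n_cuts);
        for (int k = 0; k < n_cuts; ++k) bd[k] = bt(d, k);
        soft_bin_fwd(X(i, subsets(t, d)), bd.data(), n_cuts, tau,
                     f.data() + d * nb, a.data());
      }
      for (int l = 0; l < L; ++l) {
        double prod = 1.0;
        for (int d = 0; d < m; ++d) prod *= f[d * nb + binmap[l * m + d]];
        z[l] = prod;
      }
      for (int c = 0; c < n_class; ++c) {
        double s = 0.0;
        for (int l = 0; l < L; ++l) s += z[l] * lt(l, c);
        u[c] = s;
      }
      softmax_inplace(u);
      for (int c = 0; c < n_class; ++c) out(i, c) += u[c] / T;
    }
  }
  return out;
}
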