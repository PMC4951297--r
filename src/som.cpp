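#include <Rcpp.h>
using namespace Rcpp;

// Sequential (online) SOM training.
//
// codebook: M x D (modified copy returned), data: n x D,
// order: 0-based data-row index per presentation (length epochs * n),
// alphas, radii: per-presentation schedules,
// unit_dist: M x M toroidal lattice distances,
// gaussian: false = bubble neighborhood (full alpha within radius),
//           true  = gaussian factor exp(-d^2 / (2 r^2)).
// Returns the trained codebook and the per-epoch mean quantization error
// (distance of each presented vector to its BMU, before the update).
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix codebook, NumericMatrix data,
                   IntegerVector order, NumericVector alphas,
                   NumericVector radii, NumericMatrix unit_dist,
                   int epochs, bool gaussian) {
  const int M = codebook.nrow(), D = codebook.ncol(), n = data.nrow();
  const int total = order.size();
  if (total != epochs * n) stop("order length must equal epochs * n");
  NumericMatrix W = clone(codebook);
  NumericVector qe(epochs);
  std::vector<double> x(D);
  for (int t = 0; t < total; ++t) {
    const int row = order[t];
    for (int j = 0; j < D; ++j) x[j] = data(row, j);
    // BMU: minimum squared Euclidean distance, ties -> lowest unit index
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < M; ++u) {
      double s = 0.0;
      for (int j = 0; j < D; ++j) {
        const double d = W(u, j) - x[j];
        s += d * d;
        if (s >= best) break;
      }
      if (s < best) { best = s; bmu = u; }
    }
    qe[t / n] += std::sqrt(best);
    const double alpha = alphas[t], radius = radii[t];
    if (alpha != 0.0) {
      for (int u = 0; u < M; ++u) {
        const double d = unit_dist(bmu, u);
        if (gaussian) {
          const double f = alpha * std::exp(-(d * d) / (2.0 * radius * radius));
          if (f > 1e-12)
            for (int j = 0; j < D; ++j) W(u, j) += f * (x[j] - W(u, j));
        } else if (d <= radius + 1e-12) {
          for (int j = 0; j < D; ++j) W(u, j) += alpha * (x[j] - W(u, j));
        }
      }
    }
  }
  for (int e = 0; e < epochs; ++e) qe[e] /= n;
  return List::create(_["codebook"] = W, _["epoch_qe"] = qe);
}

// BMU index (1-based) and quantization error per data vector.
// [[Rcpp::export]]
List som_bmu_cpp(NumericMatrix codebook, NumericMatrix data) {
  const int M = codebook.nrow(), D = codebook.ncol(), n = data.nrow();
  if (data.ncol() != D) stop("dimension mismatch between data and codebook");
  IntegerVector bmu(n);
  NumericVector err(n);
  for (int i = 0; i < n; ++i) {
    int best_u = 0;
    double best = R_PosInf;
    for (int u = 0; u < M; ++u) {
      double s = 0.0;
      for (int j = 0; j < D; ++j) {
        const double d = codebook(u, j) - data(i, j);
        s += d * d;
        if (s >= best) break;
      }
      if (s < best) { best = s; best_u = u; }
    }
    bmu[i] = best_u + 1;
    err[i] = std::sqrt(best);
  }
  return List::create(_["bmu"] = bmu, _["qe"] = err);
}
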