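#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the pairwise imaginary cross-spectrum statistics needed for
// the weighted phase lag index: for every channel pair (i, j) and pooled
// sample t, Im S_ij(t) = im_i re_j - re_i im_j. Returns the pooled sums of
// Im S and |Im S| as channels x channels matrices (antisymmetric /
// symmetric respectively in exact arithmetic; only i < j is computed).
// [[Rcpp::export]]
List wpli_accumulate(NumericMatrix re, NumericMatrix im) {
  const int C = re.nrow();
  const int N = re.ncol();
  NumericMatrix sum_im(C, C), sum_abs(C, C);
  for (int i = 0; i < C; ++i) {
    for (int j = i + 1; j < C; ++j) {
      double s = 0.0, sa = 0.0;
      for (int t = 0; t < N; ++t) {
        const double v = im(i, t) * re(j, t) - re(i, t) * im(j, t);
        s += v;
        sa += std::fabs(v);
      }
      sum_im(i, j) = s;
      sum_im(j, i) = -s;
      sum_abs(i, j) = sa;
      sum_abs(j, i) = sa;
    }
  }
  return List::create(_["sum_im"] = sum_im, _["sum_abs"] = sum_abs);
}

// Per-row max, min and max-absolute value of a matrix (hot path of the
// artefact-rejection scoring).
// [[Rcpp::export]]
List row_range_stats(NumericMatrix x) {
  const int R = x.nrow(), N = x.ncol();
  NumericVector mx(R, R_NegInf), mn(R, R_PosInf);
  for (int t = 0; t < N; ++t) {
    for (int r = 0; r < R; ++r) {
      const double v = x(r, t);
      if (v > mx[r]) mx[r] = v;
      if (v < mn[r]) mn[r] = v;
    }
  }
  NumericVector ab(R);
  for (int r = 0; r < R; ++r) ab[r] = std::max(std::fabs(mx[r]), std::fabs(mn[r]));
  return List::create(_["max"] = mx, _["min"] = mn, _["absmax"] = ab);
}

// Surrogate wPLI distribution: for each surrogate, every channel's pooled
// analytic samples are independently circularly shifted within each epoch
// (shift table `shifts` is channels x (n_epochs * n_surrogates), drawn in
// R for reproducibility) and the wPLI recomputed. Returns a channels x
// channels x n_surrogates array of surrogate wPLI values.
// [[Rcpp::export]]
NumericVector wpli_surrogates(NumericMatrix re, NumericMatrix im,
                              int npe, int nep, IntegerMatrix shifts,
                              int nsur) {
  const int C = re.nrow();
  NumericVector out(C * C * nsur);
  std::vector<int> si(npe), sj(npe);
  for (int s = 0; s < nsur; ++s) {
    double* slab = out.begin() + static_cast<size_t>(s) * C * C;
    for (int i = 0; i < C; ++i) {
      for (int j = i + 1; j < C; ++j) {
        double acc = 0.0, accabs = 0.0;
        for (int e = 0; e < nep; ++e) {
          const int base = e * npe;
          const int ki = shifts(i, s * nep + e);
          const int kj = shifts(j, s * nep + e);
          for (int t = 0; t < npe; ++t) {
            const int ti = base + (t + ki) % npe;
            const int tj = base + (t + kj) % npe;
            const double v = im(i, ti) * re(j, tj) - re(i, ti) * im(j, tj);
            acc += v;
            accabs += std::fabs(v);
          }
        }
        const double w = accabs > 1e-300 ? std::fabs(acc) / accabs : 0.0;
        slab[i + C * j] = w;
        slab[j + C * i] = w;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, C, nsur);
  return out;
}

// Pairwise histogram mutual information in bits from precomputed bin
// indices (channels x samples, values in 0..n_bins-1). Channels flagged
// false in `ok` (zero amplitude range) contribute 0. Returns the MI
// matrix with the per-channel marginal entropies on the diagonal.
// [[Rcpp::export]]
NumericMatrix mi_accumulate(IntegerMatrix bin, int n_bins, LogicalVector ok) {
  const int C = bin.nrow();
  const int N = bin.ncol();
  const double log2e = 1.0 / std::log(2.0);
  std::vector<std::vector<int>> marg(C, std::vector<int>(n_bins, 0));
  NumericVector H(C);
  for (int i = 0; i < C; ++i) {
    if (!ok[i]) continue;
    for (int t = 0; t < N; ++t) ++marg[i][bin(i, t)];
    double h = 0.0;
    for (int b = 0; b < n_bins; ++b) {
      if (marg[i][b] > 0) {
        const double p = static_cast<double>(marg[i][b]) / N;
        h -= p * std::log(p);
      }
    }
    H[i] = h * log2e;
  }
  NumericMatrix mi(C, C);
  std::vector<int> joint(n_bins * n_bins);
  for (int i = 0; i < C; ++i) {
    mi(i, i) = H[i];
    if (!ok[i]) continue;
    for (int j = i + 1; j < C; ++j) {
      if (!ok[j]) continue;
      std::fill(joint.begin(), joint.end(), 0);
      for (int t = 0; t < N; ++t) ++joint[bin(i, t) * n_bins + bin(j, t)];
      double hj = 0.0;
      for (size_t b = 0; b < joint.size(); ++b) {
        if (joint[b] > 0) {
          const double p = static_cast<double>(joint[b]) / N;
          hj -= p * std::log(p);
        }
      }
      double v = H[i] + H[j] - hj * log2e;
      if (v < 0.0) v = 0.0;
      mi(i, j) = v;
      mi(j, i) = v;
    }
  }
  return mi;
}
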