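// Structural gather/scatter kernels behind the autodiff primitives.
//
// im2col_gather assembles 3x3x3 convolution patch matrices from an index
// table (one 1-based source row per output voxel and tap; 0 selects an
// implicit zero row, implementing zero padding).  col2im_scatter is its
// exact adjoint.  row_gather / row_scatter are the single-tap versions used
// for up/downsampling, per-sample pooling and broadcasting.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_gather(const NumericMatrix& x, const IntegerVector& idx,
                            int vo, int taps) {
  const int cin = x.ncol();
  const int n = x.nrow();
  NumericMatrix out(vo, taps * cin);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int t = 0; t < taps; ++t) {
    const int* id = &idx[(size_t)t * vo];
    for (int c = 0; c < cin; ++c) {
      const double* xc = xp + (size_t)c * n;
      double* oc = op + ((size_t)t * cin + c) * vo;
      for (int i = 0; i < vo; ++i) {
        const int s = id[i];
        oc[i] = s > 0 ? xc[s - 1] : 0.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_scatter(const NumericMatrix& g, const IntegerVector& idx,
                             int n_out, int taps) {
  const int vo = g.nrow();
  const int cin = g.ncol() / taps;
  NumericMatrix out(n_out, cin);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int t = 0; t < taps; ++t) {
    const int* id = &idx[(size_t)t * vo];
    for (int c = 0; c < cin; ++c) {
      const double* gc = gp + ((size_t)t * cin + c) * vo;
      double* oc = op + (size_t)c * n_out;
      for (int i = 0; i < vo; ++i) {
        const int s = id[i];
        if (s > 0) oc[s - 1] += gc[i];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix row_gather(const NumericMatrix& x, const IntegerVector& idx) {
  const int n = x.nrow(), p = x.ncol(), m = idx.size();
  NumericMatrix out(m, p);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < p; ++c) {
    const double* xc = xp + (size_t)c * n;
    double* oc = op + (size_t)c * m;
    for (int i = 0; i < m; ++i) {
      const int s = idx[i];
      oc[i] = s > 0 ? xc[s - 1] : 0.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix row_scatter(const NumericMatrix& g, const IntegerVector& idx,
                          int n_out) {
  const int m = g.nrow(), p = g.ncol();
  NumericMatrix out(n_out, p);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int c = 0; c < p; ++c) {
    const double* gc = gp + (size_t)c * m;
    double* oc = op + (size_t)c * n_out;
    for (int i = 0; i < m; ++i) {
      const int s = idx[i];
      if (s > 0) oc[s - 1] += gc[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix add_rowvec_cpp(const NumericMatrix& x, const NumericVector& b) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < p; ++c) {
    const double bc = b[c];
    const double* xc = xp + (size_t)c * n;
    double* oc = op + (size_t)c * n;
    for (int i = 0; i < n; ++i) oc[i] = xc[i] + bc;
  }
  return out;
}

// [[Rcpp::export]]
List lrelu_cpp(const NumericMatrix& x, double slope) {
  const size_t n = (size_t)x.nrow() * x.ncol();
  NumericMatrix val(x.nrow(), x.ncol()), mask(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* vp = val.begin();
  double* mp = mask.begin();
  for (size_t i = 0; i < n; ++i) {
    const double m = xp[i] > 0 ? 1.0 : slope;
    mp[i] = m;
    vp[i] = xp[i] * m;
  }
  return List::create(_["val"] = val, _["mask"] = mask);
}

// elementwise a*b + c (equal shapes)
// [[Rcpp::export]]
NumericMatrix fma_cpp(const NumericMatrix& a, const NumericMatrix& b,
                      const NumericMatrix& c) {
  const size_t n = (size_t)a.nrow() * a.ncol();
  NumericMatrix out(a.nrow(), a.ncol());
  const double *ap = a.begin(), *bp = b.begin(), *cp = c.begin();
  double* op = out.begin();
  for (size_t i = 0; i < n; ++i) op[i] = ap[i] * bp[i] + cp[i];
  return out;
}

// instance normalization over contiguous per-(sample,channel) groups of V
// rows; returns the normalized field and 1/sqrt(var + eps) per group
// [[Rcpp::export]]
List inorm_fwd_cpp(const NumericMatrix& x, int V, int B, double eps) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix xhat(n, p), inv(B, p);
  for (int c = 0; c < p; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* hc = xhat.begin() + (size_t)c * n;
    for (int b = 0; b < B; ++b) {
      const double* xb = xc + (size_t)b * V;
      double* hb = hc + (size_t)b * V;
      double mu = 0;
      for (int i = 0; i < V; ++i) mu += xb[i];
      mu /= V;
      double var = 0;
      for (int i = 0; i < V; ++i) { const double d = xb[i] - mu; var += d * d; }
      var /= V;
      const double s = 1.0 / std::sqrt(var + eps);
      inv(b, c) = s;
      for (int i = 0; i < V; ++i) hb[i] = (xb[i] - mu) * s;
    }
  }
  return List::create(_["xhat"] = xhat, _["inv"] = inv);
}

// adjoint: gx = inv * (g - mean(g) - xhat * mean(g * xhat)) per group
// [[Rcpp::export]]
NumericMatrix inorm_bwd_cpp(const NumericMatrix& g, const NumericMatrix& xhat,
                            const NumericMatrix& inv, int V, int B) {
  const int n = g.nrow(), p = g.ncol();
  NumericMatrix out(n, p);
  for (int c = 0; c < p; ++c) {
    const double* gc = g.begin() + (size_t)c * n;
    const double* hc = xhat.begin() + (size_t)c * n;
    double* oc = out.begin() + (size_t)c * n;
    for (int b = 0; b < B; ++b) {
      const double* gb = gc + (size_t)b * V;
      const double* hb = hc + (size_t)b * V;
      double* ob = oc + (size_t)b * V;
      double gbar = 0, m2 = 0;
      for (int i = 0; i < V; ++i) { gbar += gb[i]; m2 += gb[i] * hb[i]; }
      gbar /= V; m2 /= V;
      const double s = inv(b, c);
      for (int i = 0; i < V; ++i) ob[i] = s * (gb[i] - gbar - hb[i] * m2);
    }
  }
  return out;
}
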