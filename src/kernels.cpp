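#include <Rcpp.h>
using namespace Rcpp;

// Per-edge inner products: out[e] = <X[ix[e], ], Y[iy[e], ]>.
// [[Rcpp::export(name = ".edgeDot")]]
NumericVector edge_dot(const NumericMatrix& X, const NumericMatrix& Y,
                       const IntegerVector& ix, const IntegerVector& iy) {
  const int E = ix.size(), d = X.ncol(), xn = X.nrow(), yn = Y.nrow();
  NumericVector out(E);
  const double* xp = REAL(X);
  const double* yp = REAL(Y);
  const int* ip = INTEGER(ix);
  const int* jp = INTEGER(iy);
  double* op = REAL(out);
  for (int j = 0; j < d; ++j) {
    const double* xc = xp + (size_t)j * xn;
    const double* yc = yp + (size_t)j * yn;
    for (int e = 0; e < E; ++e) op[e] += xc[ip[e] - 1] * yc[jp[e] - 1];
  }
  return out;
}

// Weighted gather-scatter: out[to[e], ] += w[e] * X[from[e], ], out is n x d.
// [[Rcpp::export(name = ".scatterAddGather")]]
NumericMatrix scatter_add_gather(const NumericMatrix& X,
                                 const IntegerVector& from,
                                 const IntegerVector& to,
                                 const NumericVector& w, int n) {
  const int E = from.size(), d = X.ncol(), xn = X.nrow();
  NumericMatrix out(n, d);
  const double* xp = REAL(X);
  const int* fp = INTEGER(from);
  const int* tp = INTEGER(to);
  const double* wp = REAL(w);
  double* op = REAL(out);
  for (int j = 0; j < d; ++j) {
    const double* xc = xp + (size_t)j * xn;
    double* oc = op + (size_t)j * n;
    for (int e = 0; e < E; ++e) oc[tp[e] - 1] += wp[e] * xc[fp[e] - 1];
  }
  return out;
}

// [[Rcpp::export(name = ".groupMax")]]
NumericVector group_max(const NumericVector& x, const IntegerVector& g,
                        int ng) {
  NumericVector out(ng, R_NegInf);
  const double* xp = REAL(x);
  const int* gp = INTEGER(g);
  double* op = REAL(out);
  const int E = x.size();
  for (int e = 0; e < E; ++e) {
    const int k = gp[e] - 1;
    if (xp[e] > op[k]) op[k] = xp[e];
  }
  return out;
}

// [[Rcpp::export(name = ".groupSum")]]
NumericVector group_sum(const NumericVector& x, const IntegerVector& g,
                        int ng) {
  NumericVector out(ng);
  const double* xp = REAL(x);
  const int* gp = INTEGER(g);
  double* op = REAL(out);
  const int E = x.size();
  for (int e = 0; e < E; ++e) op[gp[e] - 1] += xp[e];
  return out;
}
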