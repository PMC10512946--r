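// Temporal convolution and pooling primitives for the inception-block
// regressor.  Activations for a batch of windows are stored as a single
// (n_win * win_len) x n_channels matrix, window-major: window w occupies
// rows [w*win_len, (w+1)*win_len).  Convolutions use stride 1 and "same"
// zero padding (left pad = (k-1)/2), so the temporal length never changes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the im2col matrix: row (w*T + t), column block j holds the input at
// time t + j - left of window w (zero outside the window).
static mat im2col(const mat& X, int k, int n_win, int T) {
  const int cin = X.n_cols;
  mat IC(X.n_rows, (uword)k * cin, fill::zeros);
  const int left = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int o = j - left;               // source offset: t + o
    const int len = T - std::abs(o);
    if (len <= 0) continue;
    const int t0 = std::max(0, -o);       // first valid output time
    const int s0 = std::max(0, o);        // first source time
    for (int w = 0; w < n_win; ++w) {
      IC.submat(w * T + t0, (uword)j * cin,
                w * T + t0 + len - 1, (uword)(j + 1) * cin - 1) =
        X.rows(w * T + s0, w * T + s0 + len - 1);
    }
  }
  return IC;
}

// Flatten a (k x cin x cout) weight cube to (k*cin) x cout matching im2col
// column order (tap-major, channel within tap).
static mat flatten_w(const cube& W) {
  const int k = W.n_rows, cin = W.n_cols, cout = W.n_slices;
  mat Wm((uword)k * cin, cout);
  for (int s = 0; s < cout; ++s) {
    const mat& sl = W.slice(s);
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < cin; ++c)
        Wm((uword)j * cin + c, s) = sl(j, c);
  }
  return Wm;
}

// [[Rcpp::export]]
arma::mat conv1d_forward(const arma::mat& X, const arma::cube& W,
                         int n_win, int win_len) {
  const int k = W.n_rows;
  if ((int)X.n_cols != (int)W.n_cols)
    Rcpp::stop("conv1d_forward: input has %d channels, weights expect %d",
               (int)X.n_cols, (int)W.n_cols);
  if ((int)X.n_rows != n_win * win_len)
    Rcpp::stop("conv1d_forward: nrow(X) != n_win * win_len");
  if (k == 1) {                           // pointwise: plain matrix product
    return X * flatten_w(W);
  }
  return im2col(X, k, n_win, win_len) * flatten_w(W);
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::mat& X, const arma::cube& W,
                           const arma::mat& dY, int n_win, int win_len,
                           bool want_dx) {
  const int k = W.n_rows, cin = W.n_cols, cout = W.n_slices;
  if ((int)dY.n_rows != (int)X.n_rows || (int)dY.n_cols != cout)
    Rcpp::stop("conv1d_backward: gradient shape mismatch");
  mat Wm = flatten_w(W);
  mat dWm;
  mat dX;
  if (k == 1) {
    dWm = X.t() * dY;
    if (want_dx) dX = dY * Wm.t();
  } else {
    mat IC = im2col(X, k, n_win, win_len);
    dWm = IC.t() * dY;
    if (want_dx) {
      mat dIC = dY * Wm.t();              // (n_win*T) x (k*cin)
      dX.zeros(X.n_rows, cin);
      const int left = (k - 1) / 2;
      for (int j = 0; j < k; ++j) {       // scatter-add (col2im)
        const int o = j - left;
        const int len = win_len - std::abs(o);
        if (len <= 0) continue;
        const int t0 = std::max(0, -o);
        const int s0 = std::max(0, o);
        for (int w = 0; w < n_win; ++w) {
          dX.rows(w * win_len + s0, w * win_len + s0 + len - 1) +=
            dIC.submat(w * win_len + t0, (uword)j * cin,
                       w * win_len + t0 + len - 1, (uword)(j + 1) * cin - 1);
        }
      }
    }
  }
  cube dW(k, cin, cout);
  for (int s = 0; s < cout; ++s)
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < cin; ++c)
        dW(j, c, s) = dWm((uword)j * cin + c, s);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dX);
}

// Max pooling, width 3, stride 1, same padding.  Returns the pooled matrix
// and the chosen source offset (-1, 0, +1) for gradient routing.
// [[Rcpp::export]]
Rcpp::List maxpool3_forward(const arma::mat& X, int n_win, int win_len) {
  const int C = X.n_cols;
  mat Y(X.n_rows, C);
  imat A(X.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    arma::sword* ac = A.colptr(c);
    for (int w = 0; w < n_win; ++w) {
      const int base = w * win_len;
      for (int t = 0; t < win_len; ++t) {
        double best = xc[base + t];
        int arg = 0;
        if (t > 0 && xc[base + t - 1] > best) { best = xc[base + t - 1]; arg = -1; }
        if (t < win_len - 1 && xc[base + t + 1] > best) { best = xc[base + t + 1]; arg = 1; }
        yc[base + t] = best;
        ac[base + t] = arg;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("arg") = A);
}

// [[Rcpp::export]]
arma::mat maxpool3_backward(const arma::mat& dY, const arma::imat& A,
                            int n_win, int win_len) {
  mat dX(dY.n_rows, dY.n_cols, fill::zeros);
  const int C = dY.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* dyc = dY.colptr(c);
    const arma::sword* ac = A.colptr(c);
    double* dxc = dX.colptr(c);
    for (int w = 0; w < n_win; ++w) {
      const int base = w * win_len;
      for (int t = 0; t < win_len; ++t)
        dxc[base + t + ac[base + t]] += dyc[base + t];
    }
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat relu_forward(const arma::mat& X) {
  mat Y = X;
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

// Gradient through a rectifier given its *output* (positive where active).
// [[Rcpp::export]]
arma::mat relu_backward(const arma::mat& dY, const arma::mat& Y) {
  mat dX = dY;
  const uword n = dX.n_elem;
  const double* y = Y.memptr();
  double* d = dX.memptr();
  for (uword i = 0; i < n; ++i) if (y[i] <= 0) d[i] = 0;
  return dX;
}

// Batch normalisation over rows (batch*time) per column (channel).
// [[Rcpp::export]]
Rcpp::List bn_train_forward(const arma::mat& X, const arma::vec& gamma,
                            const arma::vec& beta, double eps) {
  const uword n = X.n_rows, C = X.n_cols;
  mat xhat(n, C), Y(n, C);
  vec mu(C), v(C), inv(C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double m = 0;
    for (uword i = 0; i < n; ++i) m += x[i];
    m /= n;
    double s = 0;
    for (uword i = 0; i < n; ++i) { const double d = x[i] - m; s += d * d; }
    s /= n;
    const double iv = 1.0 / std::sqrt(s + eps);
    mu(c) = m; v(c) = s; inv(c) = iv;
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    const double g = gamma(c), b = beta(c);
    for (uword i = 0; i < n; ++i) {
      xh[i] = (x[i] - m) * iv;
      y[i] = xh[i] * g + b;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv, Rcpp::Named("mu") = mu,
                            Rcpp::Named("v") = v);
}

// [[Rcpp::export]]
arma::mat bn_infer_forward(const arma::mat& X, const arma::vec& mean,
                           const arma::vec& var, const arma::vec& gamma,
                           const arma::vec& beta, double eps) {
  const uword n = X.n_rows, C = X.n_cols;
  mat Y(n, C);
  for (uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    const double a = gamma(c) / std::sqrt(var(c) + eps);
    const double b = beta(c) - mean(c) * a;
    for (uword i = 0; i < n; ++i) y[i] = x[i] * a + b;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List bn_train_backward(const arma::mat& dY, const arma::mat& xhat,
                             const arma::vec& inv, const arma::vec& gamma) {
  const uword n = dY.n_rows, C = dY.n_cols;
  mat dX(n, C);
  vec dgamma(C), dbeta(C);
  for (uword c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    double sg = 0, sb = 0;
    for (uword i = 0; i < n; ++i) { sg += dy[i] * xh[i]; sb += dy[i]; }
    dgamma(c) = sg; dbeta(c) = sb;
    const double g = gamma(c), iv = inv(c);
    const double m1 = g * sb / n, m2 = g * sg / n;
    double* dx = dX.colptr(c);
    for (uword i = 0; i < n; ++i)
      dx[i] = (dy[i] * g - m1 - xh[i] * m2) * iv;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
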