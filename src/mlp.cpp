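// Small fully connected feed-forward network (input -> h1 -> h2 -> 1) with
// logistic activations throughout, trained by full-batch Adam on the
// cross-entropy loss with an L2 penalty.  The network is deliberately tiny
// (default 10 and 2 hidden nodes) and refit thousands of times across
// resamples, which is why the training loop lives in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct AdamState {
  mat m, v;
  AdamState(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double b1, double b2,
            double eps, int t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * (g % g);
    mat mh = m / (1.0 - std::pow(b1, t));
    mat vh = v / (1.0 - std::pow(b2, t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
};

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                         arma::mat W1, arma::rowvec b1,
                         arma::mat W2, arma::rowvec b2,
                         arma::vec w3, double b3,
                         int max_iter, double lr, double tol, double l2) {
  const uword n = X.n_rows;
  AdamState sW1(W1.n_rows, W1.n_cols), sb1(1, b1.n_cols);
  AdamState sW2(W2.n_rows, W2.n_cols), sb2(1, b2.n_cols);
  AdamState sw3(w3.n_rows, 1), sb3(1, 1);
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  bool converged = false;
  double loss = datum::nan;
  int iter = 0;
  mat b3m(1, 1);
  b3m(0, 0) = b3;

  for (iter = 1; iter <= max_iter; ++iter) {
    mat A1 = sigm(X * W1 + repmat(b1, n, 1));
    mat A2 = sigm(A1 * W2 + repmat(b2, n, 1));
    vec p = sigm(A2 * w3 + b3m(0, 0)).col(0);
    p = clamp(p, 1e-12, 1.0 - 1e-12);
    loss = -mean(y % log(p) + (1.0 - y) % log(1.0 - p)) +
           0.5 * l2 * (accu(square(W1)) + accu(square(W2)) + accu(square(w3)));

    vec d3 = (p - y) / double(n);
    vec gw3 = A2.t() * d3 + l2 * w3;
    double gb3 = accu(d3);
    mat d2 = (d3 * w3.t()) % A2 % (1.0 - A2);
    mat gW2 = A1.t() * d2 + l2 * W2;
    rowvec gb2 = sum(d2, 0);
    mat d1 = (d2 * W2.t()) % A1 % (1.0 - A1);
    mat gW1 = X.t() * d1 + l2 * W1;
    rowvec gb1 = sum(d1, 0);

    double gmax = std::max({gW1.max(), (-gW1).max(), gW2.max(), (-gW2).max(),
                            gw3.max(), (-gw3).max(),
                            gb1.max(), (-gb1).max(), gb2.max(), (-gb2).max(),
                            std::abs(gb3)});
    if (gmax < tol) {
      converged = true;
      break;
    }
    mat gb1m = gb1, gb2m = gb2, gb3m(1, 1);
    gb3m(0, 0) = gb3;
    mat b1m = b1, b2m = b2;
    sW1.step(W1, gW1, lr, beta1, beta2, eps, iter);
    sb1.step(b1m, gb1m, lr, beta1, beta2, eps, iter);
    sW2.step(W2, gW2, lr, beta1, beta2, eps, iter);
    sb2.step(b2m, gb2m, lr, beta1, beta2, eps, iter);
    mat w3m = w3;
    sw3.step(w3m, gw3, lr, beta1, beta2, eps, iter);
    sb3.step(b3m, gb3m, lr, beta1, beta2, eps, iter);
    b1 = b1m.row(0);
    b2 = b2m.row(0);
    w3 = w3m.col(0);
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
      Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
      Rcpp::Named("w3") = w3, Rcpp::Named("b3") = b3m(0, 0),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("loss") = loss);
}

// [[Rcpp::export]]
arma::vec mlp_forward_cpp(const arma::mat& X,
                          const arma::mat& W1, const arma::rowvec& b1,
                          const arma::mat& W2, const arma::rowvec& b2,
                          const arma::vec& w3, double b3) {
  const uword n = X.n_rows;
  mat A1 = sigm(X * W1 + repmat(b1, n, 1));
  mat A2 = sigm(A1 * W2 + repmat(b2, n, 1));
  return sigm(A2 * w3 + b3).col(0);
}
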