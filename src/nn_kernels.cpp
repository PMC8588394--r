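// Batched recurrent-cell kernels (LSTM and simple/dilated RNN).
//
// Time loops over gate algebra dominate the training cost of the recurrent
// architectures; they are implemented here so that R keeps only the graph
// bookkeeping. Sequence tensors cross the boundary as (batch, features,
// time) cubes so each time step is a contiguous batch x features matrix.
// Gate order in the packed weight matrices: input, forget, candidate,
// output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

static inline mat act_f(const mat& z, bool relu) {
  if (relu) return clamp(z, 0.0, datum::inf);
  return tanh(z);
}

// derivative in terms of the activation output
static inline mat act_df(const mat& y, bool relu) {
  if (relu) return conv_to<mat>::from(y > 0);
  return 1.0 - square(y);
}

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
Rcpp::List lstm_forward_cpp(const arma::cube& x, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            bool relu, bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  cube I(B, H, T), Fg(B, H, T), G(B, H, T), O(B, H, T);
  cube C(B, H, T), Hc(B, H, T), Hs(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat z = x.slice(t) * W + h * U;
    z.each_row() += br;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = act_f(z.cols(2 * H, 3 * H - 1), relu);
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat hc = act_f(c, relu);
    h = o % hc;
    I.slice(t) = i; Fg.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
    C.slice(t) = c; Hc.slice(t) = hc; Hs.slice(t) = h;
  }
  return Rcpp::List::create(
      Rcpp::Named("out_last") = h, Rcpp::Named("I") = I,
      Rcpp::Named("Fg") = Fg, Rcpp::Named("G") = G, Rcpp::Named("O") = O,
      Rcpp::Named("C") = C, Rcpp::Named("Hc") = Hc, Rcpp::Named("Hs") = Hs);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
Rcpp::List lstm_backward_cpp(const arma::cube& x, const arma::mat& W,
                             const arma::mat& U, const arma::cube& I,
                             const arma::cube& Fg, const arma::cube& G,
                             const arma::cube& O, const arma::cube& C,
                             const arma::cube& Hc, const arma::cube& Hs,
                             const arma::cube& dout_seq,
                             const arma::mat& dout_last, bool relu,
                             bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  cube dx(B, x.n_cols, T, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros), dU(U.n_rows, U.n_cols, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = dh_next;
    if (return_seq) dh += dout_seq.slice(t);
    else if (t == T - 1) dh += dout_last;
    const mat& i = I.slice(t); const mat& f = Fg.slice(t);
    const mat& g = G.slice(t); const mat& o = O.slice(t);
    const mat& hc = Hc.slice(t);
    mat c_prev = (t > 0) ? C.slice(t - 1) : mat(B, H, fill::zeros);
    mat h_prev = (t > 0) ? Hs.slice(t - 1) : mat(B, H, fill::zeros);
    mat dc = dc_next + dh % o % act_df(hc, relu);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = dc % g % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = dc % c_prev % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dc % i % act_df(g, relu);
    dz.cols(3 * H, 4 * H - 1) = dh % hc % o % (1.0 - o);
    dW += x.slice(t).t() * dz;
    dU += h_prev.t() * dz;
    db += sum(dz, 0);
    dh_next = dz * U.t();
    dc_next = dc % f;
    dx.slice(t) = dz * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = db.t());
}

// [[Rcpp::export(name = ".rnn_forward_cpp")]]
Rcpp::List rnn_forward_cpp(const arma::cube& x, const arma::mat& W,
                           const arma::mat& U, const arma::vec& b,
                           int dilation, bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  const uword d = (uword)dilation;
  cube Hs(B, H, T);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat z = x.slice(t) * W;
    z.each_row() += br;
    if (t >= d) z += Hs.slice(t - d) * U;
    Hs.slice(t) = act_f(z, false);
  }
  return Rcpp::List::create(Rcpp::Named("out_last") = Hs.slice(T - 1),
                            Rcpp::Named("Hs") = Hs);
}

// [[Rcpp::export(name = ".rnn_backward_cpp")]]
Rcpp::List rnn_backward_cpp(const arma::cube& x, const arma::mat& W,
                            const arma::mat& U, const arma::cube& Hs,
                            const arma::cube& dout_seq,
                            const arma::mat& dout_last, int dilation,
                            bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  const uword d = (uword)dilation;
  cube dH(B, H, T, fill::zeros);
  if (return_seq) dH = dout_seq;
  else dH.slice(T - 1) = dout_last;
  cube dx(B, x.n_cols, T, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros), dU(U.n_rows, U.n_cols, fill::zeros);
  rowvec db(H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dz = dH.slice(t) % act_df(Hs.slice(t), false);
    dW += x.slice(t).t() * dz;
    db += sum(dz, 0);
    if (t >= d) {
      dU += Hs.slice(t - d).t() * dz;
      dH.slice(t - d) += dz * U.t();
    }
    dx.slice(t) = dz * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU,
                            Rcpp::Named("db") = db.t());
}

// cache-free forward passes for inference

// [[Rcpp::export(name = ".lstm_infer_cpp")]]
Rcpp::List lstm_infer_cpp(const arma::cube& x, const arma::mat& W,
                          const arma::mat& U, const arma::vec& b,
                          bool relu, bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  cube Hs;
  if (return_seq) Hs.set_size(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat z = x.slice(t) * W + h * U;
    z.each_row() += br;
    mat i = sigm(z.cols(0, H - 1));
    mat f = sigm(z.cols(H, 2 * H - 1));
    mat g = act_f(z.cols(2 * H, 3 * H - 1), relu);
    mat o = sigm(z.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % act_f(c, relu);
    if (return_seq) Hs.slice(t) = h;
  }
  if (return_seq)
    return Rcpp::List::create(Rcpp::Named("Hs") = Hs);
  return Rcpp::List::create(Rcpp::Named("out_last") = h);
}

// [[Rcpp::export(name = ".rnn_infer_cpp")]]
Rcpp::List rnn_infer_cpp(const arma::cube& x, const arma::mat& W,
                         const arma::mat& U, const arma::vec& b,
                         int dilation, bool return_seq) {
  const uword B = x.n_rows, T = x.n_slices, H = U.n_rows;
  const uword d = (uword)dilation;
  cube Hs(B, H, T);
  rowvec br = b.t();
  for (uword t = 0; t < T; ++t) {
    mat z = x.slice(t) * W;
    z.each_row() += br;
    if (t >= d) z += Hs.slice(t - d) * U;
    Hs.slice(t) = act_f(z, false);
  }
  if (return_seq)
    return Rcpp::List::create(Rcpp::Named("Hs") = Hs);
  return Rcpp::List::create(Rcpp::Named("out_last") = Hs.slice(T - 1));
}
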