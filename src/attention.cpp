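// Batched multi-head self-attention kernels. The surrounding linear
// algebra (projections, layer norm, feed-forward) stays in R where BLAS
// already does the work; these kernels remove the per-item, per-head
// interpreter overhead of the softmax attention itself.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double MASK_NEG = -1e30;

// Q, K, V: (B*L) x d matrices, item-major rows. pad: length B*L, true at
// [PAD] positions (masked out as attention keys). Returns the attended
// output O (same shape) and the attention probabilities A as an
// L x L x (nh*B) cube (head-major within item).
// [[Rcpp::export(name = ".attn_forward")]]
Rcpp::List attn_forward(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V,
                        const Rcpp::LogicalVector& pad,
                        int B, int L, int nh) {
  const int d = Q.n_cols;
  const int dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat O(Q.n_rows, d, fill::zeros);
  cube A(L, L, (size_t)nh * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    uvec masked;
    {
      std::vector<unsigned int> mk;
      for (int j = 0; j < L; ++j) if (pad[r0 + j]) mk.push_back(j);
      masked = uvec(mk);
    }
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      mat Qh = Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      mat Kh = K.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      mat S = Qh * Kh.t() * scale;
      for (uword m = 0; m < masked.n_elem; ++m) {
        S.col(masked[m]).fill(MASK_NEG);
      }
      S.each_col() -= max(S, 1);
      S = exp(S);
      S.each_col() /= sum(S, 1);
      A.slice((size_t)b * nh + h) = S;
      O.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
        S * V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// Backward pass: dO is the gradient at the attended output; A, Q, K, V are
// the forward-pass values. Returns gradients with respect to Q, K, V.
// [[Rcpp::export(name = ".attn_backward")]]
Rcpp::List attn_backward(const arma::mat& dO, const arma::cube& A,
                         const arma::mat& Q, const arma::mat& K,
                         const arma::mat& V, int B, int L, int nh) {
  const int d = Q.n_cols;
  const int dk = d / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dQ(Q.n_rows, d, fill::zeros);
  mat dK(Q.n_rows, d, fill::zeros);
  mat dV(Q.n_rows, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * dk;
      const mat& Ah = A.slice((size_t)b * nh + h);
      mat dOh = dO.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      mat Vh = V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      mat dA = dOh * Vh.t();
      dV.submat(r0, c0, r0 + L - 1, c0 + dk - 1) = Ah.t() * dOh;
      // softmax Jacobian row-wise
      vec rs = sum(dA % Ah, 1);
      mat dS = Ah % (dA.each_col() - rs);
      dQ.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
        dS * K.submat(r0, c0, r0 + L - 1, c0 + dk - 1) * scale;
      dK.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
        dS.t() * Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ,
                            Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
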