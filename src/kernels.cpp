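// Hot loops for the codon-context classifier and the third-nucleotide
// shuffle. All randomness uses R's RNG stream (unif_rand), so results are
// fully governed by set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One epoch of mini-batch SGD on the two-layer softmax classifier.
// idx:  n x L integer matrix of codon labels in 0..64 (0 = null/mask);
//       label c selects row c of E (row 0 is the pinned null embedding).
// E:    65 x d embedding matrix; W: (L*d) x 2 output weights, no bias.
// y:    0/1 labels (1 = hit); ord: 0-based presentation order (defines the
//       epoch's mini-batches); loss is mean cross-entropy over the epoch.
// Row 0 of E receives no gradient (masking embedding stays at the origin).
// [[Rcpp::export]]
List cpp_sgd_epoch(arma::mat E, arma::mat W, const arma::imat& idx,
                   const arma::ivec& y, const arma::ivec& ord,
                   double lr, int batch) {
  const int n = ord.n_elem;
  const int L = idx.n_cols;
  const int d = E.n_cols;
  double loss = 0.0;
  arma::mat gW(W.n_rows, 2);
  arma::mat gE(E.n_rows, d);
  for (int b0 = 0; b0 < n; b0 += batch) {
    const int b1 = std::min(b0 + batch, n);
    const int B = b1 - b0;
    gW.zeros();
    gE.zeros();
    for (int bi = 0; bi < B; ++bi) {
      const int ex = ord[b0 + bi];
      double l0 = 0.0, l1 = 0.0;   // logits: col 0 = hit, col 1 = decoy
      for (int x = 0; x < L; ++x) {
        const int c = idx(ex, x);
        const int w0 = x * d;
        for (int j = 0; j < d; ++j) {
          const double e = E(c, j);
          l0 += e * W(w0 + j, 0);
          l1 += e * W(w0 + j, 1);
        }
      }
      const double m = std::max(l0, l1);
      const double z0 = std::exp(l0 - m), z1 = std::exp(l1 - m);
      const double p0 = z0 / (z0 + z1);
      const double yi = (double) y[ex];
      loss += -std::log(std::max(yi == 1.0 ? p0 : 1.0 - p0, 1e-300));
      const double g0 = p0 - yi;   // softmax + cross-entropy gradient
      const double g1 = -g0;
      for (int x = 0; x < L; ++x) {
        const int c = idx(ex, x);
        const int w0 = x * d;
        for (int j = 0; j < d; ++j) {
          const double e = E(c, j);
          gW(w0 + j, 0) += e * g0;
          gW(w0 + j, 1) += e * g1;
          gE(c, j) += W(w0 + j, 0) * g0 + W(w0 + j, 1) * g1;
        }
      }
    }
    gE.row(0).zeros();
    E -= (lr / B) * gE;
    W -= (lr / B) * gW;
  }
  return List::create(_["E"] = E, _["W"] = W, _["loss"] = loss / n);
}

// Forward pass: probability that each example is a hit.
// [[Rcpp::export]]
arma::vec cpp_forward(const arma::mat& E, const arma::mat& W,
                      const arma::imat& idx) {
  const int n = idx.n_rows;
  const int L = idx.n_cols;
  const int d = E.n_cols;
  arma::vec p(n);
  for (int ex = 0; ex < n; ++ex) {
    double l0 = 0.0, l1 = 0.0;
    for (int x = 0; x < L; ++x) {
      const int c = idx(ex, x);
      const int w0 = x * d;
      for (int j = 0; j < d; ++j) {
        const double e = E(c, j);
        l0 += e * W(w0 + j, 0);
        l1 += e * W(w0 + j, 1);
      }
    }
    p[ex] = 1.0 / (1.0 + std::exp(l1 - l0));
  }
  return p;
}

// Third-nucleotide shuffle: rejection Markov chain of random pairwise swaps
// of third codon positions within each example (row). A swap is accepted iff
// both resulting codons encode their original amino acids. Codon indices are
// lexicographic 1..64 over {A,C,G,T}^3, so the third nucleotide of codon i
// is (i-1) % 4 and replacing it is index arithmetic.
// aa: length-64 integer amino-acid code per codon index.
// [[Rcpp::export]]
IntegerMatrix cpp_third_nt_shuffle(const IntegerMatrix& idx,
                                   const IntegerVector& aa,
                                   int proposalsPerSite) {
  const int n = idx.nrow();
  const int L = idx.ncol();
  IntegerMatrix out = clone(idx);
  const int nprop = proposalsPerSite * L;
  for (int r = 0; r < n; ++r) {
    for (int t = 0; t < nprop; ++t) {
      const int i = (int) (unif_rand() * L);
      const int j = (int) (unif_rand() * L);
      if (i == j) continue;
      const int ci = out(r, i), cj = out(r, j);
      const int ni = (ci - 1) % 4, nj = (cj - 1) % 4;
      if (ni == nj) continue;
      const int ci2 = ci - ni + nj, cj2 = cj - nj + ni;
      if (aa[ci2 - 1] == aa[ci - 1] && aa[cj2 - 1] == aa[cj - 1]) {
        out(r, i) = ci2;
        out(r, j) = cj2;
      }
    }
  }
  return out;
}
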