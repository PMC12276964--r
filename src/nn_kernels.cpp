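// Fused forward/backward kernel for the locations branch, the spatial-score
// combiner and the final dense stack. Mirrors the R reference
// implementations (loc_forward / combiner_forward / *_backward) exactly;
// the R paths remain the oracle in tests, this path serves the training
// loop where the large w^2*k element-wise tensors dominate runtime.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat relu(const arma::mat& z) {
  return arma::clamp(z, 0.0, arma::datum::inf);
}

// [[Rcpp::export(name = ".comb_fused")]]
List comb_fused(const arma::mat& tab, const arma::mat& G,
                const arma::mat& target, const arma::uvec& keep,
                const arma::mat& loc1_w, const arma::rowvec& loc1_b,
                const arma::mat& loc2_w, const arma::rowvec& loc2_b,
                const arma::mat& comb_w, const arma::rowvec& comb_b,
                const arma::mat& f1_w, const arma::rowvec& f1_b,
                const arma::mat& f2_w, const arma::rowvec& f2_b,
                int w, bool want_grads) {
  const int k = G.n_rows;
  const int w2 = w * w;

  // locations branch
  arma::mat Z1 = tab * loc1_w; Z1.each_row() += loc1_b;
  arma::mat H1 = relu(Z1);
  arma::mat Z2 = H1 * loc2_w; Z2.each_row() += loc2_b;
  arma::mat S = relu(Z2);

  // combiner: element-wise product with G replicated per cell
  arma::mat TE(S.n_rows, S.n_cols);
  for (int i = 0; i < w2; ++i) {
    TE.rows((arma::uword)i * k, (arma::uword)(i + 1) * k - 1) =
      S.rows((arma::uword)i * k, (arma::uword)(i + 1) * k - 1) % G;
  }
  arma::mat Z = TE * comb_w; Z.each_row() += comb_b;
  arma::mat U = relu(Z);
  // pair aggregation normalized by k (matches the R reference path)
  arma::mat Csum(w2, U.n_cols);
  for (int i = 0; i < w2; ++i) {
    Csum.row(i) = arma::sum(U.rows((arma::uword)i * k,
                                   (arma::uword)(i + 1) * k - 1), 0) / k;
  }
  arma::mat Zf1 = Csum * f1_w; Zf1.each_row() += f1_b;
  arma::mat Hf1 = relu(Zf1);
  arma::mat Y = Hf1 * f2_w; Y.each_row() += f2_b;

  // masked MSE loss (Eq. 2 denominator: 2 * number of kept cells)
  arma::mat diff = Y - target;
  int nkeep = 0;
  for (int i = 0; i < w2; ++i) {
    if (keep[i]) nkeep++; else diff.row(i).zeros();
  }
  double loss = arma::accu(arma::square(diff)) / (2.0 * nkeep);

  if (!want_grads) {
    return List::create(_["loss"] = loss, _["Y"] = Y);
  }

  arma::mat dY = diff / nkeep;
  arma::mat g_f2_w = Hf1.t() * dY;
  arma::rowvec g_f2_b = arma::sum(dY, 0);
  arma::mat dHf1 = dY * f2_w.t();
  arma::mat dZf1 = dHf1; dZf1.elem(arma::find(Zf1 <= 0)).zeros();
  arma::mat g_f1_w = Csum.t() * dZf1;
  arma::rowvec g_f1_b = arma::sum(dZf1, 0);
  arma::mat dCsum = dZf1 * f1_w.t();

  arma::mat dZc(Z.n_rows, Z.n_cols);
  for (int i = 0; i < w2; ++i) {
    dZc.rows((arma::uword)i * k, (arma::uword)(i + 1) * k - 1) =
      arma::repmat(dCsum.row(i) / k, k, 1);
  }
  dZc.elem(arma::find(Z <= 0)).zeros();
  arma::mat g_comb_w = TE.t() * dZc;
  arma::rowvec g_comb_b = arma::sum(dZc, 0);
  arma::mat dTE = dZc * comb_w.t();

  arma::mat dS = dTE;
  arma::mat dG(k, G.n_cols, arma::fill::zeros);
  for (int i = 0; i < w2; ++i) {
    arma::uword a = (arma::uword)i * k, b = (arma::uword)(i + 1) * k - 1;
    dG += dTE.rows(a, b) % S.rows(a, b);
    dS.rows(a, b) %= G;
  }

  arma::mat dZ2 = dS; dZ2.elem(arma::find(Z2 <= 0)).zeros();
  arma::mat g_loc2_w = H1.t() * dZ2;
  arma::rowvec g_loc2_b = arma::sum(dZ2, 0);
  arma::mat dH1 = dZ2 * loc2_w.t();
  arma::mat dZ1 = dH1; dZ1.elem(arma::find(Z1 <= 0)).zeros();
  arma::mat g_loc1_w = tab.t() * dZ1;
  arma::rowvec g_loc1_b = arma::sum(dZ1, 0);

  return List::create(
    _["loss"] = loss, _["Y"] = Y, _["dG"] = dG,
    _["loc1_w"] = g_loc1_w, _["loc1_b"] = g_loc1_b,
    _["loc2_w"] = g_loc2_w, _["loc2_b"] = g_loc2_b,
    _["comb_w"] = g_comb_w, _["comb_b"] = g_comb_b,
    _["f1_w"] = g_f1_w, _["f1_b"] = g_f1_b,
    _["f2_w"] = g_f2_w, _["f2_b"] = g_f2_b);
}
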