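#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Regularized coordinate-descent (HALS) solver for X ~ W * H with
// W >= 0, H >= 0.  Minimizes
//   0.5*||X - W*H||_F^2 + alpha*l1*(sum|W| + sum|H|)
//     + alpha*(1-l1)*(sum(W^2) + sum(H^2)),
// which has the same minimizers as the half-scaled cost reported by
// nmfCost() (it is exactly twice that cost).  One iteration sweeps every
// row of H and every column of W; the sweep order and the deterministic
// initialization make the solver reproducible.  Convergence follows the
// usual coordinate-descent criterion: the sum of projected-gradient
// magnitudes accumulated over a sweep, relative to the first sweep,
// must drop below tol.
// [[Rcpp::export]]
Rcpp::List nmf_hals(const arma::mat& X, arma::mat W, arma::mat H,
                    double alpha, double l1, int maxIter, double tol) {
    if (!X.is_finite()) Rcpp::stop("non-finite input to the NMF solver");
    const double lam1 = alpha * l1;
    const double lam2 = 2.0 * alpha * (1.0 - l1);

    double v0 = -1.0;
    bool converged = false;
    int it = 0;
    for (it = 1; it <= maxIter; ++it) {
        double violation = 0.0;

        mat WtW = W.t() * W;
        mat WtX = W.t() * X;
        for (uword j = 0; j < H.n_rows; ++j) {
            double denom = WtW(j, j) + lam2;
            if (denom <= 0.0) continue;
            rowvec num = WtX.row(j) - WtW.row(j) * H
                         + WtW(j, j) * H.row(j) - lam1;
            rowvec g = denom * H.row(j) - num;
            for (uword t = 0; t < g.n_elem; ++t) {
                double pg = (H(j, t) > 0.0) ? g(t) : std::min(g(t), 0.0);
                violation += std::fabs(pg);
            }
            H.row(j) = clamp(num / denom, 0.0, datum::inf);
        }

        mat HHt = H * H.t();
        mat XHt = X * H.t();
        for (uword j = 0; j < W.n_cols; ++j) {
            double denom = HHt(j, j) + lam2;
            if (denom <= 0.0) continue;
            vec num = XHt.col(j) - W * HHt.col(j)
                      + HHt(j, j) * W.col(j) - lam1;
            vec g = denom * W.col(j) - num;
            for (uword i = 0; i < g.n_elem; ++i) {
                double pg = (W(i, j) > 0.0) ? g(i) : std::min(g(i), 0.0);
                violation += std::fabs(pg);
            }
            W.col(j) = clamp(num / denom, 0.0, datum::inf);
        }

        if (it == 1) {
            v0 = violation;
            if (v0 == 0.0) { converged = true; break; }
        } else if (violation / v0 < tol) {
            converged = true;
            break;
        }
    }
    if (it > maxIter) it = maxIter;
    double obj = 0.5 * accu(square(X - W * H))
        + lam1 * (accu(abs(W)) + accu(abs(H)))
        + 0.5 * lam2 * (accu(square(W)) + accu(square(H)));
    return Rcpp::List::create(Rcpp::Named("W") = W,
                              Rcpp::Named("H") = H,
                              Rcpp::Named("iterations") = it,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("objective") = obj);
}
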