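// Sparse non-negative matrix factorization
//   min_{B,H >= 0} 0.5 * ( ||X - BH||_F^2 + eta ||B||_F^2
//                          + beta * sum_j ||H(:,j)||_1^2 )
// Two solvers:
//  * "mu"   — multiplicative updates (Lee-Seung rules applied to the
//             augmented least-squares forms of the B- and H-subproblems;
//             monotone non-increasing objective, restart-sensitive local
//             optima — the behaviour random-restart consensus clustering
//             relies on);
//  * "anls" — exact alternating non-negative least squares via block
//             principal pivoting (Kim & Park), monotone and much closer
//             to a global optimum per restart.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min_X ||C X - D||_F^2 s.t. X >= 0 column-wise via normal equations
// G = C'C, F = C'D, using block principal pivoting (Kim & Park) with the
// combinatorial grouping of van Benthem & Keenan: all columns sharing a
// passive set are solved in one m x m system with multiple right-hand
// sides. Exact per column, so alternating updates stay monotone.
static mat nnls_bpp(const mat& G, const mat& F) {
  const uword m = G.n_rows;
  const uword n = F.n_cols;
  const double tol = 1e-12;

  umat passive(m, n, fill::zeros);
  mat X(m, n, fill::zeros);
  mat Y = -F;
  ivec pcol(n);
  pcol.fill(3);
  uvec ninf(n);
  ninf.fill(m + 1);
  uvec alive = regspace<uvec>(0, n - 1);

  for (int iter = 0; iter < 200 && alive.n_elem > 0; ++iter) {
    // exchange rules, per still-infeasible column
    std::vector<uword> keep;
    for (uword idx = 0; idx < alive.n_elem; ++idx) {
      uword j = alive(idx);
      uvec viol(m, fill::zeros);
      uword nv = 0;
      for (uword i = 0; i < m; ++i) {
        if ((passive(i, j) && X(i, j) < -tol) ||
            (!passive(i, j) && Y(i, j) < -tol)) {
          viol(i) = 1;
          ++nv;
        }
      }
      if (nv == 0) continue;  // column solved
      if (nv < ninf(j)) {
        ninf(j) = nv;
        pcol(j) = 3;
      } else if (pcol(j) >= 1) {
        --pcol(j);
      } else {
        for (uword i = m; i-- > 0;) {  // backup: flip highest index only
          if (viol(i)) {
            viol.zeros();
            viol(i) = 1;
            break;
          }
        }
      }
      for (uword i = 0; i < m; ++i) {
        if (viol(i)) passive(i, j) = 1 - passive(i, j);
      }
      keep.push_back(j);
    }
    alive = uvec(keep);
    if (alive.n_elem == 0) break;

    // group columns by passive-set bitmask, solve each group jointly
    std::map<unsigned long long, std::vector<uword>> groups;
    for (uword idx = 0; idx < alive.n_elem; ++idx) {
      uword j = alive(idx);
      unsigned long long key = 0;
      for (uword i = 0; i < m; ++i) {
        if (passive(i, j)) key |= (1ULL << i);
      }
      groups[key].push_back(j);
    }
    for (auto& kv : groups) {
      uvec cols(kv.second);
      uvec Fset = find(passive.col(cols(0)) == 1);
      uvec Aset = find(passive.col(cols(0)) == 0);
      X.cols(cols).zeros();
      Y.cols(cols).zeros();
      if (Fset.n_elem > 0) {
        mat GFF = G.submat(Fset, Fset);
        GFF.diag() += 1e-12;  // guard against singular subsystems
        mat XF;
        if (!solve(XF, GFF, F.submat(Fset, cols), solve_opts::no_approx)) {
          XF = pinv(GFF) * F.submat(Fset, cols);
        }
        X.submat(Fset, cols) = XF;
        if (Aset.n_elem > 0) {
          Y.submat(Aset, cols) = G.submat(Aset, Fset) * XF - F.submat(Aset, cols);
        }
      } else {
        Y.cols(cols) = -F.cols(cols);
      }
    }
  }
  return clamp(X, 0.0, datum::inf);
}

static double snmf_objective(const mat& X, const mat& B, const mat& H,
                             double beta, double eta) {
  double rec = accu(square(X - B * H));
  double l1 = accu(square(sum(H, 0)));  // H >= 0: column l1 = column sum
  return 0.5 * (rec + eta * accu(square(B)) + beta * l1);
}

// [[Rcpp::export]]
Rcpp::List snmf_solve_cpp(const arma::mat& X, arma::mat B, arma::mat H,
                          double beta, double eta, int max_iter, double tol,
                          std::string method, bool conn_stop,
                          int conn_patience) {
  const uword m = B.n_cols;
  const double mu_eps = 1e-16;
  const bool use_mu = (method == "mu");
  std::vector<double> trace;
  double prev = snmf_objective(X, B, H, beta, eta);
  trace.push_back(prev);

  // connectivity-based stopping (Brunet): track the argmax partition of H
  // and stop once it is unchanged for conn_patience consecutive iterations
  urowvec conn_prev;
  int conn_streak = 0;

  for (int it = 0; it < max_iter; ++it) {
    if (use_mu) {
      // Lee-Seung rules on the augmented least-squares subproblems:
      // H-design [B; sqrt(beta) 1_{1 x m}] adds beta * colsum(H) to the
      // denominator; B-design [H'; sqrt(eta) I] adds eta * B.
      mat BtB = B.t() * B;
      mat denomH = BtB * H;
      if (beta > 0) denomH += beta * repmat(sum(H, 0), m, 1);
      H = H % (B.t() * X) / (denomH + mu_eps);
      mat HHt = H * H.t();
      mat denomB = B * HHt;
      if (eta > 0) denomB += eta * B;
      B = B % (X * H.t()) / (denomB + mu_eps);
    } else {
      // H-update: rows of the augmented design are [B; sqrt(beta) * 1_{1 x m}]
      mat G = B.t() * B;
      if (beta > 0) G += beta * ones<mat>(m, m);
      H = nnls_bpp(G, B.t() * X);

      // B-update on B': design [H'; sqrt(eta) I]
      mat G2 = H * H.t();
      if (eta > 0) G2.diag() += eta;
      B = nnls_bpp(G2, H * X.t()).t();
    }

    double obj = snmf_objective(X, B, H, beta, eta);
    trace.push_back(obj);
    if (conn_stop) {
      urowvec conn = index_max(H, 0);
      if (conn_prev.n_elem == conn.n_elem && all(conn == conn_prev)) {
        if (++conn_streak >= conn_patience) {
          prev = obj;
          break;
        }
      } else {
        conn_streak = 0;
      }
      conn_prev = conn;
    }
    if (tol > 0 && std::abs(prev - obj) <= tol * std::max(1.0, std::abs(prev))) {
      prev = obj;
      break;
    }
    prev = obj;
  }
  return Rcpp::List::create(
    Rcpp::Named("B") = B,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = prev,
    Rcpp::Named("trace") = trace
  );
}
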