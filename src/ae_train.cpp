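// Mini-batch SGD training loop of the multi-modal sparse denoising
// autoencoder. Mirrors the R reference implementation of the forward
// pass / analytic gradient (R/autoencoder.R), which is what the
// finite-difference tests exercise; this compiled loop exists because a
// full study trains thousands of small networks (tuning x folds x
// pathways). All randomness (shuffling, dropout masks) is drawn from the
// R RNG, so training is deterministic given the R-side seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  std::vector<mat> W1, W4;   // per-modality encoder-in / decoder-out
  std::vector<rowvec> b1, b4;
  mat W2, W3;                // H x 1 and 1 x H
  double b2;
  rowvec b3;
};

struct Arch {
  int k;
  std::vector<int> p, h;
  std::vector<int> off;  // column offset of each modality in the hidden concat
  int H;
};

Params params_from_list(const Rcpp::List& par, const Arch& a,
                        const std::vector<std::string>& mods) {
  Params P;
  for (int j = 0; j < a.k; ++j) {
    P.W1.push_back(Rcpp::as<mat>(par["enc1.W." + mods[j]]));
    P.b1.push_back(Rcpp::as<rowvec>(par["enc1.b." + mods[j]]));
    P.W4.push_back(Rcpp::as<mat>(par["dec2.W." + mods[j]]));
    P.b4.push_back(Rcpp::as<rowvec>(par["dec2.b." + mods[j]]));
  }
  P.W2 = Rcpp::as<mat>(par["enc2.W"]);
  P.b2 = Rcpp::as<double>(par["enc2.b"]);
  P.W3 = Rcpp::as<mat>(par["dec1.W"]);
  P.b3 = Rcpp::as<rowvec>(par["dec1.b"]);
  return P;
}

Rcpp::List params_to_list(const Params& P, const Arch& a,
                          const std::vector<std::string>& mods) {
  Rcpp::List out;
  for (int j = 0; j < a.k; ++j) {
    out["enc1.W." + mods[j]] = P.W1[j];
    out["enc1.b." + mods[j]] = Rcpp::NumericVector(P.b1[j].begin(), P.b1[j].end());
    out["dec2.W." + mods[j]] = P.W4[j];
    out["dec2.b." + mods[j]] = Rcpp::NumericVector(P.b4[j].begin(), P.b4[j].end());
  }
  out["enc2.W"] = P.W2;
  out["enc2.b"] = P.b2;
  out["dec1.W"] = P.W3;
  out["dec1.b"] = Rcpp::NumericVector(P.b3.begin(), P.b3.end());
  return out;
}

double penalty(const Params& P, const Arch& a, double lambda, double alpha) {
  if (lambda <= 0) return 0.0;
  double group = 0.0, l1 = 0.0;
  for (int j = 0; j < a.k; ++j) {
    group += std::sqrt(double(a.p[j]) * double(a.h[j])) * accu(square(P.W1[j]));
    l1 += accu(abs(P.W1[j])) + accu(abs(P.W4[j]));
  }
  l1 += accu(abs(P.W2)) + accu(abs(P.W3));
  return 0.5 * lambda * ((1.0 - alpha) * group + alpha * l1);
}

// full-data objective on clean inputs: 0.5 * sigma + penalty
double objective(const Params& P, const Arch& a, const std::vector<mat>& Xs,
                 double lambda, double alpha) {
  const uword n = Xs[0].n_rows;
  mat A1(n, a.H);
  for (int j = 0; j < a.k; ++j) {
    A1.cols(a.off[j], a.off[j] + a.h[j] - 1) =
        tanh(Xs[j] * P.W1[j] + repmat(P.b1[j], n, 1));
  }
  mat score = tanh(A1 * P.W2 + P.b2);
  mat A3 = tanh(score * P.W3 + repmat(P.b3, n, 1));
  double sse = 0.0;
  for (int j = 0; j < a.k; ++j) {
    mat Z = A3.cols(a.off[j], a.off[j] + a.h[j] - 1) * P.W4[j] +
            repmat(P.b4[j], n, 1);
    sse += accu(square(Z - Xs[j]));
  }
  return 0.5 * sse / double(n) + penalty(P, a, lambda, alpha);
}

// gradient of the mini-batch objective; writes into G (same shapes as P)
void gradient(const Params& P, const Arch& a, const std::vector<mat>& Xin,
              const std::vector<mat>& Xt, double lambda, double alpha,
              Params& G) {
  const uword n = Xin[0].n_rows;
  mat A1(n, a.H);
  for (int j = 0; j < a.k; ++j) {
    A1.cols(a.off[j], a.off[j] + a.h[j] - 1) =
        tanh(Xin[j] * P.W1[j] + repmat(P.b1[j], n, 1));
  }
  mat score = tanh(A1 * P.W2 + P.b2);
  mat A3 = tanh(score * P.W3 + repmat(P.b3, n, 1));

  mat dA3(n, a.H);
  for (int j = 0; j < a.k; ++j) {
    mat Z = A3.cols(a.off[j], a.off[j] + a.h[j] - 1) * P.W4[j] +
            repmat(P.b4[j], n, 1);
    mat dZ = (Z - Xt[j]) / double(n);
    G.W4[j] = A3.cols(a.off[j], a.off[j] + a.h[j] - 1).t() * dZ;
    G.b4[j] = sum(dZ, 0);
    dA3.cols(a.off[j], a.off[j] + a.h[j] - 1) = dZ * P.W4[j].t();
  }
  mat dS3 = dA3 % (1.0 - square(A3));
  G.W3 = score.t() * dS3;
  G.b3 = sum(dS3, 0);
  mat dscore = dS3 * P.W3.t();
  mat dS2 = dscore % (1.0 - square(score));
  G.W2 = A1.t() * dS2;
  G.b2 = accu(dS2);
  mat dA1 = dS2 * P.W2.t();
  mat dS1 = dA1 % (1.0 - square(A1));
  for (int j = 0; j < a.k; ++j) {
    mat dS1j = dS1.cols(a.off[j], a.off[j] + a.h[j] - 1);
    G.W1[j] = Xin[j].t() * dS1j;
    G.b1[j] = sum(dS1j, 0);
  }
  if (lambda > 0) {
    for (int j = 0; j < a.k; ++j) {
      G.W1[j] += lambda * (1.0 - alpha) *
                 std::sqrt(double(a.p[j]) * double(a.h[j])) * P.W1[j];
      G.W1[j] += 0.5 * lambda * alpha * sign(P.W1[j]);
      G.W4[j] += 0.5 * lambda * alpha * sign(P.W4[j]);
    }
    G.W2 += 0.5 * lambda * alpha * sign(P.W2);
    G.W3 += 0.5 * lambda * alpha * sign(P.W3);
  }
}

// one optimizer state slot per parameter tensor
struct Opt {
  std::vector<mat> m, v;
  long t = 0;
};

enum class OptKind { momentum, rmsprop, adam, nadam };

void opt_update(OptKind kind, mat& P, const mat& G, mat& M, mat& V,
                long t, double rho) {
  const double eps = 1e-8;
  switch (kind) {
    case OptKind::momentum:
      M = 0.9 * M - rho * G;
      P += M;
      break;
    case OptKind::rmsprop:
      V = 0.9 * V + 0.1 * square(G);
      P -= rho * G / sqrt(V + eps);
      break;
    case OptKind::adam: {
      M = 0.9 * M + 0.1 * G;
      V = 0.999 * V + 0.001 * square(G);
      mat mh = M / (1.0 - std::pow(0.9, double(t)));
      mat vh = V / (1.0 - std::pow(0.999, double(t)));
      P -= rho * mh / (sqrt(vh) + eps);
      break;
    }
    case OptKind::nadam: {
      M = 0.9 * M + 0.1 * G;
      V = 0.999 * V + 0.001 * square(G);
      mat mh = M / (1.0 - std::pow(0.9, double(t) + 1.0));
      mat vh = V / (1.0 - std::pow(0.999, double(t)));
      mat nes = 0.9 * mh + 0.1 * G / (1.0 - std::pow(0.9, double(t)));
      P -= rho * nes / (sqrt(vh) + eps);
      break;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List ae_fit_cpp(Rcpp::List Xs_list, Rcpp::List init_params,
                      Rcpp::CharacterVector modalities,
                      Rcpp::IntegerVector p_j, Rcpp::IntegerVector h_j,
                      int mini_batch, double lambda, double alpha, double rho,
                      double p_keep, std::string optimizer, int max_epochs,
                      int patience) {
  Arch a;
  a.k = p_j.size();
  int off = 0;
  for (int j = 0; j < a.k; ++j) {
    a.p.push_back(p_j[j]);
    a.h.push_back(h_j[j]);
    a.off.push_back(off);
    off += h_j[j];
  }
  a.H = off;
  std::vector<std::string> mods;
  for (int j = 0; j < a.k; ++j) mods.push_back(Rcpp::as<std::string>(modalities[j]));

  std::vector<mat> Xs;
  for (int j = 0; j < a.k; ++j) Xs.push_back(Rcpp::as<mat>(Xs_list[j]));
  const int n = Xs[0].n_rows;
  const int bs = std::min(mini_batch, n);

  Params P = params_from_list(init_params, a, mods);
  Params G = P;  // shape template; contents overwritten by gradient()

  OptKind kind = optimizer == "momentum" ? OptKind::momentum
               : optimizer == "rmsprop"  ? OptKind::rmsprop
               : optimizer == "nadam"    ? OptKind::nadam
                                         : OptKind::adam;

  // flatten parameter/gradient/state access
  std::vector<mat*> pp, gg;
  auto collect = [&](Params& S, std::vector<mat*>& out) {
    out.clear();
    for (int j = 0; j < a.k; ++j) out.push_back(&S.W1[j]);
    out.push_back(&S.W2);
    out.push_back(&S.W3);
    for (int j = 0; j < a.k; ++j) out.push_back(&S.W4[j]);
  };
  collect(P, pp);
  collect(G, gg);
  // biases handled as 1-row matrices through separate storage
  std::vector<rowvec*> pb = {&P.b3}, gb = {&G.b3};
  for (int j = 0; j < a.k; ++j) { pb.push_back(&P.b1[j]); gb.push_back(&G.b1[j]); }
  for (int j = 0; j < a.k; ++j) { pb.push_back(&P.b4[j]); gb.push_back(&G.b4[j]); }

  Opt st;
  for (auto* m : pp) { st.m.push_back(zeros<mat>(m->n_rows, m->n_cols));
                       st.v.push_back(zeros<mat>(m->n_rows, m->n_cols)); }
  std::vector<mat> stbm, stbv;
  for (auto* b : pb) { stbm.push_back(zeros<mat>(1, b->n_elem));
                       stbv.push_back(zeros<mat>(1, b->n_elem)); }
  mat b2m = zeros<mat>(1, 1), b2v = zeros<mat>(1, 1);

  std::vector<double> trace;
  double best = datum::inf;
  Params best_P = P;
  int stall = 0;

  std::vector<mat> Xb(a.k), Xin(a.k);
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // R-RNG-driven shuffle (deterministic under set.seed)
    Rcpp::IntegerVector ord = Rcpp::sample(n, n, false);
    for (int start = 0; start < n; start += bs) {
      int stop = std::min(start + bs, n) - 1;
      uvec rows(stop - start + 1);
      for (int r = start; r <= stop; ++r) rows(r - start) = ord[r] - 1;
      for (int j = 0; j < a.k; ++j) {
        Xb[j] = Xs[j].rows(rows);
        if (p_keep < 1.0) {
          mat mask(Xb[j].n_rows, Xb[j].n_cols);
          for (uword q = 0; q < mask.n_elem; ++q) {
            mask(q) = (R::unif_rand() < p_keep) ? 1.0 : 0.0;
          }
          Xin[j] = Xb[j] % mask;
        } else {
          Xin[j] = Xb[j];
        }
      }
      gradient(P, a, Xin, Xb, lambda, alpha, G);
      ++st.t;
      for (size_t q = 0; q < pp.size(); ++q) {
        opt_update(kind, *pp[q], *gg[q], st.m[q], st.v[q], st.t, rho);
      }
      for (size_t q = 0; q < pb.size(); ++q) {
        mat bp(*pb[q]), bg(*gb[q]);
        opt_update(kind, bp, bg, stbm[q], stbv[q], st.t, rho);
        *pb[q] = bp.row(0);
      }
      mat b2p(1, 1), b2g(1, 1);
      b2p(0, 0) = P.b2;
      b2g(0, 0) = G.b2;
      opt_update(kind, b2p, b2g, b2m, b2v, st.t, rho);
      P.b2 = b2p(0, 0);
    }
    double obj = objective(P, a, Xs, lambda, alpha);
    if (!std::isfinite(obj)) {
      Rcpp::stop("training diverged at epoch %d (non-finite objective)", epoch);
    }
    trace.push_back(obj);
    if (!std::isfinite(best) || best - obj > 1e-6 * std::max(best, 1e-12)) {
      best = obj;
      best_P = P;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(best_P, a, mods),
    Rcpp::Named("trace") = trace
  );
}
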