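// Fused forward/backward pass for one training minibatch: kernel feature
// layer (RBF or Matern-3/2, trainable centres and shared log-lengthscale),
// tanh MLPs for the feature map, encoder and decoder, the two data-space
// squared-error losses, and the KL term, with gradients for every parameter
// group. Mirrors the reference R implementation (pivae_loss_core) exactly;
// the finite-difference tests exercise this code path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
};

Net net_from_list(const Rcpp::List& net) {
  Rcpp::List Wl = net["W"], bl = net["b"];
  Net out;
  for (int l = 0; l < Wl.size(); ++l) {
    out.W.push_back(Rcpp::as<mat>(Wl[l]));
    out.b.push_back(Rcpp::as<vec>(bl[l]));
  }
  return out;
}

// forward pass caching activations (acts[0] = input)
mat net_forward(const Net& net, const mat& X, std::vector<mat>& acts) {
  acts.clear();
  acts.push_back(X);
  mat H = X;
  const size_t nl = net.W.size();
  for (size_t l = 0; l < nl; ++l) {
    H = H * net.W[l];
    H.each_row() += net.b[l].t();
    if (l + 1 < nl) H = tanh(H);
    acts.push_back(H);
  }
  return H;
}

// gradients of sum(G % out); returns gradient w.r.t. the input batch
mat net_backprop(const Net& net, const std::vector<mat>& acts, const mat& G,
                 std::vector<mat>& gW, std::vector<vec>& gb) {
  const size_t nl = net.W.size();
  gW.assign(nl, mat());
  gb.assign(nl, vec());
  mat delta = G;
  for (size_t l = nl; l-- > 0;) {
    if (l + 1 < nl) delta %= (1.0 - square(acts[l + 1]));
    gW[l] = acts[l].t() * delta;
    gb[l] = sum(delta, 0).t();
    delta = delta * net.W[l].t();
  }
  return delta;
}

struct GradAcc {
  std::vector<std::string> names;
  std::vector<Rcpp::RObject> values;  // RObject keeps each SEXP protected
  void add(const std::string& nm, SEXP v) {
    names.push_back(nm);
    values.push_back(Rcpp::RObject(v));
  }
  void add_net(const std::vector<mat>& gW, const std::vector<vec>& gb,
               const std::string& prefix) {
    for (size_t l = 0; l < gW.size(); ++l) {
      add(prefix + "_W" + std::to_string(l + 1), Rcpp::wrap(gW[l]));
      add(prefix + "_b" + std::to_string(l + 1),
          Rcpp::NumericVector(gb[l].begin(), gb[l].end()));
    }
  }
  Rcpp::List as_list() const {
    Rcpp::List out(values.size());
    Rcpp::CharacterVector nm(values.size());
    for (size_t i = 0; i < values.size(); ++i) {
      out[i] = values[i];
      nm[i] = names[i];
    }
    out.attr("names") = nm;
    return out;
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_pivae_batch")]]
Rcpp::List cpp_pivae_batch(const arma::mat& S, const arma::mat& Y,
                           const arma::mat& betaB, const arma::mat& centres,
                           double log_ell, std::string flavour,
                           Rcpp::List phi_net, Rcpp::List enc_net,
                           Rcpp::List dec_net, const arma::mat& eps,
                           double kl_weight, int K, bool phi_trainable,
                           bool want_grads) {
  const int BK = S.n_rows;
  const int B = betaB.n_rows;
  const int F = betaB.n_cols;
  const int P = Y.n_cols;
  const int L = eps.n_cols;
  const double ell = std::exp(log_ell);

  Net phi = net_from_list(phi_net);
  Net enc = net_from_list(enc_net);
  Net dec = net_from_list(dec_net);

  // kernel layer
  mat d2 = -2.0 * (S * centres.t());
  d2.each_col() += sum(square(S), 1);
  d2.each_row() += sum(square(centres), 1).t();
  d2.transform([](double v) { return v < 0 ? 0.0 : v; });
  mat E, R;
  const bool rbf = (flavour == "rbf");
  if (rbf) {
    E = exp(-d2 / (ell * ell));
  } else {
    const double a = std::sqrt(3.0) / ell;
    R = sqrt(d2);
    E = (1.0 + a * R) % exp(-a * R);
  }

  std::vector<mat> phi_acts, enc_acts, dec_acts;
  mat Phi = net_forward(phi, E, phi_acts);           // BK x (F*P)

  // expand beta over the K points of each draw (rows are draw-major)
  uvec ridx(BK);
  for (int i = 0; i < B; ++i)
    for (int k = 0; k < K; ++k) ridx[i * K + k] = i;
  mat Bexp = betaB.rows(ridx);

  // encoder / reparameterisation / decoder
  mat heads = net_forward(enc, betaB, enc_acts);     // B x 2L
  mat mu = heads.cols(0, L - 1);
  mat raw = heads.cols(L, 2 * L - 1);
  // softplus with overflow guard
  mat sd = raw;
  sd.transform([](double v) { return v > 30 ? v : std::log1p(std::exp(v)); });
  mat z = mu + sd % eps;
  mat betahat = net_forward(dec, z, dec_acts);       // B x F
  mat Bhexp = betahat.rows(ridx);

  double loss1 = 0.0, loss2 = 0.0;
  mat G1(BK, P), G2(BK, P);
  const double scale = 1.0 / double(B) / double(K);
  mat dPhi(BK, F * P, fill::zeros);
  mat dBeta(B, F, fill::zeros), dBetahat(B, F, fill::zeros);
  for (int p = 0; p < P; ++p) {
    mat Phip = Phi.cols(p * F, (p + 1) * F - 1);
    vec f1 = sum(Bexp % Phip, 1);
    vec f2 = sum(Bhexp % Phip, 1);
    vec r1 = f1 - Y.col(p);
    vec r2 = f2 - Y.col(p);
    loss1 += accu(square(r1)) * scale;
    loss2 += accu(square(r2)) * scale;
    G1.col(p) = 2.0 * scale * r1;
    G2.col(p) = 2.0 * scale * r2;
    if (want_grads) {
      dPhi.cols(p * F, (p + 1) * F - 1) =
          (Bexp.each_col() % G1.col(p)) + (Bhexp.each_col() % G2.col(p));
      mat t1 = Phip.each_col() % G1.col(p);
      mat t2 = Phip.each_col() % G2.col(p);
      for (int i = 0; i < B; ++i) {
        dBeta.row(i) += sum(t1.rows(i * K, (i + 1) * K - 1), 0);
        dBetahat.row(i) += sum(t2.rows(i * K, (i + 1) * K - 1), 0);
      }
    }
  }

  double kl = 0.5 * accu(square(sd) + square(mu) - 1.0 - 2.0 * log(sd)) *
              scale;
  double total = loss1 + loss2 + kl_weight * kl;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss1") = loss1, Rcpp::Named("loss2") = loss2,
      Rcpp::Named("kl") = kl, Rcpp::Named("total") = total);
  if (!want_grads) return out;

  // decoder backprop
  std::vector<mat> gWd, gWe, gWp;
  std::vector<vec> gbd, gbe, gbp;
  mat dZ = net_backprop(dec, dec_acts, dBetahat, gWd, gbd);
  // KL + reparameterisation into the encoder heads
  mat dmu = dZ + kl_weight * mu * scale;
  mat dsd = dZ % eps + kl_weight * (sd - 1.0 / sd) * scale;
  mat sig = 1.0 / (1.0 + exp(-raw));  // d softplus
  mat dheads = join_rows(dmu, dsd % sig);
  mat dBeta_enc = net_backprop(enc, enc_acts, dheads, gWe, gbe);
  dBeta += dBeta_enc;

  GradAcc grads;
  grads.add_net(gWd, gbd, "dec");
  grads.add_net(gWe, gbe, "enc");

  if (phi_trainable) {
    mat dE = net_backprop(phi, phi_acts, dPhi, gWp, gbp);
    grads.add_net(gWp, gbp, "phi");
    mat TT;
    double g_logell;
    if (rbf) {
      TT = dE % (-E / (ell * ell));
      g_logell = accu(dE % E % (2.0 * d2 / (ell * ell)));
    } else {
      const double a = std::sqrt(3.0) / ell;
      mat expar = exp(-a * R);
      TT = dE % (-(a * a / 2.0) * expar);
      g_logell = accu(dE % (a * a * d2 % expar));
    }
    mat gC = 2.0 * (centres.each_col() % sum(TT, 0).t() - TT.t() * S);
    grads.add("phi_centres", Rcpp::wrap(gC));
    grads.add("phi_log_lengthscale", Rcpp::wrap(g_logell));
  }

  out["grads"] = grads.as_list();
  out["dBeta"] = Rcpp::wrap(dBeta);
  return out;
}
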