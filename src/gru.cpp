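// GRU regression engine: forward pass, backpropagation through time and the
// Adam training loop. Mirrors the reference R implementation in R/gru.R
// (classic v1 GRU, one bias per gate, inverted dropout with per-sequence
// masks shared across time steps); the two are held equal by tests.
//
// Input tensors arrive as (n, d, T) arrays so that slice t is the n x d
// frame matrix. All randomness (shuffling, dropout masks) is drawn from R's
// RNG, so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// act: 1 = relu, 0 = identity (gates are always sigmoid)
static mat activ(const mat& x, int act) {
  if (act == 1) return clamp(x, 0.0, datum::inf);
  return x;
}
static mat dactiv(const mat& x, int act) {
  if (act == 1) return conv_to<mat>::from(x > 0.0);
  return ones(size(x));
}

struct GruParams {
  mat Wz, Wr, Wc, Uz, Ur, Uc;
  rowvec bz, br, bc;
  vec w;
  double b;
};

static GruParams params_from_list(const List& p) {
  GruParams q;
  q.Wz = Rcpp::as<mat>(p["Wz"]); q.Wr = Rcpp::as<mat>(p["Wr"]);
  q.Wc = Rcpp::as<mat>(p["Wc"]);
  q.Uz = Rcpp::as<mat>(p["Uz"]); q.Ur = Rcpp::as<mat>(p["Ur"]);
  q.Uc = Rcpp::as<mat>(p["Uc"]);
  q.bz = Rcpp::as<rowvec>(p["bz"]); q.br = Rcpp::as<rowvec>(p["br"]);
  q.bc = Rcpp::as<rowvec>(p["bc"]);
  q.w = Rcpp::as<vec>(p["w"]);
  q.b = Rcpp::as<double>(p["b"]);
  return q;
}

static List params_to_list(const GruParams& q) {
  return List::create(
    Named("Wz") = q.Wz, Named("Wr") = q.Wr, Named("Wc") = q.Wc,
    Named("Uz") = q.Uz, Named("Ur") = q.Ur, Named("Uc") = q.Uc,
    Named("bz") = Rcpp::NumericVector(q.bz.begin(), q.bz.end()),
    Named("br") = Rcpp::NumericVector(q.br.begin(), q.br.end()),
    Named("bc") = Rcpp::NumericVector(q.bc.begin(), q.bc.end()),
    Named("w") = mat(q.w), Named("b") = q.b);
}

struct StepCache {
  std::vector<mat> Xt, Hd, Hprev, Z, R, RH, Ac, C;
};

static mat forward_pass(const GruParams& q, const cube& X, int act,
                        const mat* mask_in, const mat* mask_rec,
                        StepCache* cache) {
  const uword n = X.n_rows, Tn = X.n_slices;
  const uword h = q.bz.n_elem;
  mat H(n, h, fill::zeros);
  for (uword t = 0; t < Tn; ++t) {
    mat Xt = X.slice(t);
    if (mask_in) Xt %= *mask_in;
    mat Hd = mask_rec ? mat(H % *mask_rec) : H;
    mat Az = Xt * q.Wz + Hd * q.Uz;
    Az.each_row() += q.bz;
    mat Z = sigm(Az);
    mat Ar = Xt * q.Wr + Hd * q.Ur;
    Ar.each_row() += q.br;
    mat R = sigm(Ar);
    mat RH = R % Hd;
    mat Ac = Xt * q.Wc + RH * q.Uc;
    Ac.each_row() += q.bc;
    mat C = activ(Ac, act);
    mat Hnew = Z % H + (1.0 - Z) % C;
    if (cache) {
      cache->Xt.push_back(Xt); cache->Hd.push_back(Hd);
      cache->Hprev.push_back(H); cache->Z.push_back(Z);
      cache->R.push_back(R); cache->RH.push_back(RH);
      cache->Ac.push_back(Ac); cache->C.push_back(C);
    }
    H = Hnew;
  }
  return H;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_gru_predict(List params, Rcpp::NumericVector Xv,
                                    int act) {
  Rcpp::IntegerVector dims = Xv.attr("dim");
  cube X(Xv.begin(), dims[0], dims[1], dims[2]);
  GruParams q = params_from_list(params);
  mat H = forward_pass(q, X, act, nullptr, nullptr, nullptr);
  vec pred = H * q.w + q.b;
  return Rcpp::NumericVector(pred.begin(), pred.end());
}

static void backward_pass(const GruParams& q, const StepCache& cache,
                          const mat& H_last, const vec& pred, const vec& y,
                          int act, const mat* mask_rec, GruParams& g) {
  const uword n = H_last.n_rows;
  const uword Tn = cache.Xt.size();
  vec dpred = sign(pred - y) / double(n);
  g.w = H_last.t() * dpred;
  g.b = accu(dpred);
  mat dH = dpred * q.w.t();
  for (uword ti = Tn; ti-- > 0;) {
    const mat& Z = cache.Z[ti];
    const mat& R = cache.R[ti];
    mat dC = dH % (1.0 - Z);
    mat dAc = dC % dactiv(cache.Ac[ti], act);
    mat dAz = (dH % (cache.Hprev[ti] - cache.C[ti])) % Z % (1.0 - Z);
    mat dRH = dAc * q.Uc.t();
    mat dAr = (dRH % cache.Hd[ti]) % R % (1.0 - R);
    g.Wz += cache.Xt[ti].t() * dAz;
    g.Wr += cache.Xt[ti].t() * dAr;
    g.Wc += cache.Xt[ti].t() * dAc;
    g.Uz += cache.Hd[ti].t() * dAz;
    g.Ur += cache.Hd[ti].t() * dAr;
    g.Uc += cache.RH[ti].t() * dAc;
    g.bz += sum(dAz, 0);
    g.br += sum(dAr, 0);
    g.bc += sum(dAc, 0);
    mat dHd = dAz * q.Uz.t() + dAr * q.Ur.t() + dRH % R;
    if (mask_rec) dHd %= *mask_rec;
    dH = dH % Z + dHd;
  }
}

// [[Rcpp::export]]
List cpp_gru_grad(List params, Rcpp::NumericVector Xv, Rcpp::NumericVector yv,
                  int act) {
  Rcpp::IntegerVector dims = Xv.attr("dim");
  cube X(Xv.begin(), dims[0], dims[1], dims[2]);
  vec y(yv.begin(), yv.size());
  GruParams q = params_from_list(params);
  StepCache cache;
  mat H = forward_pass(q, X, act, nullptr, nullptr, &cache);
  vec pred = H * q.w + q.b;
  GruParams g;
  g.Wz = zeros(size(q.Wz)); g.Wr = zeros(size(q.Wr)); g.Wc = zeros(size(q.Wc));
  g.Uz = zeros(size(q.Uz)); g.Ur = zeros(size(q.Ur)); g.Uc = zeros(size(q.Uc));
  g.bz = zeros<rowvec>(q.bz.n_elem); g.br = zeros<rowvec>(q.br.n_elem);
  g.bc = zeros<rowvec>(q.bc.n_elem);
  g.w = zeros(q.w.n_elem); g.b = 0.0;
  backward_pass(q, cache, H, pred, y, act, nullptr, g);
  return params_to_list(g);
}

struct AdamState {
  GruParams m, v;
  int t = 0;
};

static void adam_one(mat& p, const mat& g, mat& m, mat& v,
                     double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}
static void adam_one_row(rowvec& p, const rowvec& g, rowvec& m, rowvec& v,
                         double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}
static void adam_one_vec(vec& p, const vec& g, vec& m, vec& v,
                         double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}
static void adam_one_scalar(double& p, double g, double& m, double& v,
                            double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * g * g;
  p -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-8);
}

static mat draw_mask(uword n, uword k, double rate) {
  mat msk(n, k);
  for (uword j = 0; j < k; ++j)
    for (uword i = 0; i < n; ++i)
      msk(i, j) = (unif_rand() >= rate) ? 1.0 / (1.0 - rate) : 0.0;
  return msk;
}

// [[Rcpp::export]]
List cpp_gru_fit(List params, Rcpp::NumericVector Xv, Rcpp::NumericVector yv,
                 double dropout, double recurrent_dropout, double lr,
                 int batch_size, int epochs, int act) {
  Rcpp::IntegerVector dims = Xv.attr("dim");
  const uword n = dims[0], d = dims[1];
  cube X(Xv.begin(), n, d, dims[2]);
  vec y(yv.begin(), yv.size());
  GruParams q = params_from_list(params);
  const uword h = q.bz.n_elem;

  AdamState st;
  st.m.Wz = zeros(size(q.Wz)); st.m.Wr = zeros(size(q.Wr));
  st.m.Wc = zeros(size(q.Wc));
  st.m.Uz = zeros(size(q.Uz)); st.m.Ur = zeros(size(q.Ur));
  st.m.Uc = zeros(size(q.Uc));
  st.m.bz = zeros<rowvec>(h); st.m.br = zeros<rowvec>(h);
  st.m.bc = zeros<rowvec>(h);
  st.m.w = zeros(h); st.m.b = 0.0;
  st.v = st.m;

  double mb = 0.0, vb = 0.0; // Adam state for the output bias scalar

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates over 0..n-1 driven by R's RNG (matches sample.int draws
    // in spirit; only self-consistency is required)
    uvec perm = regspace<uvec>(0, n - 1);
    for (uword i = 0; i < n - 1; ++i) {
      uword j = i + (uword)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(perm(i), perm(j));
    }
    for (uword s = 0; s < n; s += batch_size) {
      uword e = std::min(s + (uword)batch_size, n) - 1;
      uvec idx = perm.subvec(s, e);
      uword nb = idx.n_elem;
      cube Xb(nb, d, X.n_slices);
      for (uword t = 0; t < X.n_slices; ++t)
        Xb.slice(t) = X.slice(t).rows(idx);
      vec yb = y.elem(idx);
      mat mi, mr;
      const mat* pmi = nullptr;
      const mat* pmr = nullptr;
      if (dropout > 0) { mi = draw_mask(nb, d, dropout); pmi = &mi; }
      if (recurrent_dropout > 0) {
        mr = draw_mask(nb, h, recurrent_dropout); pmr = &mr;
      }
      StepCache cache;
      mat H = forward_pass(q, Xb, act, pmi, pmr, &cache);
      vec pred = H * q.w + q.b;
      GruParams g;
      g.Wz = zeros(size(q.Wz)); g.Wr = zeros(size(q.Wr));
      g.Wc = zeros(size(q.Wc));
      g.Uz = zeros(size(q.Uz)); g.Ur = zeros(size(q.Ur));
      g.Uc = zeros(size(q.Uc));
      g.bz = zeros<rowvec>(h); g.br = zeros<rowvec>(h);
      g.bc = zeros<rowvec>(h);
      g.w = zeros(h); g.b = 0.0;
      backward_pass(q, cache, H, pred, yb, act, pmr, g);

      st.t += 1;
      double bc1 = 1.0 - std::pow(0.9, st.t);
      double bc2 = 1.0 - std::pow(0.999, st.t);
      adam_one(q.Wz, g.Wz, st.m.Wz, st.v.Wz, lr, bc1, bc2);
      adam_one(q.Wr, g.Wr, st.m.Wr, st.v.Wr, lr, bc1, bc2);
      adam_one(q.Wc, g.Wc, st.m.Wc, st.v.Wc, lr, bc1, bc2);
      adam_one(q.Uz, g.Uz, st.m.Uz, st.v.Uz, lr, bc1, bc2);
      adam_one(q.Ur, g.Ur, st.m.Ur, st.v.Ur, lr, bc1, bc2);
      adam_one(q.Uc, g.Uc, st.m.Uc, st.v.Uc, lr, bc1, bc2);
      adam_one_row(q.bz, g.bz, st.m.bz, st.v.bz, lr, bc1, bc2);
      adam_one_row(q.br, g.br, st.m.br, st.v.br, lr, bc1, bc2);
      adam_one_row(q.bc, g.bc, st.m.bc, st.v.bc, lr, bc1, bc2);
      adam_one_vec(q.w, g.w, st.m.w, st.v.w, lr, bc1, bc2);
      adam_one_scalar(q.b, g.b, mb, vb, lr, bc1, bc2);
    }
  }
  return params_to_list(q);
}
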