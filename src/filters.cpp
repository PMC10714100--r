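// Compiled inner loops for the Poisson model: stationary PCF/PPF filtering,
// RTS smoothing, and the switching (IMM-mixed) filter and smoother.
// These mirror the generic R implementations exactly; tests assert agreement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sym2(const mat& M) { return 0.5 * (M + M.t()); }

static mat mat_sqrt_c(const mat& S) {
  if (!S.is_finite()) Rcpp::stop("non-finite covariance in matrix square root");
  mat L;
  if (chol(L, sym2(S), "lower")) return L;
  vec ev; mat V;
  eig_sym(ev, V, sym2(S));
  ev = clamp(ev, 0.0, datum::inf);
  return V * diagmat(sqrt(ev)) * V.t();
}

// Cholesky solve with escalating diagonal jitter (1e-10 .. 1e-4 of the
// diagonal scale); matches psd_solve() on the R side.
static mat psd_solve_c(const mat& S, const mat& B) {
  if (!S.is_finite()) Rcpp::stop("non-finite matrix in symmetric solve");
  mat Ssym = sym2(S);
  double scale = mean(Ssym.diag());
  if (!(scale > 0) || !std::isfinite(scale)) scale = 1.0;
  double jit = 0.0;
  while (true) {
    mat R;
    if (chol(R, Ssym + jit * scale * eye(size(S)))) {
      return solve(trimatu(R),
                   solve(trimatl(R.t()), B, solve_opts::fast),
                   solve_opts::fast);
    }
    jit = (jit == 0.0) ? 1e-10 : jit * 10.0;
    if (jit > 1e-4) break;
  }
  // last resort for badly indefinite matrices: eigenvalue-clipped solve
  vec ev; mat V;
  if (!eig_sym(ev, V, Ssym)) Rcpp::stop("symmetric eigendecomposition failed");
  ev = clamp(ev, 1e-10 * scale, datum::inf);
  return V * diagmat(1.0 / ev) * V.t() * B;
}

// rate matrix for a block of points: exp(clip(alpha + beta * X))
static mat rate_mat(const mat& X, const vec& alpha, const mat& beta) {
  mat Eta = beta * X;
  Eta.each_col() += alpha;
  Eta = clamp(Eta, -30.0, 30.0);
  return exp(Eta);
}

struct UpdateOut {
  vec mean; mat cov; double loglik; vec spike_prob; bool has_ll;
};

// PCF measurement update at one bin
static UpdateOut pcf_step(const vec& m, const mat& P, const vec& n,
                          const vec& alpha, const mat& beta,
                          const mat& pts, const vec& w,
                          bool want_ll, bool want_sp) {
  UpdateOut out; out.has_ll = want_ll;
  mat L = mat_sqrt_c(P);
  mat X = L * pts;
  X.each_col() += m;
  mat Pm = rate_mat(X, alpha, beta);        // C x npts expected counts
  vec nhat = Pm * w;
  mat Lnn = Pm * diagmat(w) * Pm.t() + diagmat(nhat) - nhat * nhat.t();
  mat Lxn = X * diagmat(w) * Pm.t() - m * nhat.t();
  mat K = psd_solve_c(Lnn, Lxn.t()).t();
  out.mean = m + K * (n - nhat);
  out.cov = sym2(P - K * Lxn.t());
  if (want_ll) {
    // log E_x[P(n | x)] by max-shifted cubature over the point set
    mat Eta = log(Pm);                       // clipped eta
    rowvec ll = n.t() * Eta - sum(Pm, 0);    // + const(-sum lgamma(n+1))
    double cst = 0.0;
    for (uword c = 0; c < n.n_elem; c++) cst -= std::lgamma(n(c) + 1.0);
    double mx = ll.max();
    double s = dot(w, exp(ll.t() - mx));
    if (s > 0) out.loglik = mx + std::log(s) + cst;
    else {
      vec r0 = rate_mat(m, alpha, beta);
      out.loglik = dot(n, log(r0)) - accu(r0) + cst;
    }
  } else out.loglik = 0.0;
  if (want_sp) {
    out.spike_prob = clamp(1.0 - exp(-Pm) * w, 0.0, 1.0);
  }
  return out;
}

// PPF (Laplace) measurement update: damped Newton from the prediction
static UpdateOut ppf_step(const vec& m, const mat& P, const vec& n,
                          const vec& alpha, const mat& beta,
                          const mat& pts, const vec& w,
                          bool one_step, bool want_ll, bool want_sp) {
  UpdateOut out; out.has_ll = want_ll;
  uword d = m.n_elem;
  mat Pinv = psd_solve_c(P, eye(d, d));
  vec x = m;
  if (one_step) {
    vec r = rate_mat(x, alpha, beta);
    mat J = Pinv + beta.t() * diagmat(r) * beta;
    vec g = beta.t() * (n - r);
    x = x + psd_solve_c(J, g);
  } else {
    auto obj = [&](const vec& z) {
      vec r = rate_mat(z, alpha, beta);
      vec dx = z - m;
      return dot(n, log(r)) - accu(r) - 0.5 * dot(dx, Pinv * dx);
    };
    double f0 = obj(x);
    for (int it = 0; it < 25; it++) {
      vec r = rate_mat(x, alpha, beta);
      vec g = beta.t() * (n - r) - Pinv * (x - m);
      mat J = Pinv + beta.t() * diagmat(r) * beta;
      vec step = psd_solve_c(J, g);
      double a = 1.0;
      vec xn = x + step;
      while (obj(xn) < f0 - 1e-12 && a > 1e-6) { a *= 0.5; xn = x + a * step; }
      double moved = norm(xn - x);
      x = xn; f0 = obj(x);
      if (moved < 1e-8) break;
    }
  }
  vec r = rate_mat(x, alpha, beta);
  mat J = Pinv + beta.t() * diagmat(r) * beta;
  out.mean = x;
  out.cov = sym2(psd_solve_c(J, eye(d, d)));
  if (want_ll || want_sp) {
    mat L = mat_sqrt_c(P);
    mat X = L * pts;
    X.each_col() += m;
    mat Pm = rate_mat(X, alpha, beta);
    if (want_ll) {
      mat Eta = log(Pm);
      rowvec ll = n.t() * Eta - sum(Pm, 0);
      double cst = 0.0;
      for (uword c = 0; c < n.n_elem; c++) cst -= std::lgamma(n(c) + 1.0);
      double mx = ll.max();
      double s = dot(w, exp(ll.t() - mx));
      if (s > 0) out.loglik = mx + std::log(s) + cst;
      else {
        vec r0 = rate_mat(m, alpha, beta);
        out.loglik = dot(n, log(r0)) - accu(r0) + cst;
      }
    }
    if (want_sp) out.spike_prob = clamp(1.0 - exp(-Pm) * w, 0.0, 1.0);
  }
  if (!want_ll) out.loglik = 0.0;
  return out;
}

// [[Rcpp::export]]
Rcpp::List plds_filter_cpp(const arma::mat& counts, const arma::mat& A,
                           const arma::mat& Q, const arma::vec& mu0,
                           const arma::mat& Lambda0, const arma::vec& alpha,
                           const arma::mat& beta, const arma::mat& pts,
                           const arma::vec& w, bool ppf, bool one_step,
                           bool spike_probs, bool loglik) {
  uword d = A.n_rows, T = counts.n_cols, C = counts.n_rows;
  mat xf(d, T), xp(d, T);
  cube Pf(d, d, T), Pp(d, d, T);
  mat sp; if (spike_probs) sp.set_size(C, T);
  vec ll; if (loglik) ll.set_size(T);
  vec m = mu0; mat P = Lambda0;
  for (uword t = 0; t < T; t++) {
    vec mpred = A * m;
    mat Ppred = sym2(A * P * A.t() + Q);
    xp.col(t) = mpred; Pp.slice(t) = Ppred;
    UpdateOut u = ppf
      ? ppf_step(mpred, Ppred, counts.col(t), alpha, beta, pts, w,
                 one_step, loglik, spike_probs)
      : pcf_step(mpred, Ppred, counts.col(t), alpha, beta, pts, w,
                 loglik, spike_probs);
    m = u.mean; P = u.cov;
    xf.col(t) = m; Pf.slice(t) = P;
    if (spike_probs) sp.col(t) = u.spike_prob;
    if (loglik) ll(t) = u.loglik;
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("xf") = xf, Rcpp::Named("Pf") = Pf,
    Rcpp::Named("xp") = xp, Rcpp::Named("Pp") = Pp);
  if (spike_probs) out["spike_prob"] = sp;
  if (loglik) out["loglik"] = ll;
  return out;
}

// [[Rcpp::export]]
Rcpp::List rts_smooth_cpp(const arma::mat& xf, const arma::cube& Pf,
                          const arma::mat& xp, const arma::cube& Pp,
                          const arma::mat& A, const arma::vec& mu0,
                          const arma::mat& Lambda0) {
  uword d = xf.n_rows, T = xf.n_cols;
  mat xs = xf;
  cube Ps = Pf;
  cube cross(d, d, T, fill::zeros);
  for (uword t = T - 1; t >= 1; t--) {
    mat G = psd_solve_c(Pp.slice(t), A * Pf.slice(t - 1)).t();
    xs.col(t - 1) = xf.col(t - 1) + G * (xs.col(t) - xp.col(t));
    Ps.slice(t - 1) = sym2(Pf.slice(t - 1) +
      G * (Ps.slice(t) - Pp.slice(t)) * G.t());
    cross.slice(t) = Ps.slice(t) * G.t() + xs.col(t) * xs.col(t - 1).t();
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("xs") = xs, Rcpp::Named("Ps") = Ps,
    Rcpp::Named("cross") = cross);
  if (mu0.n_elem == d) {
    mat G0 = psd_solve_c(Pp.slice(0), A * Lambda0).t();
    vec x0 = mu0 + G0 * (xs.col(0) - xp.col(0));
    mat P0 = sym2(Lambda0 + G0 * (Ps.slice(0) - Pp.slice(0)) * G0.t());
    cross.slice(0) = Ps.slice(0) * G0.t() + xs.col(0) * x0.t();
    out["x0"] = x0; out["P0"] = P0; out["cross"] = cross;
  }
  return out;
}

// Switching filter: IMM-style destination-conditioned mixing, a bank of M
// per-regime PCF/PPF updates, and the regime posterior from cubature
// predictive likelihoods. All regime-weight arithmetic is in log domain.
// [[Rcpp::export]]
Rcpp::List switching_filter_cpp(const arma::mat& counts, const arma::cube& A,
                                const arma::cube& Q, const arma::mat& mu0,
                                const arma::cube& Lambda0,
                                const arma::mat& alpha, const arma::cube& beta,
                                const arma::mat& Phi, const arma::vec& pi,
                                const arma::mat& pts, const arma::vec& w,
                                bool ppf, bool one_step, bool spike_probs) {
  uword d = A.n_rows, T = counts.n_cols, C = counts.n_rows, M = Phi.n_cols;
  mat w_filt(M, T), w_pred(M, T), ell(M, T);
  vec ll_tot(T);
  // per-regime storage
  Rcpp::List xf_l(M), Pf_l(M), xp_l(M), Pp_l(M), xmix_l(M), Pmix_l(M);
  std::vector<mat> xf(M, mat(d, T)), xp(M, mat(d, T)), xmix(M, mat(d, T));
  std::vector<cube> Pf(M, cube(d, d, T)), Pp(M, cube(d, d, T)),
                    Pmix(M, cube(d, d, T));
  mat sp; if (spike_probs) sp.set_size(C, T);
  mat merged_mean(d, T);

  std::vector<vec> mprev(M);
  std::vector<mat> Pprev(M);
  vec wprev(M);
  for (uword j = 0; j < M; j++) { mprev[j] = mu0.col(j); Pprev[j] = Lambda0.slice(j); }
  wprev = pi;

  for (uword t = 0; t < T; t++) {
    vec n = counts.col(t);
    vec pr(M), lognum(M);
    mat spj; if (spike_probs) spj.set_size(C, M);
    for (uword j = 0; j < M; j++) {
      vec mmix; mat Pmx;
      if (t == 0) {
        // no regime history yet: prior of regime j, predicted weight pi_j
        mmix = mu0.col(j); Pmx = Lambda0.slice(j);
        pr(j) = pi(j);
      } else {
        vec num = Phi.row(j).t() % wprev;      // Phi[j,i] * w_{t-1}(i)
        pr(j) = accu(num);
        vec mu_ij = (pr(j) > 0) ? vec(num / pr(j))
                                : vec(ones<vec>(M) / M);
        mmix = zeros<vec>(d);
        for (uword i = 0; i < M; i++) mmix += mu_ij(i) * mprev[i];
        Pmx = zeros<mat>(d, d);
        for (uword i = 0; i < M; i++) {
          vec dm = mprev[i] - mmix;
          Pmx += mu_ij(i) * (Pprev[i] + dm * dm.t());
        }
      }
      xmix[j].col(t) = mmix; Pmix[j].slice(t) = Pmx;
      vec mpred = A.slice(j) * mmix;
      mat Ppred = sym2(A.slice(j) * Pmx * A.slice(j).t() + Q.slice(j));
      xp[j].col(t) = mpred; Pp[j].slice(t) = Ppred;
      UpdateOut u = ppf
        ? ppf_step(mpred, Ppred, n, alpha.col(j), beta.slice(j), pts, w,
                   one_step, true, spike_probs)
        : pcf_step(mpred, Ppred, n, alpha.col(j), beta.slice(j), pts, w,
                   true, spike_probs);
      xf[j].col(t) = u.mean; Pf[j].slice(t) = u.cov;
      ell(j, t) = u.loglik;
      if (spike_probs) spj.col(j) = u.spike_prob;
      lognum(j) = (pr(j) > 0 ? std::log(pr(j)) : -datum::inf) + u.loglik;
    }
    w_pred.col(t) = pr;
    double mx = lognum.max();
    vec wnew(M);
    if (!std::isfinite(mx)) {
      wnew.fill(1.0 / M);   // all-zero unnormalized weights: uniform fallback
    } else {
      wnew = exp(lognum - mx);
      wnew /= accu(wnew);
    }
    w_filt.col(t) = wnew;
    ll_tot(t) = std::isfinite(mx) ? mx + std::log(accu(exp(lognum - mx))) : -datum::inf;
    if (spike_probs) sp.col(t) = spj * pr;   // regime-weighted mixture
    vec mm = zeros<vec>(d);
    for (uword j = 0; j < M; j++) mm += wnew(j) * xf[j].col(t);
    merged_mean.col(t) = mm;
    for (uword j = 0; j < M; j++) { mprev[j] = xf[j].col(t); Pprev[j] = Pf[j].slice(t); }
    wprev = wnew;
  }
  for (uword j = 0; j < M; j++) {
    xf_l[j] = xf[j]; Pf_l[j] = Pf[j]; xp_l[j] = xp[j]; Pp_l[j] = Pp[j];
    xmix_l[j] = xmix[j]; Pmix_l[j] = Pmix[j];
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("w_filt") = w_filt, Rcpp::Named("w_pred") = w_pred,
    Rcpp::Named("ell") = ell, Rcpp::Named("loglik") = ll_tot,
    Rcpp::Named("xf") = xf_l, Rcpp::Named("Pf") = Pf_l,
    Rcpp::Named("xp") = xp_l, Rcpp::Named("Pp") = Pp_l,
    Rcpp::Named("xmix") = xmix_l, Rcpp::Named("Pmix") = Pmix_l,
    Rcpp::Named("merged_mean") = merged_mean);
  if (spike_probs) out["spike_prob"] = sp;
  return out;
}

// Switching smoother with expectation correction: the backward conditional
// P(s_t=i | s_{t+1}=j, n_{1:T}) is proportional to the filtered weight times
// a Gaussian overlap factor, the (i -> j) pair prediction density evaluated
// at the smoothed mean of (t+1, j); the bin-likelihood factor is constant in
// the source regime and cancels in the normalization. Per-regime smoothed
// latents come from pair-conditioned RTS steps moment-matched over the
// successor regime, and the regime-conditioned one-lag statistics needed by
// the switch EM M-step are anchored at the filter's mixed priors.
// [[Rcpp::export]]
Rcpp::List switching_smoother_cpp(const Rcpp::List& filt,
                                  const arma::cube& A, const arma::cube& Q,
                                  const arma::mat& Phi) {
  mat w_filt = filt["w_filt"];
  uword M = w_filt.n_rows, T = w_filt.n_cols;
  std::vector<mat> xf(M), xp(M), xmix(M);
  std::vector<cube> Pf(M), Pp(M), Pmix(M);
  Rcpp::List xf_l = filt["xf"], Pf_l = filt["Pf"], xp_l = filt["xp"],
             Pp_l = filt["Pp"], xmix_l = filt["xmix"], Pmix_l = filt["Pmix"];
  for (uword j = 0; j < M; j++) {
    xf[j] = Rcpp::as<mat>(xf_l[j]); Pf[j] = Rcpp::as<cube>(Pf_l[j]);
    xp[j] = Rcpp::as<mat>(xp_l[j]); Pp[j] = Rcpp::as<cube>(Pp_l[j]);
    xmix[j] = Rcpp::as<mat>(xmix_l[j]); Pmix[j] = Rcpp::as<cube>(Pmix_l[j]);
  }
  uword d = xf[0].n_rows;

  mat Ws(M, T);
  cube pairwise(M, M, T, fill::zeros);   // slice t: [j, i] = P(s_t=j, s_{t-1}=i)
  std::vector<mat> xs(M, mat(d, T));
  std::vector<cube> Ps(M, cube(d, d, T));
  Ws.col(T - 1) = w_filt.col(T - 1);
  for (uword j = 0; j < M; j++) {
    xs[j].col(T - 1) = xf[j].col(T - 1);
    Ps[j].slice(T - 1) = Pf[j].slice(T - 1);
  }
  auto log_mvn = [&](const vec& x, const vec& mu, const mat& S) {
    mat R;
    if (!chol(R, sym2(S) + 1e-12 * eye(d, d))) return -1e30;
    vec z = solve(trimatl(R.t()), x - mu, solve_opts::fast);
    double ld = accu(log(R.diag()));
    return -0.5 * (d * std::log(2.0 * datum::pi) + dot(z, z)) - ld;
  };
  for (uword t = T - 1; t >= 1; t--) {
    // expectation-corrected two-slice weights [i at t-1, j at t]
    mat log_rho(M, M);
    log_rho.fill(-datum::inf);
    cube cm(d, M, M);                    // conditional means [., i, j]
    std::vector<std::vector<mat>> cP(M, std::vector<mat>(M));
    for (uword j = 0; j < M; j++) {
      for (uword i = 0; i < M; i++) {
        mat Pfi = Pf[i].slice(t - 1);
        vec a = A.slice(j) * xf[i].col(t - 1);
        mat Apred = sym2(A.slice(j) * Pfi * A.slice(j).t() + Q.slice(j));
        double z = log_mvn(xs[j].col(t), a, Apred);
        double lphi = (Phi(j, i) > 0) ? std::log(Phi(j, i)) : -datum::inf;
        double lw = (w_filt(i, t - 1) > 0) ? std::log(w_filt(i, t - 1))
                                           : -datum::inf;
        log_rho(i, j) = lw + lphi + z;
        mat G = psd_solve_c(Apred, A.slice(j) * Pfi).t();
        cm.slice(j).col(i) = xf[i].col(t - 1) + G * (xs[j].col(t) - a);
        cP[i][j] = sym2(Pfi + G * (Ps[j].slice(t) - Apred) * G.t());
      }
    }
    for (uword j = 0; j < M; j++) {
      vec lr = log_rho.col(j);
      double mx = lr.max();
      vec cond(M);
      if (std::isfinite(mx)) {
        cond = exp(lr - mx);
        cond /= accu(cond);
      } else cond.fill(1.0 / M);
      pairwise.slice(t).row(j) = Ws(j, t) * cond.t();
    }
    Ws.col(t - 1) = pairwise.slice(t).t() * ones<vec>(M);
    // moment-match the smoothed latent of regime i at t-1 over successor j
    for (uword i = 0; i < M; i++) {
      vec wk = pairwise.slice(t).col(i);
      double s = accu(wk);
      if (s > 0) wk /= s; else wk.fill(1.0 / M);
      vec mean_acc = zeros<vec>(d);
      for (uword j = 0; j < M; j++) mean_acc += wk(j) * cm.slice(j).col(i);
      mat cov_acc = zeros<mat>(d, d);
      for (uword j = 0; j < M; j++) {
        vec dm = cm.slice(j).col(i) - mean_acc;
        cov_acc += wk(j) * (cP[i][j] + dm * dm.t());
      }
      xs[i].col(t - 1) = mean_acc;
      Ps[i].slice(t - 1) = sym2(cov_acc);
    }
  }
  std::vector<mat> x_prev(M, mat(d, T));          // E[x_{t-1} | n_{1:T}, s_t=j]
  std::vector<cube> P_prev(M, cube(d, d, T));     // Cov of the same
  std::vector<cube> cross(M, cube(d, d, T));      // E[x_t x_{t-1}' | ., s_t=j]
  // regime-conditioned one-lag statistics through the filter's mixed priors
  for (uword t = 0; t < T; t++) {
    for (uword j = 0; j < M; j++) {
      mat G = psd_solve_c(Pp[j].slice(t), A.slice(j) * Pmix[j].slice(t)).t();
      vec xprev = xmix[j].col(t) + G * (xs[j].col(t) - xp[j].col(t));
      mat Pprev_ = sym2(Pmix[j].slice(t) + G * (Ps[j].slice(t) - Pp[j].slice(t)) * G.t());
      x_prev[j].col(t) = xprev;
      P_prev[j].slice(t) = Pprev_;
      cross[j].slice(t) = Ps[j].slice(t) * G.t() + xs[j].col(t) * xprev.t();
    }
  }
  // merged smoothed latents (moment-matched mixture over regimes)
  mat merged(d, T);
  cube merged_cov(d, d, T);
  for (uword t = 0; t < T; t++) {
    vec mm = zeros<vec>(d);
    for (uword j = 0; j < M; j++) mm += Ws(j, t) * xs[j].col(t);
    mat cc = zeros<mat>(d, d);
    for (uword j = 0; j < M; j++) {
      vec dm = xs[j].col(t) - mm;
      cc += Ws(j, t) * (Ps[j].slice(t) + dm * dm.t());
    }
    merged.col(t) = mm; merged_cov.slice(t) = cc;
  }
  Rcpp::List xs_l(M), Ps_l(M), xprev_l(M), Pprev_l(M), cross_l(M);
  for (uword j = 0; j < M; j++) {
    xs_l[j] = xs[j]; Ps_l[j] = Ps[j]; xprev_l[j] = x_prev[j];
    Pprev_l[j] = P_prev[j]; cross_l[j] = cross[j];
  }
  return Rcpp::List::create(
    Rcpp::Named("Ws") = Ws, Rcpp::Named("pairwise") = pairwise,
    Rcpp::Named("xs") = xs_l, Rcpp::Named("Ps") = Ps_l,
    Rcpp::Named("x_prev") = xprev_l, Rcpp::Named("P_prev") = Pprev_l,
    Rcpp::Named("cross") = cross_l,
    Rcpp::Named("merged_mean") = merged, Rcpp::Named("merged_cov") = merged_cov);
}

// Newton maximization of the concave per-neuron observation objective
//   sum_t w_t [ n_t (a + b'm_t) - exp(a + b'm_t + b'S_t b / 2) ];
// straight port of the reference R implementation.
// [[Rcpp::export]]
Rcpp::List mstep_observation_cpp(const arma::mat& counts, const arma::mat& m,
                                 const arma::mat& Smat, const arma::vec& w,
                                 const arma::vec& alpha0, const arma::mat& beta0,
                                 int max_iter, double tol) {
  uword C = counts.n_rows, d = m.n_rows, T = m.n_cols;
  vec alpha = alpha0;
  mat beta = beta0;
  int failed = 0;
  auto Sb = [&](const vec& b) {
    mat out(d, T, fill::zeros);
    for (uword l = 0; l < d; l++) out += Smat.rows(l * d, l * d + d - 1) * b(l);
    return out;
  };
  for (uword i = 0; i < C; i++) {
    vec n = counts.row(i).t();
    double a = alpha0(i);
    vec b = beta0.row(i).t();
    auto value = [&](double a_, const vec& b_) {
      vec u = a_ + m.t() * b_;
      mat Sbt = Sb(b_);
      vec v = 0.5 * (Sbt.t() * b_);
      return dot(w, n % u - exp(clamp(u + v, -datum::inf, 30.0)));
    };
    double f0 = value(a, b);
    bool converged = false;
    double moved = 0.0;
    for (int it = 0; it < max_iter; it++) {
      mat Sbt = Sb(b);
      vec u = a + m.t() * b;
      vec v = 0.5 * (Sbt.t() * b);
      vec g = exp(clamp(u + v, -datum::inf, 30.0));
      vec wg = w % g;
      mat mm = m + Sbt;
      vec grad(d + 1);
      grad(0) = dot(w, n) - accu(wg);
      grad.subvec(1, d) = m * (w % n) - mm * wg;
      mat H(d + 1, d + 1);
      H(0, 0) = accu(wg);
      vec Hab = mm * wg;
      H.submat(0, 1, 0, d) = Hab.t();
      H.submat(1, 0, d, 0) = Hab;
      mat SW = reshape(Smat * wg, d, d);
      H.submat(1, 1, d, d) = mm * diagmat(wg) * mm.t() + SW;
      vec step;
      if (!solve(step, H, grad, solve_opts::likely_sympd + solve_opts::no_approx)) {
        mat Hr = H + 1e-10 * mean(H.diag()) * eye(d + 1, d + 1);
        if (!solve(step, Hr, grad, solve_opts::no_approx)) break;
      }
      double al = 1.0;
      double an = a + step(0);
      vec bn = b + step.subvec(1, d);
      double fn = value(an, bn);
      while (fn < f0 - 1e-12 && al > 1e-8) {
        al *= 0.5;
        an = a + al * step(0);
        bn = b + al * step.subvec(1, d);
        fn = value(an, bn);
      }
      if (fn < f0 - 1e-12) { an = a; bn = b; fn = f0; }
      moved = std::sqrt(std::pow(an - a, 2) + accu(square(bn - b)));
      a = an; b = bn; f0 = fn;
      if (moved < tol) { converged = true; break; }
    }
    if (converged) {
      alpha(i) = a;
      beta.row(i) = b.t();
    } else failed++;
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("n_failed") = failed);
}
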