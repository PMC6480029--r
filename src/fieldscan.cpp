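#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Cholesky of a (nearly) symmetric PD matrix with an escalating relative
// ridge.  Returns false when the matrix stays indefinite at 1e-4 of its
// diagonal scale.
static bool ridged_chol(mat& R, const mat& A0) {
  mat A = 0.5 * (A0 + A0.t());
  if (chol(R, A)) return true;
  double scale = mean(A.diag());
  if (!std::isfinite(scale) || scale <= 0.0) scale = 1.0;
  for (double j = 1e-10; j <= 1e-4; j *= 10.0) {
    mat Aj = A;
    Aj.diag() += j * scale;
    if (chol(R, Aj)) return true;
  }
  return false;
}

struct EmData {
  std::vector<mat> K;     // per-process kernel rows (ntl x n)
  std::vector<vec> x;     // observed values
  double ntot;
  int L, n;
  double pi0, tau, s2min;
  const mat* kinv;
};

// Reusable per-slice workspace so the EM inner loop allocates nothing.
struct EmWork {
  mat Lo, Wacc, Cn, Csym;
  std::vector<mat> V, A, Ra, Z, W, VtV;
  std::vector<vec> r, w, res;
  void init(const EmData& d) {
    const int n = d.n;
    Lo.set_size(n, n); Wacc.set_size(n, n); Cn.set_size(n, n);
    Csym.set_size(n, n);
    V.resize(d.L); A.resize(d.L); Ra.resize(d.L); Z.resize(d.L);
    W.resize(d.L); VtV.resize(d.L); r.resize(d.L); w.resize(d.L);
    res.resize(d.L);
    for (int l = 0; l < d.L; ++l) {
      const int ntl = d.x[l].n_elem;
      V[l].set_size(ntl, n); A[l].set_size(ntl, ntl);
      Z[l].set_size(ntl, n); W[l].set_size(n, n); VtV[l].set_size(n, n);
      r[l].set_size(ntl); w[l].set_size(ntl); res[l].set_size(ntl);
    }
  }
};

struct EmState {
  vec m;
  mat C;
  double s2;
};

// One EM map evaluation: E-step for every process, then the M-step.
// The E-step uses the matrix-inversion-lemma (Gaussian-process
// regression) form, which never inverts the prior covariance C and
// stays well-conditioned for any noise variance: with the lower
// Cholesky factor C = Lo Lo', V_l = K_l Lo and A = V_l V_l' + s2 I,
//   alpha_l = m + Lo V_l' A^-1 (x_l - K_l m),
//   C_l     = Lo (I - Z_l' Z_l) Lo',  Z_l = chol(A)^-T V_l,
// algebraically identical to the precision-form update.  Returns false
// if a factorization fails (e.g. on an extrapolated state), leaving
// `out` untouched.
static bool em_map(const EmData& d, EmWork& ws, const EmState& in,
                   EmState& out, std::vector<vec>* alpha_out,
                   std::vector<mat>* Calpha_out) {
  const int L = d.L, n = d.n;
  const double s2 = in.s2;
  mat R;                                  // C = R'R, R upper
  if (!ridged_chol(R, in.C)) return false;
  ws.Lo = R.t();
  std::vector<vec> alpha(L);
  vec m_new = zeros<vec>(n);
  ws.Wacc.zeros();                        // sum_l (I - Z_l'Z_l)
  double s2n = 0.0;
  for (int l = 0; l < L; ++l) {
    const int ntl = d.x[l].n_elem;
    if (ntl == 0) {
      alpha[l] = in.m;
      ws.Wacc.diag() += 1.0;
      ws.W[l].eye(n, n);
      m_new += alpha[l];
      continue;
    }
    ws.V[l] = d.K[l] * trimatl(ws.Lo);    // ntl x n (trmm)
    ws.A[l] = ws.V[l] * ws.V[l].t();
    ws.A[l].diag() += s2;
    if (!ridged_chol(ws.Ra[l], ws.A[l])) return false;
    ws.Z[l] = solve(trimatl(ws.Ra[l].t()), ws.V[l]);   // ntl x n
    ws.W[l] = -(ws.Z[l].t() * ws.Z[l]);
    ws.W[l].diag() += 1.0;                // I - Z'Z
    ws.Wacc += ws.W[l];
    ws.r[l] = d.x[l] - d.K[l] * in.m;
    ws.w[l] = solve(trimatu(ws.Ra[l]),
                    solve(trimatl(ws.Ra[l].t()), ws.r[l]));
    alpha[l] = in.m + ws.Lo * (ws.V[l].t() * ws.w[l]);
    m_new += alpha[l];
    // residual and trace term of the noise-variance update
    ws.res[l] = d.x[l] - d.K[l] * alpha[l];
    ws.VtV[l] = ws.V[l].t() * ws.V[l];
    s2n += dot(ws.res[l], ws.res[l]) + accu(ws.VtV[l] % ws.W[l]);
  }
  m_new /= (d.pi0 + L);
  ws.Wacc = trimatl(ws.Lo) * ws.Wacc;     // trmm, left
  ws.Wacc = ws.Wacc * trimatu(ws.Lo.t()); // trmm, right
  ws.Cn = d.pi0 * (m_new * m_new.t()) + d.tau * (*d.kinv) + ws.Wacc;
  for (int l = 0; l < L; ++l) {
    vec dd = alpha[l] - m_new;
    ws.Cn += dd * dd.t();
  }
  ws.Csym = (ws.Cn + ws.Cn.t()) / (2.0 * (d.tau + L));
  s2n = std::max(s2n / d.ntot, d.s2min);
  out.m = m_new;
  out.C = ws.Csym;
  out.s2 = s2n;
  if (alpha_out) *alpha_out = alpha;
  if (Calpha_out) {
    Calpha_out->resize(L);
    for (int l = 0; l < L; ++l)
      (*Calpha_out)[l] = ws.Lo * ws.W[l] * ws.Lo.t();
  }
  return true;
}

static double rel_change(const EmState& a, const EmState& b) {
  double dm = norm(b.m - a.m) / (norm(a.m) + 1e-12);
  double ds = std::fabs(b.s2 - a.s2) / (a.s2 + 1e-12);
  return std::max(dm, ds);
}

// EM to convergence.  With `accelerate`, a SQUAREM-type vector
// extrapolation in (m, C, log s2) is applied after every cycle of two
// map evaluations; the first map of the following cycle doubles as the
// stabilization step, so each cycle costs exactly two evaluations.  The
// fixed point is unchanged and the stopping rule is still the relative
// change of (m, s2) across one map evaluation.
static bool em_run(const EmData& d, EmWork& ws, EmState& th, double tol,
                   int maxit, bool accelerate, int& evals,
                   bool& converged, std::vector<vec>* alpha_out = nullptr) {
  evals = 0;
  converged = false;
  EmState t1, t2, fallback;
  bool haveFallback = false;
  while (evals < maxit) {
    if (!em_map(d, ws, th, t1, alpha_out, nullptr)) {
      if (!haveFallback) return false;
      th = fallback;          // extrapolated state infeasible; back off
      haveFallback = false;
      continue;
    }
    ++evals;
    if (rel_change(th, t1) < tol && !haveFallback) {
      th = t1;
      converged = true;
      break;
    }
    haveFallback = false;
    if (!accelerate || evals >= maxit) { th = t1; continue; }
    if (!em_map(d, ws, t1, t2, alpha_out, nullptr)) return false;
    ++evals;
    if (rel_change(t1, t2) < tol) { th = t2; converged = true; break; }
    // SQUAREM extrapolation in (m, C, log s2)
    const int n = d.n;
    const int len = n + n * n + 1;
    vec v0(len), v1(len), v2(len);
    v0.head(n) = th.m;  v0.subvec(n, n + n * n - 1) = vectorise(th.C);
    v0[len - 1] = std::log(th.s2);
    v1.head(n) = t1.m;  v1.subvec(n, n + n * n - 1) = vectorise(t1.C);
    v1[len - 1] = std::log(t1.s2);
    v2.head(n) = t2.m;  v2.subvec(n, n + n * n - 1) = vectorise(t2.C);
    v2[len - 1] = std::log(t2.s2);
    vec r = v1 - v0;
    vec q = v2 - v1 - r;
    double qn = norm(q);
    if (qn < 1e-300) { th = t2; continue; }
    double a = -norm(r) / qn;
    if (a > -1.0) a = -1.0;
    vec vex = v0 - 2.0 * a * r + (a * a) * q;
    th.m = vex.head(n);
    th.C = reshape(vex.subvec(n, n + n * n - 1), n, n);
    th.C = 0.5 * (th.C + th.C.t());
    th.s2 = std::max(std::exp(vex[len - 1]), d.s2min);
    fallback = t2;            // plain iterate, in case th is infeasible
    haveFallback = true;
  }
  return true;
}

static EmData make_data(const std::vector<vec>& x,
                        const std::vector<uvec>& obs, const mat& kj,
                        const mat& kinv, double pi0, double tau,
                        double s2min) {
  EmData d;
  d.L = x.size();
  d.n = kj.n_cols;
  d.pi0 = pi0;
  d.tau = tau;
  d.s2min = s2min;
  d.kinv = &kinv;
  d.K.resize(d.L);
  d.x = x;
  d.ntot = 0.0;
  for (int l = 0; l < d.L; ++l) {
    d.K[l] = kj.rows(obs[l]);
    d.ntot += obs[l].n_elem;
  }
  return d;
}

// [[Rcpp::export]]
List cpp_em_fit(List x, List obs, const arma::mat& kj,
                const arma::mat& kinv, double pi0, double tau, double tol,
                int maxit, double s2min, const arma::vec& m0,
                const arma::mat& C0, double s20, bool accelerate) {
  const int L = x.size();
  std::vector<vec> xv(L);
  std::vector<uvec> ov(L);
  for (int l = 0; l < L; ++l) {
    xv[l] = as<vec>(x[l]);
    ov[l] = as<uvec>(obs[l]);
    if (ov[l].n_elem > 0) ov[l] -= 1;  // 1-based from R
  }
  EmData d = make_data(xv, ov, kj, kinv, pi0, tau, s2min);
  EmWork ws;
  ws.init(d);
  EmState th;
  th.m = m0;
  th.C = C0;
  th.s2 = s20;
  int evals = 0;
  bool converged = false;
  if (maxit > 0) {
    if (!em_run(d, ws, th, tol, maxit, accelerate, evals, converged))
      stop("EM factorization failed beyond jitter repair");
  }
  // final E-step at the returned state, for the fitted weights
  List al(L), cl(L);
  if (maxit > 0) {
    EmState dummy;
    std::vector<vec> alpha;
    std::vector<mat> Calpha;
    if (!em_map(d, ws, th, dummy, &alpha, &Calpha))
      stop("EM factorization failed beyond jitter repair");
    for (int l = 0; l < L; ++l) {
      al[l] = alpha[l];
      cl[l] = Calpha[l];
    }
  }
  return List::create(_["m"] = th.m, _["C"] = th.C, _["s2"] = th.s2,
                      _["alpha"] = al, _["Calpha"] = cl,
                      _["iterations"] = evals, _["converged"] = converged);
}

// Draw `k` distinct 0-based indices from 0..n-1 (partial Fisher-Yates
// on R's uniform stream).
static void draw_missing(int n, int k, uvec& out, uvec& pool) {
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int j = 0; j < k; ++j) {
    int idx = j + (int)std::floor(unif_rand() * (n - j));
    if (idx >= n) idx = n - 1;
    std::swap(pool[j], pool[idx]);
    out[j] = pool[j];
  }
}

// Simulate one slice of the monitored pipeline and return the completed
// target-process slice: latent field draw (+ shift), per-process noise,
// per-process MCAR masking, then either multitask-EM imputation of the
// target (mode 0) or in-control-mean substitution (mode 1).
static void simulate_slice(const mat& cholU, const vec& shift, bool shifted,
                           int L, double noiseSd, int nmiss, const vec& mu0,
                           const mat& kj, const mat& kinv, double pi0,
                           double tau, double tol, int maxit, double s2min,
                           int mode, std::vector<vec>& xv,
                           std::vector<uvec>& ov, uvec& missbuf, uvec& pool,
                           vec& xhat) {
  const int n = cholU.n_cols;
  vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  vec xfield = cholU.t() * z;
  if (shifted) xfield += shift;
  uvec miss_target;
  vec x_target(n);
  for (int l = 0; l < L; ++l) {
    vec xl(n);
    for (int i = 0; i < n; ++i) xl[i] = xfield[i] + noiseSd * norm_rand();
    draw_missing(n, nmiss, missbuf, pool);
    uvec miss = sort(missbuf.head(nmiss));
    uvec keep(n - nmiss);
    int k2 = 0, mj = 0;
    for (int i = 0; i < n; ++i) {
      if (mj < nmiss && (int)miss[mj] == i) { ++mj; continue; }
      keep[k2++] = i;
    }
    ov[l] = keep;
    xv[l] = xl.elem(keep);
    if (l == 0) { miss_target = miss; x_target = xl; }
  }
  xhat = x_target;
  if (nmiss > 0) {
    if (mode == 1) {
      xhat.elem(miss_target) = mu0.elem(miss_target);
    } else {
      EmData d = make_data(xv, ov, kj, kinv, pi0, tau, s2min);
      EmWork ws;
      ws.init(d);
      EmState th;
      th.m = zeros<vec>(n);
      th.C = kj;
      th.s2 = 1.0;
      int evals;
      bool conv;
      std::vector<vec> alpha;
      if (!em_run(d, ws, th, tol, maxit, true, evals, conv, &alpha))
        stop("EM factorization failed beyond jitter repair");
      vec yhat = kj * alpha[0];
      xhat.elem(miss_target) = yhat.elem(miss_target);
    }
  }
}

// Simulate the monitored run until the global statistic exceeds hstop or
// `cap` steps have elapsed; returns the global-statistic trajectory.
// [[Rcpp::export]]
List cpp_run_traj(const arma::mat& cholU, const arma::vec& shift, int v,
                  int L, double noiseSd, int nmiss, const arma::vec& mu0,
                  const arma::mat& kj, const arma::mat& kinv, double pi0,
                  double tau, double tol, int maxit, double s2min,
                  const arma::mat& Bt, const arma::vec& offs, double hstop,
                  int cap, int mode) {
  RNGScope scope;
  const int n = cholU.n_cols;
  const int M = Bt.n_rows;
  vec S = zeros<vec>(M);
  vec U(cap);
  uvec missbuf(std::max(nmiss, 1)), pool(n);
  std::vector<vec> xv(L);
  std::vector<uvec> ov(L);
  vec xhat(n);
  bool alarm = false;
  int tlast = 0, argmax = 1;
  for (int t = 1; t <= cap; ++t) {
    simulate_slice(cholU, shift, v > 0 && t >= v, L, noiseSd, nmiss, mu0,
                   kj, kinv, pi0, tau, tol, maxit, s2min, mode, xv, ov,
                   missbuf, pool, xhat);
    vec inc = Bt * xhat - offs;
    S = clamp(S + inc, 0.0, datum::inf);
    uword am;
    double u = S.max(am);
    U[t - 1] = u;
    tlast = t;
    argmax = (int)am + 1;
    if (u > hstop) { alarm = true; break; }
  }
  return List::create(_["U"] = U.head(tlast), _["alarm"] = alarm,
                      _["argmax"] = argmax);
}

// In-control increment stream for regenerative calibration: `nsteps`
// i.i.d. slices through the full pipeline, returning the per-cluster
// likelihood-ratio increments (one column per step).
// [[Rcpp::export]]
arma::mat cpp_increment_stream(const arma::mat& cholU, int L,
                               double noiseSd, int nmiss,
                               const arma::vec& mu0, const arma::mat& kj,
                               const arma::mat& kinv, double pi0,
                               double tau, double tol, int maxit,
                               double s2min, const arma::mat& Bt,
                               const arma::vec& offs, int nsteps,
                               int mode) {
  RNGScope scope;
  const int n = cholU.n_cols;
  const int M = Bt.n_rows;
  mat out(M, nsteps);
  uvec missbuf(std::max(nmiss, 1)), pool(n);
  std::vector<vec> xv(L);
  std::vector<uvec> ov(L);
  vec xhat(n), zero = zeros<vec>(n);
  for (int t = 0; t < nsteps; ++t) {
    simulate_slice(cholU, zero, false, L, noiseSd, nmiss, mu0, kj, kinv,
                   pi0, tau, tol, maxit, s2min, mode, xv, ov, missbuf,
                   pool, xhat);
    out.col(t) = Bt * xhat - offs;
  }
  return out;
}

// Regenerative run lengths of the reflected CUSUM scan at threshold h:
// the CUSUM vector restarts from zero after every alarm, so the segment
// lengths between alarms are i.i.d. run lengths.  The final partial
// segment, if any, is returned as a censored tail.
// [[Rcpp::export]]
List cpp_segment_run_lengths(const arma::mat& inc, double h) {
  const int M = inc.n_rows;
  const int N = inc.n_cols;
  vec S = zeros<vec>(M);
  std::vector<int> lens;
  int seg = 0;
  for (int t = 0; t < N; ++t) {
    S += inc.col(t);
    S = clamp(S, 0.0, datum::inf);
    ++seg;
    if (S.max() > h) {
      lens.push_back(seg);
      seg = 0;
      S.zeros();
    }
  }
  return List::create(_["lengths"] = wrap(lens), _["tail"] = seg);
}

// Global-statistic trajectory of the never-resetting CUSUM scan over a
// stored increment stream (used to bracket the control limit: the
// largest value bounds every achievable threshold).
// [[Rcpp::export]]
arma::vec cpp_global_path(const arma::mat& inc) {
  const int M = inc.n_rows;
  const int N = inc.n_cols;
  vec S = zeros<vec>(M);
  vec U(N);
  for (int t = 0; t < N; ++t) {
    S += inc.col(t);
    S = clamp(S, 0.0, datum::inf);
    U[t] = S.max();
  }
  return U;
}
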