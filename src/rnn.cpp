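// Core numerics for the Elman network: forward rollout, backpropagation
// through time for the composite (position MSE + state cross-entropy) loss,
// and a gradient-descent fixed-point solver. Everything here is
// deterministic; all randomness lives on the R side.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline mat relu(const arma::mat& h) {
  mat out = h;
  out.elem(find(out < 0.0)).zeros();
  return out;
}

// in-place forward rollout into a preallocated cube (avoids per-step temporaries)
static void forward_into(cube& X, const mat& A, const mat& B, const vec& beta,
                         const mat& D, const vec& gamma,
                         const cube& U, const mat& Z) {
  const uword T = U.n_slices;
  X.slice(0) = D * Z;
  X.slice(0).each_col() += gamma;
  for (uword t = 0; t < T; ++t) {
    mat& Xn = X.slice(t + 1);
    Xn = A * X.slice(t);
    Xn += B * U.slice(t);
    Xn.each_col() += beta;
    double* p = Xn.memptr();
    const uword n = Xn.n_elem;
    for (uword i = 0; i < n; ++i) if (p[i] < 0.0) p[i] = 0.0;
  }
}

// Forward rollout of x_{t+1} = ReLU(A x_t + B u_t + beta) from x_0 = D z + gamma,
// with linear readout y_t = C x_t + alpha for t = 1..T.
// U: M x batch x T cube; Z: M0 x batch.
// Returns X (N x batch x T+1, slice 0 = x_0) and Y (L x batch x T).
// [[Rcpp::export]]
Rcpp::List rnn_forward_cpp(const arma::mat& A, const arma::mat& B, const arma::vec& beta,
                           const arma::mat& C, const arma::vec& alpha,
                           const arma::mat& D, const arma::vec& gamma,
                           const arma::cube& U, const arma::mat& Z) {
  const uword N = A.n_rows, batch = Z.n_cols, T = U.n_slices, L = C.n_rows;
  cube X(N, batch, T + 1);
  forward_into(X, A, B, beta, D, gamma, U, Z);
  // one big GEMM over all post-initial states
  const mat Xall(const_cast<double*>(X.memptr()) + N * batch, N, batch * T, false, true);
  mat Y = C * Xall;
  Y.each_col() += alpha;
  cube Ycube(Y.memptr(), L, batch, T);
  return Rcpp::List::create(Rcpp::Named("X") = X, Rcpp::Named("Y") = Ycube);
}

// Composite loss and (optionally) gradients for one batch.
// Tpos: 2*d x batch x T targets (sin, cos per spatial dimension);
// Tstate: T x batch integer matrix of 1-based state labels.
// Position term: mean squared error over all (2d, batch, T) elements.
// State term: mean categorical cross-entropy over (batch, T) steps.
// [[Rcpp::export]]
Rcpp::List rnn_loss_grad_cpp(const arma::mat& A, const arma::mat& B, const arma::vec& beta,
                             const arma::mat& C, const arma::vec& alpha,
                             const arma::mat& D, const arma::vec& gamma,
                             const arma::cube& U, const arma::mat& Z,
                             const arma::cube& Tpos, const arma::imat& Tstate,
                             const bool want_grad = true) {
  const uword N = A.n_rows, M = B.n_cols, batch = Z.n_cols, T = U.n_slices;
  const uword L = C.n_rows, twod = Tpos.n_rows, K = L - twod;

  cube X(N, batch, T + 1);
  forward_into(X, A, B, beta, D, gamma, U, Z);

  const uword S = batch * T;  // total graded steps
  const mat Xall(const_cast<double*>(X.memptr()) + N * batch, N, S, false, true);
  const mat TposAll(const_cast<double*>(Tpos.memptr()), twod, S, false, true);

  mat Y = C * Xall;
  Y.each_col() += alpha;

  // position mean squared error
  mat dpos = Y.rows(0, twod - 1) - TposAll;
  const double loss_pos = accu(square(dpos)) / double(twod * S);

  // state cross-entropy via log-sum-exp
  mat logits = Y.rows(twod, L - 1);
  rowvec mx = max(logits, 0);
  logits.each_row() -= mx;
  mat ex = exp(logits);
  rowvec se = sum(ex, 0);
  double xent = 0.0;
  for (uword t = 0; t < T; ++t) {
    for (uword b = 0; b < batch; ++b) {
      const uword s = t * batch + b;
      xent += std::log(se(s)) - logits(uword(Tstate(t, b)) - 1, s);
    }
  }
  const double loss_state = xent / double(S);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("total") = loss_pos + loss_state,
      Rcpp::Named("position_mse") = loss_pos,
      Rcpp::Named("state_xent") = loss_state);
  if (!want_grad) return out;

  // dL/dY
  mat dY(L, S);
  dY.rows(0, twod - 1) = (2.0 / double(twod * S)) * dpos;
  mat soft = ex.each_row() / se;  // softmax
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < batch; ++b)
      soft(uword(Tstate(t, b)) - 1, t * batch + b) -= 1.0;
  dY.rows(twod, L - 1) = soft / double(S);

  mat dC = dY * Xall.t();
  vec dalpha = sum(dY, 1);
  mat dXout = C.t() * dY;  // N x S

  // backward through time; per-step GEMM accumulation of the weight gradients
  mat dA(N, N, fill::zeros), dB(N, M, fill::zeros);
  vec dbeta(N, fill::zeros);
  mat delta(N, batch), carry(N, batch, fill::zeros);
  const mat At = A.t();
  const uword nb = N * batch;
  for (uword t = T; t-- > 0;) {
    double* pd = delta.memptr();
    const double* po = dXout.memptr() + t * nb;
    const double* pc = carry.memptr();
    const double* px = X.memptr() + (t + 1) * nb;  // ReLU subgradient (0 at kink)
    for (uword i = 0; i < nb; ++i) pd[i] = (px[i] > 0.0) ? po[i] + pc[i] : 0.0;
    dA += delta * X.slice(t).t();
    dB += delta * U.slice(t).t();
    dbeta += sum(delta, 1);
    carry = At * delta;
  }
  mat dD = carry * Z.t();  // x_0 is linear in D, gamma
  vec dgamma = sum(carry, 1);

  out["grad"] = Rcpp::List::create(
      Rcpp::Named("A") = dA, Rcpp::Named("B") = dB, Rcpp::Named("beta") = dbeta,
      Rcpp::Named("C") = dC, Rcpp::Named("alpha") = dalpha,
      Rcpp::Named("D") = dD, Rcpp::Named("gamma") = dgamma);
  return out;
}

// Fixed points of x -> ReLU(A x + beta) (zero input): minimize
// q(x) = ||x - ReLU(A x + beta)||^2 from each column of `inits` by damped
// Gauss-Newton (Levenberg-Marquardt). The residual r(x) = x - ReLU(Ax+beta)
// is piecewise linear with Jacobian J = I - diag(g) A on each active set
// (g = pre-activation > 0), so Gauss-Newton steps are exact within a
// region and the damping handles active-set crossings. Deterministic.
// [[Rcpp::export]]
Rcpp::List find_fixed_points_cpp(const arma::mat& A, const arma::vec& beta, const arma::mat& inits,
                                 const double tol = 1e-8,
                                 const int max_iter = 10000) {
  const uword N = A.n_rows, n = inits.n_cols;
  mat sol(N, n);
  vec resid(n);
  ivec iters(n);
  const mat I = eye(N, N);

  for (uword j = 0; j < n; ++j) {
    vec x = inits.col(j);
    vec h = A * x + beta;
    vec r = x - relu(h);
    double q = dot(r, r);
    double lambda = 1e-4;
    int it = 0;
    while (it < max_iter && q >= tol) {
      ++it;
      // Jacobian of the residual on the current active set
      mat J = A;
      for (uword i = 0; i < N; ++i) {
        if (h(i) <= 0.0) J.row(i).zeros();
      }
      J = I - J;
      mat JtJ = J.t() * J;
      vec Jtr = J.t() * r;
      bool accepted = false;
      vec xn, hn, rn;
      double qn = q;
      for (int tries = 0; tries < 40; ++tries) {
        vec dx;
        const bool ok = solve(dx, JtJ + lambda * I, -Jtr,
                              solve_opts::likely_sympd + solve_opts::no_approx);
        if (ok) {
          xn = x + dx;
          hn = A * xn + beta;
          rn = xn - relu(hn);
          qn = dot(rn, rn);
          if (qn < q) { accepted = true; break; }
        }
        lambda *= 10.0;
        if (lambda > 1e12) break;
      }
      if (!accepted) break;
      lambda = std::max(lambda * 0.25, 1e-12);
      const double drop = q - qn;
      x = xn; h = hn; r = rn; q = qn;
      if (drop < 1e-16 * (q + 1e-300) && q >= tol) break;  // stalled
    }
    sol.col(j) = x;
    resid(j) = q;
    iters(j) = it;
  }
  return Rcpp::List::create(Rcpp::Named("states") = sol,
                            Rcpp::Named("residual") = resid,
                            Rcpp::Named("iterations") = iters);
}
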