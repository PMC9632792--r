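// Simulation core: steady-state network solver, stochastic structural
// plasticity steps (top-k and resource-pool variants), and the training loop.
// All randomness is drawn from R's RNG stream (unif_rand) so that results are
// reproducible from set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void rectify(arma::vec& x) {
  x.for_each([](double& v) { if (v < 0) v = 0; });
}

// Resilience phi(G) = [G - G0]_+ (G - G1)
static inline double phi_fun(double G, double G0, double G1) {
  double a = G - G0;
  return a > 0 ? a * (G - G1) : 0.0;
}

// Pool-dependent resilience: formation term scaled by pool fill-level minus a
// pool-independent removal term.
static inline double phi_tilde_fun(double G, double P, double kf, double rf,
                                   double kr, double rr, double R0, double P0) {
  double form = (std::tanh(kf * (G - rf)) + 1.0 + R0) * (P / P0);
  double rem = (std::tanh(kr * (G - rr)) + 1.0) / 2.0 + R0;
  return form - rem;
}

// Integrate tau_M dM/dt = -M + [tanh(S - gamma W G)]_+ with instantaneous
// G = [W^T M - g_thr]_+ until max|dM/dt| < tol. Explicit stepping with an
// adaptive step: the step is halved whenever the residual stops decreasing
// (the rectifiers can induce slowly-decaying flip-flop modes at full step).
static bool steady_state(const arma::vec& S, const arma::mat& W, double gamma,
                         double g_thr, double tau_M, double h0, double tol,
                         double t_max, arma::vec& M, arma::vec& G, int& iters) {
  double h = h0, last = arma::datum::inf, t = 0.0;
  iters = 0;
  for (;;) {
    G = W.t() * M - g_thr;
    rectify(G);
    arma::vec F = arma::tanh(S - gamma * (W * G));
    rectify(F);
    arma::vec dM = (F - M) / tau_M;
    double res = arma::abs(dM).max();
    if (res < tol) return true;
    if (t > t_max) return false;
    if (res > 0.97 * last)
      h = std::max(h * 0.5, 0.01 * tau_M);
    else
      h = std::min(h * 1.1, h0);  // recover once the residual shrinks again
    last = res;
    M += h * dM;
    t += h;
    ++iters;
  }
}

// [[Rcpp::export]]
List cpp_solve_ss(const arma::vec& S, const arma::mat& W, double gamma,
                  double g_thr, double tau_M, Nullable<NumericVector> M0,
                  double h0, double tol, double t_max) {
  arma::vec M;
  if (M0.isNotNull()) {
    M = as<arma::vec>(M0);
  } else {
    M = arma::tanh(S);
    rectify(M);
  }
  arma::vec G;
  int iters = 0;
  bool ok = steady_state(S, W, gamma, g_thr, tau_M, h0, tol, t_max, M, G, iters);
  return List::create(_["M"] = M, _["G"] = G, _["converged"] = ok,
                      _["iterations"] = iters);
}

// Remove the (deg - k) synapses with the smallest R on column j; ties broken
// uniformly at random. Removed rows are flagged in `blocked` (if given) so the
// learning sub-step does not recreate them, and appended to `removed`.
static void topk_column(arma::mat& W, int j, const arma::vec& Rcol, int k,
                        int& degj, std::vector<char>* blocked,
                        std::vector<std::pair<int, int>>* removed) {
  int nmc = W.n_rows;
  std::vector<std::tuple<double, double, int>> syn;
  syn.reserve(degj);
  for (int i = 0; i < nmc; ++i)
    if (W(i, j) != 0) syn.emplace_back(Rcol[i], unif_rand(), i);
  std::sort(syn.begin(), syn.end());
  int nrem = degj - k;
  for (int m = 0; m < nrem; ++m) {
    int i = std::get<2>(syn[m]);
    W(i, j) = 0;
    if (blocked) (*blocked)[i] = 1;
    if (removed) removed->emplace_back(i, j);
  }
  degj = k;
}

// [[Rcpp::export]]
List cpp_apply_topk(arma::mat W, const arma::mat& Rmat, int k) {
  int ngc = W.n_cols;
  std::vector<std::pair<int, int>> removed;
  for (int j = 0; j < ngc; ++j) {
    int degj = (int)arma::accu(W.col(j));
    if (degj > k) topk_column(W, j, Rmat.col(j), k, degj, nullptr, &removed);
  }
  IntegerMatrix rem(removed.size(), 2);
  for (size_t m = 0; m < removed.size(); ++m) {
    rem(m, 0) = removed[m].first + 1;  // 1-based for R
    rem(m, 1) = removed[m].second + 1;
  }
  return List::create(_["W"] = W, _["removed"] = rem);
}

// Scan rows 0..n-1 and emit row i with probability p_i = 1 - exp(-c * M_i)
// for eligible rows. Uses geometric skip-sampling under the uniform bound
// p_max = 1 - exp(-c * max M): exact thinning, O(#events) RNG draws instead
// of one draw per row, which matters since per-trial event probabilities are
// typically ~1e-3.
template <class Pred, class Emit>
static void bernoulli_scan(int n, const arma::vec& M, double c, double m_max,
                           Pred eligible, Emit emit) {
  double p_max = 1.0 - std::exp(-c * m_max);
  if (p_max <= 0) return;
  if (p_max > 0.999999) {  // bound useless; plain per-row draws
    for (int i = 0; i < n; ++i)
      if (eligible(i) && M[i] > 0 &&
          unif_rand() < 1.0 - std::exp(-c * M[i]))
        emit(i);
    return;
  }
  const double lq = std::log1p(-p_max);
  int i = -1;
  for (;;) {
    double u = unif_rand();
    if (u <= 0) u = DBL_MIN;
    double ds = std::log(u) / lq;
    if (ds > (double)n + 1.0) return;
    i += 1 + (int)ds;
    if (i >= n) return;
    if (!eligible(i) || M[i] <= 0) continue;
    double p = 1.0 - std::exp(-c * M[i]);
    if (unif_rand() * p_max < p) emit(i);
  }
}

// One top-k plasticity step given the steady-state activities: homeostasis
// (top-k per GC), then stochastic formation/removal, never recreating a
// synapse removed by homeostasis in the same step.
static void step_topk(arma::mat& W, arma::ivec& deg, const arma::vec& M,
                      const arma::vec& G, double G0, double G1, double lambda_f,
                      double lambda_r, double dt, int k) {
  int nmc = W.n_rows, ngc = W.n_cols;
  double m_max = M.max();
  std::vector<char> blocked(nmc);
  for (int j = 0; j < ngc; ++j) {
    double ph = phi_fun(G[j], G0, G1);
    bool over = deg[j] > k;
    if (!over && ph == 0.0) continue;
    std::fill(blocked.begin(), blocked.end(), 0);
    if (over) {
      int degj = deg[j];
      arma::vec Rcol = M * ph;
      topk_column(W, j, Rcol, k, degj, &blocked, nullptr);
      deg[j] = degj;
    }
    if (ph > 0) {
      double c = lambda_f * ph * dt;
      bernoulli_scan(nmc, M, c, m_max,
                     [&](int i) { return W(i, j) == 0 && !blocked[i]; },
                     [&](int i) { W(i, j) = 1; ++deg[j]; });
    } else if (ph < 0) {
      double c = lambda_r * (-ph) * dt;
      bernoulli_scan(nmc, M, c, m_max,
                     [&](int i) { return W(i, j) != 0; },
                     [&](int i) { W(i, j) = 0; --deg[j]; });
    }
  }
}

// One resource-pool plasticity step. Formation consumes one pool unit per
// synapse and is suppressed once the pool is empty (a random subset of the
// accepted candidates is kept if more formations are drawn than the pool can
// fund); removal returns the unit to the pool.
static void step_pool(arma::mat& W, arma::ivec& deg, arma::ivec& P,
                      const arma::vec& M, const arma::vec& G, double lambda_f,
                      double lambda_r, double dt, double kf, double rf,
                      double kr, double rr, double R0, double P0) {
  int nmc = W.n_rows, ngc = W.n_cols;
  double m_max = M.max();
  std::vector<int> cand;
  for (int j = 0; j < ngc; ++j) {
    double ph = phi_tilde_fun(G[j], (double)P[j], kf, rf, kr, rr, R0, P0);
    if (ph > 0) {
      if (P[j] <= 0) continue;
      double c = lambda_f * ph * dt;
      cand.clear();
      bernoulli_scan(nmc, M, c, m_max,
                     [&](int i) { return W(i, j) == 0; },
                     [&](int i) { cand.push_back(i); });
      int nform = std::min((int)cand.size(), (int)P[j]);
      if ((int)cand.size() > nform) {
        for (int m = 0; m < nform; ++m) {  // partial Fisher-Yates
          int pick = m + (int)(unif_rand() * (cand.size() - m));
          if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
          std::swap(cand[m], cand[pick]);
        }
      }
      for (int m = 0; m < nform; ++m) W(cand[m], j) = 1;
      deg[j] += nform;
      P[j] -= nform;
    } else if (ph < 0) {
      double c = lambda_r * (-ph) * dt;
      int nrem = 0;
      bernoulli_scan(nmc, M, c, m_max,
                     [&](int i) { return W(i, j) != 0; },
                     [&](int i) { W(i, j) = 0; ++nrem; });
      deg[j] -= nrem;
      P[j] += nrem;
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_step_topk(arma::mat W, const arma::vec& M, const arma::vec& G,
                        double G0, double G1, double lambda_f, double lambda_r,
                        double dt, int k) {
  arma::ivec deg = arma::conv_to<arma::ivec>::from(
      arma::sum(W, 0).t());
  step_topk(W, deg, M, G, G0, G1, lambda_f, lambda_r, dt, k);
  return W;
}

// [[Rcpp::export]]
List cpp_step_pool(arma::mat W, arma::ivec P, const arma::vec& M,
                   const arma::vec& G, double lambda_f, double lambda_r,
                   double dt, double kf, double rf, double kr, double rr,
                   double R0, double P0) {
  arma::ivec deg = arma::conv_to<arma::ivec>::from(arma::sum(W, 0).t());
  step_pool(W, deg, P, M, G, lambda_f, lambda_r, dt, kf, rf, kr, rr, R0, P0);
  return List::create(_["W"] = W, _["P"] = P);
}

// Training loop. `schedule` holds 1-based column indices into `stimuli`, one
// per trial. Steady-state solves are warm-started per stimulus. Probe
// activities (columns of `probes`) are recorded before the first trial, after
// every `stride` trials, and after the last trial.
// [[Rcpp::export]]
List cpp_train(arma::mat W, const arma::mat& stimuli,
               const IntegerVector& schedule, const arma::mat& probes,
               int stride, double gamma, double g_thr, double tau_M, double G0,
               double G1, double lambda_f, double lambda_r, double dt, int k,
               double h0, double tol, double t_max, int variant, double kf,
               double rf, double kr, double rr, double R0, double P0,
               int P_all) {
  const int n_steps = schedule.size();
  const int n_stim = stimuli.n_cols;
  const int n_probe = probes.n_cols;
  const int nmc = W.n_rows, ngc = W.n_cols;

  arma::ivec deg = arma::conv_to<arma::ivec>::from(arma::sum(W, 0).t());
  arma::ivec P(ngc, arma::fill::zeros);
  if (variant == 1)
    for (int j = 0; j < ngc; ++j) P[j] = P_all - deg[j];

  // warm-start caches
  arma::mat Mstim(nmc, n_stim);
  std::vector<char> stim_init(n_stim, 0);
  arma::mat Mprobe(nmc, n_probe);
  std::vector<char> probe_init(n_probe, 0);

  std::vector<int> rec_steps;
  rec_steps.push_back(0);
  for (int s = stride; s <= n_steps; s += stride) rec_steps.push_back(s);
  if (rec_steps.back() != n_steps) rec_steps.push_back(n_steps);
  const int n_rec = rec_steps.size();

  arma::cube rec(nmc, std::max(n_probe, 1), n_rec, arma::fill::zeros);
  arma::imat deg_rec(ngc, n_rec);
  arma::imat pool_rec;
  if (variant == 1) pool_rec.set_size(ngc, n_rec);

  arma::vec M, G;
  int iters = 0;
  long total_iters = 0;

  auto record = [&](int r) {
    for (int p = 0; p < n_probe; ++p) {
      arma::vec Mp;
      if (probe_init[p]) {
        Mp = Mprobe.col(p);
      } else {
        Mp = arma::tanh(probes.col(p));
        rectify(Mp);
      }
      arma::vec Gp;
      int its = 0;
      if (!steady_state(probes.col(p), W, gamma, g_thr, tau_M, h0, tol, t_max,
                        Mp, Gp, its))
        stop("steady state did not converge for probe stimulus %d", p + 1);
      total_iters += its;
      Mprobe.col(p) = Mp;
      probe_init[p] = 1;
      rec.slice(r).col(p) = Mp;
    }
    deg_rec.col(r) = deg;
    if (variant == 1) pool_rec.col(r) = P;
  };

  int r = 0;
  record(r++);
  for (int s = 1; s <= n_steps; ++s) {
    int idx = schedule[s - 1] - 1;
    if (idx < 0 || idx >= n_stim) stop("schedule index out of range");
    if (stim_init[idx]) {
      M = Mstim.col(idx);
    } else {
      M = arma::tanh(stimuli.col(idx));
      rectify(M);
    }
    if (!steady_state(stimuli.col(idx), W, gamma, g_thr, tau_M, h0, tol, t_max,
                      M, G, iters))
      stop("steady state did not converge for stimulus %d at step %d", idx + 1,
           s);
    total_iters += iters;
    Mstim.col(idx) = M;
    stim_init[idx] = 1;

    if (variant == 1)
      step_pool(W, deg, P, M, G, lambda_f, lambda_r, dt, kf, rf, kr, rr, R0,
                P0);
    else
      step_topk(W, deg, M, G, G0, G1, lambda_f, lambda_r, dt, k);

    if (r < n_rec && s == rec_steps[r]) record(r++);
    if (s % 256 == 0) checkUserInterrupt();
  }

  List out = List::create(
      _["W"] = W, _["probe_rates"] = rec,
      _["steps"] = IntegerVector(rec_steps.begin(), rec_steps.end()),
      _["degrees"] = deg_rec, _["solver_iterations"] = (double)total_iters);
  if (variant == 1) out["pool"] = pool_rec;
  return out;
}
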