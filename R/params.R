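#' Model parameters for the mitral-cell/granule-cell network
#'
#' Bundles every scalar parameter of the firing-rate network and its
#' structural-plasticity rule. Defaults are the standard simulation values
#' used throughout the package.
#'
#' @param n_mc Number of mitral cells (MCs), i.e. input channels.
#' @param n_gc Number of granule cells (GCs).
#' @param n_conn Initial number of synapses per GC.
#' @param k Maximum number of synapses a GC may keep under top-k competition.
#'   Must satisfy `n_conn <= k <= n_mc`.
#' @param tau_m,tau_g Membrane time constants of MCs and GCs (dimensionless
#'   time units). GC dynamics are treated as instantaneous (`tau_g = 0`), so
#'   the GC rates are slaved to the MC rates.
#' @param dt Duration of one plasticity trial (one odor presentation).
#' @param g_thr GC firing threshold.
#' @param gamma Inhibitory weight of each GC-to-MC synapse.
#' @param g0,g1 Lower and upper thresholds of the resilience function
#'   \eqn{\phi(G) = [G - G^{(0)}]_+ (G - G^{(1)})}: below `g0` spines are
#'   inert, between `g0` and `g1` they are removed, above `g1` they form.
#' @param lambda_f,lambda_r Poisson rates of synapse formation and removal.
#' @param theta Response threshold used to classify MCs as responsive or
#'   divergent.
#' @param rng_seed Optional integer seed; when set, training runs seeded with
#'   these parameters are bit-reproducible.
#' @param solver_h Initial time step of the steady-state integrator, in units
#'   of `tau_m`.
#' @param solver_tol Convergence tolerance on `max |dM/dt|`.
#' @param solver_t_max Integration horizon in units of `tau_m` (counted along
#'   the adaptive steps); exceeding it
#'   raises an error naming the stimulus.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$g_thr
#' small <- model_params(n_mc = 10, n_gc = 20, n_conn = 3, k = 4)
#' @export
model_params <- function(n_mc = 240, n_gc = 1000, n_conn = 60, k = 66,
                         tau_m = 1, tau_g = 0, dt = 1, g_thr = 4.4,
                         gamma = 5e-4, g0 = 1, g1 = 4, lambda_f = 6e-4,
                         lambda_r = 6e-3, theta = 0.2, rng_seed = NULL,
                         solver_h = 0.5, solver_tol = 1e-6,
                         solver_t_max = 500) {
  p <- list(n_mc = as.integer(n_mc), n_gc = as.integer(n_gc),
            n_conn = as.integer(n_conn), k = as.integer(k), tau_m = tau_m,
            tau_g = tau_g, dt = dt, g_thr = g_thr, gamma = gamma, g0 = g0,
            g1 = g1, lambda_f = lambda_f, lambda_r = lambda_r, theta = theta,
            rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
            solver_h = solver_h, solver_tol = solver_tol,
            solver_t_max = solver_t_max)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  stopifnot(p$n_mc > 0, p$n_gc > 0, p$n_conn > 0)
  if (!(p$n_conn <= p$k && p$k <= p$n_mc))
    stop("need n_conn <= k <= n_mc, got n_conn = ", p$n_conn, ", k = ", p$k,
         ", n_mc = ", p$n_mc)
  if (!(p$g0 >= 0 && p$g0 < p$g1))
    stop("need 0 <= g0 < g1, got g0 = ", p$g0, ", g1 = ", p$g1)
  stopifnot(p$gamma >= 0, p$lambda_f >= 0, p$lambda_r >= 0, p$tau_m > 0,
            p$tau_g >= 0, p$dt >= 0, p$theta > 0, p$solver_tol > 0,
            p$solver_h > 0, p$solver_t_max > 0)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", x$n_mc, " MCs x ", x$n_gc,
      " GCs; n_conn = ", x$n_conn, ", k = ", x$k, "\n", sep = "")
  cat("  g_thr = ", x$g_thr, ", gamma = ", format(x$gamma),
      ", G(0) = ", x$g0, ", G(1) = ", x$g1, "\n", sep = "")
  cat("  lambda_f = ", format(x$lambda_f), ", lambda_r = ",
      format(x$lambda_r), ", dt = ", x$dt, ", theta = ", x$theta, "\n",
      sep = "")
  invisible(x)
}

#' Parameters of the resource-pool competition model
#'
#' The resource-pool variant replaces the hard top-k competition by a per-GC
#' finite resource: forming a synapse consumes one unit, removing one returns
#' it, and the formation term of the pool-dependent resilience
#' \eqn{\tilde\phi(G, P)} is proportional to the fill-level `P`. The
#' equilibrium fill-level `p0` sets the degree each GC relaxes to under
#' spontaneous input: total resource `p_all = n_conn + p0`.
#'
#' @param kappa_form,kappa_rem Slopes of the sigmoidal formation and removal
#'   terms.
#' @param r_form,r_rem Half-activation GC rates of the two terms.
#' @param r0 Baseline offset shared by both terms.
#' @param p0 Equilibrium pool size (in synapse units).
#' @param dt Trial duration override for pool runs.
#' @param gamma Inhibitory strength override for pool runs.
#' @param lambda_f,lambda_r Formation/removal rate overrides for pool runs.
#'
#' @return An object of class `resource_params`.
#' @examples
#' rp <- resource_params()
#' phi_tilde(0, p = rp$p0, rp) # ~0 at equilibrium with no GC activity
#' @export
resource_params <- function(kappa_form = 2.5, kappa_rem = 5, r_form = 2,
                            r_rem = 1, r0 = 0.8, p0 = 20, dt = 1,
                            gamma = 4.2e-4, lambda_f = 1, lambda_r = 1) {
  stopifnot(p0 > 0, lambda_f >= 0, lambda_r >= 0, dt >= 0, gamma >= 0)
  structure(list(kappa_form = kappa_form, kappa_rem = kappa_rem,
                 r_form = r_form, r_rem = r_rem, r0 = r0, p0 = p0, dt = dt,
                 gamma = gamma, lambda_f = lambda_f, lambda_r = lambda_r),
            class = "resource_params")
}

#' @export
print.resource_params <- function(x, ...) {
  cat("<resource_params> kappa_form = ", x$kappa_form, ", kappa_rem = ",
      x$kappa_rem, ", r_form = ", x$r_form, ", r_rem = ", x$r_rem, "\n",
      "  R0 = ", x$r0, ", P0 = ", x$p0, ", gamma = ", format(x$gamma),
      ", lambda_f = ", x$lambda_f, ", lambda_r = ", x$lambda_r, "\n",
      sep = "")
  invisible(x)
}
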