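#' Pool-dependent resilience function
#'
#' Resilience of a spine under resource-pool competition,
#' \deqn{\tilde\phi(G, P) = \left[\tanh(\kappa_{form}(G - r_{form})) + 1 +
#' R_0\right] \frac{P}{P_0} - \left[\frac{\tanh(\kappa_{rem}(G - r_{rem})) +
#' 1}{2} + R_0\right].}
#' The formation term scales with the pool fill-level `p`, so a depleted pool
#' (`p < p0`) biases the cell toward removal and a full one toward formation
#' at identical GC activity — a sliding formation threshold.
#'
#' @param g Nonnegative GC rate (vectorized).
#' @param p Pool fill-level (vectorized, recycled against `g`).
#' @param rp A [resource_params()] object.
#' @return Resilience value(s).
#' @examples
#' rp <- resource_params()
#' phi_tilde(0, rp$p0, rp) # ~0: equilibrium
#' @export
phi_tilde <- function(g, p, rp) {
  form <- (tanh(rp$kappa_form * (g - rp$r_form)) + 1 + rp$r0) * (p / rp$p0)
  rem <- (tanh(rp$kappa_rem * (g - rp$r_rem)) + 1) / 2 + rp$r0
  form - rem
}

#' Effective plasticity thresholds of the resource-pool model
#'
#' The roots \eqn{\tilde G^{(0)} < \tilde G^{(1)}} of
#' \eqn{\tilde\phi(G, P) = 0}, found by bracketed root-finding on a grid scan.
#' As the pool empties (`p` decreases), \eqn{\tilde G^{(1)}} rises, making
#' further formation harder; \eqn{\tilde G^{(0)}} moves the opposite way
#' until it reaches zero: once \eqn{\tilde\phi(0, P) < 0} (any pool level
#' noticeably below `p0`) removal is active already at zero GC activity and
#' only the formation threshold \eqn{\tilde G^{(1)}} remains (`g0` is `NA`).
#'
#' @param p Pool fill-level.
#' @param rp A [resource_params()] object.
#' @param g_max Upper end of the scanned GC-rate range.
#' @return Named numeric vector `c(g0 = ..., g1 = ...)`; `g0` is `NA` in the
#'   single-root regime.
#' @export
effective_thresholds <- function(p, rp, g_max = 50) {
  f <- function(g) phi_tilde(g, p, rp)
  grid <- seq(0, g_max, length.out = 2001)
  fv <- f(grid)
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root, numeric(1))
  roots <- sort(unique(c(roots, grid[fv == 0])))
  if (length(roots) == 0 || length(roots) > 2)
    stop("effective_thresholds: found ", length(roots),
         " roots of phi_tilde in [0, ", g_max,
         "] (no-root or unexpected parameter regime)")
  if (length(roots) == 1) c(g0 = NA_real_, g1 = roots[1])
  else c(g0 = roots[1], g1 = roots[2])
}

#' Resource state of the granule cells
#'
#' Tracks each GC's pool fill-level `p` and the (shared) total resource
#' `p_all`. Conservation `p_j + degree_j = p_all` holds exactly at every
#' step; at initialization `p_all = n_conn + p0`.
#'
#' @param W Binary connectivity matrix.
#' @param params A [model_params()] object (supplies `n_conn`).
#' @param rp A [resource_params()] object (supplies `p0`).
#' @return A `resource_state` object with integer vector `p` and scalar
#'   `p_all`.
#' @export
resource_state <- function(W, params, rp) {
  p_all <- params$n_conn + rp$p0
  p <- p_all - colSums(W)
  if (any(p < 0))
    stop("resource_state: some GC carries more synapses than p_all")
  structure(list(p = as.integer(p), p_all = as.integer(p_all)),
            class = "resource_state")
}

#' @export
print.resource_state <- function(x, ...) {
  cat("<resource_state> ", length(x$p), " GCs, p_all = ", x$p_all,
      ", pool range [", min(x$p), ", ", max(x$p), "]\n", sep = "")
  invisible(x)
}

#' One structural-plasticity trial under resource-pool competition
#'
#' Same stochastic formation/removal machinery as [plasticity_step()] but
#' with \eqn{R_{ij} = M_i \tilde\phi(G_j, P_j)} and no top-k pruning: each
#' formation consumes one pool unit (formation is suppressed on a GC whose
#' pool is empty), each removal returns one. The trial uses the pool-model
#' overrides for `gamma`, `dt` and the event rates.
#'
#' @param W Binary connectivity matrix.
#' @param state A [resource_state()] object.
#' @param S Stimulus vector.
#' @param params A [model_params()] object.
#' @param rp A [resource_params()] object.
#' @param stimulus_id Optional label for error messages.
#' @return List with updated `W` and `state`.
#' @export
pool_step <- function(W, state, S, params, rp, stimulus_id = NULL) {
  pp <- params
  pp$gamma <- rp$gamma
  st <- solve_steady_state(S, W, pp, stimulus_id = stimulus_id)
  res <- cpp_step_pool(W, state$p, st$M, st$G, rp$lambda_f, rp$lambda_r,
                       rp$dt, rp$kappa_form, rp$r_form, rp$kappa_rem,
                       rp$r_rem, rp$r0, rp$p0)
  state$p <- as.integer(res$P)
  list(W = res$W, state = state)
}
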