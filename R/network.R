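#' MC activation function
#'
#' Saturating rectified activation of the mitral cells,
#' \eqn{F_M(x) = [\tanh(x)]_+}. MC firing rates therefore lie in `[0, 1)`.
#'
#' @param x Numeric vector of net inputs.
#' @return Numeric vector of rates in `[0, 1)`.
#' @examples
#' mc_activation(c(-5, 0, 1))
#' @export
mc_activation <- function(x) {
  if (!all(is.finite(x))) stop("mc_activation: input must be finite")
  pmax(tanh(x), 0)
}

#' GC activation function
#'
#' Piecewise-linear rectifier used by the granule cells,
#' \eqn{F_G(x) = [x]_+}.
#'
#' @param x Numeric vector of net inputs.
#' @return Numeric vector of nonnegative rates.
#' @export
gc_activation <- function(x) {
  if (!all(is.finite(x))) stop("gc_activation: input must be finite")
  pmax(x, 0)
}

#' Instantaneous GC response to a pattern of MC activity
#'
#' With the GC membrane time constant set to zero the GC rates are slaved to
#' the MC rates: \eqn{G = [W^T M - g_{thr}]_+}.
#'
#' @param W Binary connectivity matrix, MCs in rows, GCs in columns.
#' @param M MC firing-rate vector (length `nrow(W)`).
#' @param g_thr GC firing threshold.
#' @return GC firing-rate vector of length `ncol(W)`.
#' @examples
#' W <- matrix(c(1, 1, 0, 1), 2, 2)
#' gc_response(W, c(0.5, 0.8), g_thr = 0.6)
#' @export
gc_response <- function(W, M, g_thr) {
  if (length(M) != nrow(W))
    stop("gc_response: length(M) = ", length(M), " but nrow(W) = ", nrow(W))
  as.vector(gc_activation(crossprod(W, M) - g_thr))
}

#' Random initial connectivity
#'
#' Draws a binary MC-by-GC adjacency matrix in which every GC (column) is
#' connected to exactly `n_conn` uniformly chosen MCs, the initial condition
#' of every simulation.
#'
#' @param params A [model_params()] object.
#' @return Binary matrix of dimension `n_mc` x `n_gc`.
#' @examples
#' set.seed(1)
#' W <- init_connectivity(model_params(n_mc = 10, n_gc = 5, n_conn = 3, k = 4))
#' colSums(W)
#' @export
init_connectivity <- function(params) {
  W <- matrix(0, params$n_mc, params$n_gc)
  for (j in seq_len(params$n_gc))
    W[sample.int(params$n_mc, params$n_conn), j] <- 1
  W
}

#' Steady-state network response to a stimulus
#'
#' Integrates the MC rate equation
#' \eqn{\tau_M \, dM/dt = -M + F_M(S - \gamma W G)} with the instantaneous GC
#' response \eqn{G = [W^T M - g_{thr}]_+} until `max |dM/dt|` falls below
#' `params$solver_tol`. The explicit integrator adapts its step: whenever the
#' residual stops decreasing the step is halved, which damps the flip-flop
#' modes that the two rectifiers can produce near threshold.
#'
#' @param S Nonnegative stimulus vector of length `n_mc`.
#' @param W Binary connectivity matrix.
#' @param params A [model_params()] object.
#' @param M0 Optional warm-start MC rate vector.
#' @param stimulus_id Optional label stored in the result (used in error
#'   messages and downstream bookkeeping).
#' @return A `network_state` object: list with MC rates `M`, GC rates `G` and
#'   `stimulus_id`.
#' @examples
#' p <- model_params(n_mc = 4, n_gc = 3, n_conn = 2, k = 3)
#' W <- matrix(0, 4, 3)
#' st <- solve_steady_state(rep(0.5, 4), W, p)
#' all.equal(st$M, rep(tanh(0.5), 4))
#' @export
solve_steady_state <- function(S, W, params, M0 = NULL, stimulus_id = NULL) {
  if (length(S) != nrow(W))
    stop("solve_steady_state: length(S) = ", length(S), " but nrow(W) = ",
         nrow(W))
  if (any(!is.finite(S)) || any(S < 0))
    stop("solve_steady_state: stimulus must be finite and nonnegative")
  res <- cpp_solve_ss(S, W, params$gamma, params$g_thr, params$tau_m,
                      M0, params$solver_h * params$tau_m, params$solver_tol,
                      params$solver_t_max * params$tau_m)
  if (!res$converged)
    stop("solve_steady_state: no convergence within t_max = ",
         params$solver_t_max, " tau_M for stimulus '",
         if (is.null(stimulus_id)) "<unnamed>" else stimulus_id, "'")
  network_state(as.vector(res$M), as.vector(res$G), stimulus_id)
}

network_state <- function(M, G, stimulus_id = NULL) {
  structure(list(M = M, G = G, stimulus_id = stimulus_id),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> stimulus:",
      if (is.null(x$stimulus_id)) "<unnamed>" else x$stimulus_id, "\n")
  cat("  M:", length(x$M), "MCs, mean", signif(mean(x$M), 4),
      "| G:", length(x$G), "GCs,", sum(x$G > 0), "active\n")
  invisible(x)
}

#' Effective MC-MC connectivity
#'
#' Computes \eqn{W^{(mm)} = W W^T}. The off-diagonal entry `(i, j)` counts
#' the GCs connected to both MC `i` and MC `j`, i.e. the strength of their
#' mutual disynaptic inhibition. The diagonal holds each MC's GC degree; it
#' is kept in the matrix but ignored by the block-structure analyses.
#'
#' @param W Binary connectivity matrix.
#' @return Symmetric integer matrix `n_mc` x `n_mc`.
#' @examples
#' W <- cbind(c(1, 1, 0), c(0, 1, 1)) # GC1 <-> {MC1, MC2}, GC2 <-> {MC2, MC3}
#' effective_connectivity(W)
#' @export
effective_connectivity <- function(W) {
  tcrossprod(W)
}
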