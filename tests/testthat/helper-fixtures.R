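# Small-network fixtures shared across test files.

small_params <- function(...) {
  args <- utils::modifyList(list(n_mc = 10, n_gc = 8, n_conn = 3, k = 4,
                                 g_thr = 0.5, gamma = 0.05), list(...))
  do.call(model_params, args)
}

# Random small network with the given seed: params, connectivity and a
# localized stimulus.
small_net <- function(seed = 1, ...) {
  p <- small_params(...)
  set.seed(seed)
  W <- init_connectivity(p)
  S <- gaussian_stimulus(p$n_mc, center = 4, width = 2, amplitude = 2) + 0.2
  list(p = p, W = W, S = S)
}

# Independent steady-state oracle: heavily damped fixed-point iteration of
# M <- (1 - a) M + a F(M), run to a much tighter tolerance than the solver
# under test.
fp_oracle <- function(S, W, p, alpha = 0.05, max_iter = 2e5, tol = 1e-10) {
  M <- pmax(tanh(S), 0)
  for (i in seq_len(max_iter)) {
    G <- pmax(crossprod(W, M) - p$g_thr, 0)
    Mn <- (1 - alpha) * M + alpha * pmax(tanh(S - p$gamma * (W %*% G)), 0)
    if (max(abs(Mn - M)) < alpha * tol) return(as.vector(Mn))
    M <- Mn
  }
  stop("fp_oracle did not converge")
}
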