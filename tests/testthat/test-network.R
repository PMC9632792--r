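test_that("MC activation is the rectified tanh", {
  expect_equal(mc_activation(0), 0)
  expect_equal(mc_activation(-5), 0)
  expect_equal(mc_activation(1), tanh(1))
  expect_equal(mc_activation(c(-1, 0.3)), c(0, tanh(0.3)))
  expect_error(mc_activation(c(1, NaN)), "finite")
  expect_error(mc_activation(Inf), "finite")
})

test_that("GC response is the thresholded linear drive", {
  # six MCs at rate 1, all connected to one GC: drive 6, threshold 4.4
  W <- matrix(1, 6, 1)
  expect_equal(gc_response(W, rep(1, 6), g_thr = 4.4), 1.6)
  # sub-threshold drive gives zero
  expect_equal(gc_response(W, rep(0.5, 6), g_thr = 4.4), 0)
  # no synapses, positive threshold
  expect_equal(gc_response(matrix(0, 4, 3), rep(1, 4), g_thr = 0.5),
               rep(0, 3))
  expect_error(gc_response(W, rep(1, 5), 4.4), "nrow")
})

test_that("steady state matches closed forms without inhibition", {
  p <- small_params(gamma = 0)
  set.seed(2)
  W <- init_connectivity(p)
  s <- 0.7
  st <- solve_steady_state(rep(s, p$n_mc), W, p)
  expect_equal(st$M, rep(tanh(s), p$n_mc), tolerance = 1e-6)

  # zero connectivity decouples the MCs for any gamma
  p2 <- small_params()
  S <- runif(p2$n_mc, 0, 2)
  st2 <- solve_steady_state(S, matrix(0, p2$n_mc, p2$n_gc), p2)
  expect_equal(st2$M, pmax(tanh(S), 0), tolerance = 1e-6)
})

test_that("steady state agrees with a damped fixed-point oracle", {
  # minimal recurrent circuit: 2 MCs, 1 GC, full reciprocal coupling
  p <- model_params(n_mc = 2, n_gc = 1, n_conn = 2, k = 2, g_thr = 0.2,
                    gamma = 0.5, solver_tol = 1e-10)
  W <- matrix(1, 2, 1)
  S <- c(1.2, 0.8)
  st <- solve_steady_state(S, W, p)
  expect_lt(max(abs(st$M - fp_oracle(S, W, p))), 1e-8)

  # random instances up to 10 x 10
  set.seed(42)
  for (rep in 1:100) {
    n_mc <- sample(2:10, 1)
    n_gc <- sample(1:10, 1)
    p <- model_params(n_mc = n_mc, n_gc = n_gc, n_conn = 1, k = n_mc,
                      g_thr = runif(1, 0.1, 1), gamma = runif(1, 0, 0.3),
                      solver_tol = 1e-9)
    W <- matrix(rbinom(n_mc * n_gc, 1, 0.4), n_mc, n_gc)
    S <- runif(n_mc, 0, 3)
    st <- solve_steady_state(S, W, p)
    expect_lt(max(abs(st$M - fp_oracle(S, W, p))), 1e-6)
    expect_true(all(st$M >= 0 & st$M < 1))
    expect_true(all(st$G >= 0))
  }
})

test_that("steady state agrees with a deSolve ODE integration", {
  skip_if_not_installed("deSolve")
  net <- small_net(3)
  deriv <- function(t, M, parms) {
    G <- pmax(crossprod(net$W, M) - net$p$g_thr, 0)
    list(as.vector(pmax(tanh(net$S - net$p$gamma * (net$W %*% G)), 0) - M))
  }
  out <- deSolve::ode(y = pmax(tanh(net$S), 0), times = c(0, 200),
                      func = deriv, parms = NULL, rtol = 1e-10, atol = 1e-10)
  st <- solve_steady_state(net$S, net$W, net$p)
  expect_equal(st$M, unname(out[2, -1]), tolerance = 1e-5)
})

test_that("non-convergence raises an error naming the stimulus", {
  p <- small_params(solver_t_max = 1e-3)
  net <- small_net(1)
  expect_error(solve_steady_state(net$S, net$W, p, stimulus_id = "odorX"),
               "odorX")
  expect_error(solve_steady_state(c(net$S, 1), net$W, p), "length")
  expect_error(solve_steady_state(-net$S, net$W, p), "nonnegative")
})

test_that("effective connectivity counts shared GCs and is symmetric", {
  expect_equal(effective_connectivity(matrix(0, 3, 2)), matrix(0, 3, 3))

  # GC1 <-> {MC1, MC2}, GC2 <-> {MC2, MC3}
  W <- cbind(c(1, 1, 0), c(0, 1, 1))
  wmm <- effective_connectivity(W)
  expect_equal(wmm[1, 2], 1)
  expect_equal(wmm[2, 3], 1)
  expect_equal(wmm[1, 3], 0)
  expect_equal(diag(wmm), c(1, 2, 1)) # GC degrees on the diagonal

  set.seed(5)
  Wr <- matrix(rbinom(60, 1, 0.3), 6, 10)
  expect_equal(effective_connectivity(Wr), t(effective_connectivity(Wr)))
})

test_that("initial connectivity gives every GC exactly n_conn synapses", {
  p <- small_params()
  set.seed(9)
  W <- init_connectivity(p)
  expect_true(all(W %in% 0:1))
  expect_equal(colSums(W), rep(p$n_conn, p$n_gc))
})
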