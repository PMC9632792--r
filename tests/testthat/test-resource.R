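test_that("pool-dependent resilience has the documented shape", {
  rp <- resource_params()
  # empty pool: only the removal term remains, so phi_tilde < 0
  expect_lt(phi_tilde(2, 0, rp), 0)
  expect_equal(phi_tilde(2, 0, rp),
               -((tanh(rp$kappa_rem * (2 - rp$r_rem)) + 1) / 2 + rp$r0))
  # equilibrium: no net drive at zero GC activity and full pool
  expect_lt(abs(phi_tilde(0, rp$p0, rp)), 1e-3)
  # fill-level shifts the curve up (P > P0) or down (P < P0) at fixed G
  g <- seq(0, 6, by = 0.5)
  expect_true(all(phi_tilde(g, rp$p0 + 5, rp) > phi_tilde(g, rp$p0, rp)))
  expect_true(all(phi_tilde(g, rp$p0 - 5, rp) < phi_tilde(g, rp$p0, rp)))
})

test_that("effective thresholds are roots and slide with the pool", {
  rp <- resource_params()
  th <- effective_thresholds(rp$p0, rp)
  expect_lt(th["g0"], th["g1"])
  expect_lt(abs(phi_tilde(th["g0"], rp$p0, rp)), 1e-8)
  expect_lt(abs(phi_tilde(th["g1"], rp$p0, rp)), 1e-8)
  # emptier pool -> higher formation threshold; fuller pool -> lower
  low <- effective_thresholds(rp$p0 - 3, rp)
  expect_gt(low["g1"], th["g1"])
  expect_lt(effective_thresholds(rp$p0 + 3, rp)["g1"], th["g1"])
  # below ~p0 removal is active at zero GC activity: g0 disappears
  expect_true(is.na(low["g0"]))
  expect_gt(effective_thresholds(rp$p0 + 3, rp)["g0"], th["g0"])
  # no-root regime reported as an error
  expect_error(effective_thresholds(20 * rp$p0, rp), "root")
})

test_that("resource state enforces conservation at initialization", {
  p <- small_params()
  rp <- resource_params(p0 = 5)
  set.seed(21)
  W <- init_connectivity(p)
  st <- resource_state(W, p, rp)
  expect_equal(st$p_all, p$n_conn + rp$p0)
  expect_equal(st$p + colSums(W), rep(st$p_all, p$n_gc))
})

test_that("pool steps conserve resource exactly and respect depletion", {
  p <- small_params()
  rp <- resource_params(p0 = 5, gamma = p$gamma)
  set.seed(22)
  W <- init_connectivity(p)
  st <- resource_state(W, p, rp)
  S <- gaussian_stimulus(p$n_mc, 4, 2, 2) + 0.2
  for (i in 1:300) {
    out <- pool_step(W, st, S, p, rp)
    W <- out$W
    st <- out$state
    expect_equal(st$p + colSums(W), rep(st$p_all, p$n_gc))
    expect_true(all(st$p >= 0))
  }
})

test_that("air-only input relaxes GC degrees toward n_conn", {
  p <- model_params(n_mc = 30, n_gc = 20, n_conn = 6, k = 8, g_thr = 2,
                    gamma = 0.01)
  rp <- resource_params(p0 = 4, gamma = 0.01)
  set.seed(23)
  # start displaced from equilibrium: degrees 2 and 10 instead of 6
  W <- matrix(0, p$n_mc, p$n_gc)
  for (j in 1:10) W[sample.int(p$n_mc, 2), j] <- 1
  for (j in 11:20) W[sample.int(p$n_mc, 10), j] <- 1
  st <- resource_state(W, p, rp)
  air <- rep(0.2, p$n_mc)
  dev0 <- mean(abs(colSums(W) - p$n_conn))
  for (i in 1:400) {
    out <- pool_step(W, st, air, p, rp)
    W <- out$W
    st <- out$state
  }
  dev1 <- mean(abs(colSums(W) - p$n_conn))
  expect_lt(dev1, dev0 / 2)
})

test_that("air trials are inserted after every four training trials", {
  expect_equal(schedule_with_air(rep(1:2, 4), air_index = 0),
               c(1, 2, 1, 2, 0, 1, 2, 1, 2, 0))
  expect_equal(schedule_with_air(integer(0), air_index = 0), integer(0))
  s <- schedule_with_air(rep(1L, 4), air_index = 9L)
  expect_equal(length(s), 5)
  expect_equal(s[5], 9L)
  # trailing partial group gets no air trial
  expect_equal(schedule_with_air(rep(1L, 6), air_index = 0),
               c(1, 1, 1, 1, 0, 1, 1))
})

test_that("pool training keeps conservation across a full train() run", {
  p <- model_params(n_mc = 30, n_gc = 20, n_conn = 6, k = 8, g_thr = 1,
                    gamma = 0.02)
  rp <- resource_params(p0 = 4, gamma = 0.02)
  set.seed(24)
  W0 <- init_connectivity(p)
  s <- simplified_stimuli(n_mc = p$n_mc, centers = c(10, 20), width = 4)
  fit <- train(W0, s, training_schedule(200, rng_seed = 3), p,
               variant = "pool", rp = rp, record_every = 20)
  p_all <- p$n_conn + rp$p0
  for (r in seq_along(fit$steps))
    expect_equal(fit$pool[, r] + fit$degrees[, r], rep(p_all, p$n_gc))
})
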