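#' Train the network on a stimulus ensemble
#'
#' Iterates structural-plasticity trials over a training schedule, recording
#' discriminability metrics for a probe odor pair along the way. Three model
#' variants are available: `"topk"` (activity-dependent plasticity with hard
#' top-k competition per GC, the default), `"pool"` (activity-dependent
#' plasticity with per-GC resource-pool competition; air trials are inserted
#' after every four training trials and the pool-model `gamma`, `dt` and
#' event-rate overrides apply), and `"random"` (the activity-independent
#' control: spine counts follow a global ramp toward `random_target`,
#' positions are uniformly random).
#'
#' Runs are deterministic given the schedule's `rng_seed` (or
#' `params$rng_seed`).
#'
#' @param W0 Initial binary connectivity matrix (`n_mc` x `n_gc`).
#' @param stimuli A [stimulus_set()].
#' @param schedule A [training_schedule()].
#' @param params A [model_params()] object.
#' @param variant `"topk"`, `"pool"` or `"random"`.
#' @param rp A [resource_params()] object (pool variant only).
#' @param train_odors Odor names/indices used for training (default: all
#'   odors in the set).
#' @param probe_odors Two odor names/indices whose discriminability is
#'   tracked (default: the first two training odors). Air is always probed.
#' @param record_every Metric recording stride in trials.
#' @param random_target Final mean synapse count per GC for the random
#'   control; the per-GC target ramps linearly from `n_conn` to this value.
#' @param di_average Passed to [summarize_discrimination()].
#' @param air_every Insert one air trial after this many training trials
#'   (pool variant).
#' @return A `plasticity_fit` object: final connectivity `W`, a metrics
#'   tibble (one row per record), the recorded probe rate array, degree
#'   snapshots, and (pool variant) pool-level snapshots. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- model_params(n_mc = 40, n_gc = 60, n_conn = 10, k = 11, g_thr = 1)
#' set.seed(1)
#' W0 <- init_connectivity(p)
#' s <- simplified_stimuli(n_mc = 40, centers = c(15, 25), width = 4)
#' fit <- train(W0, s, training_schedule(50, rng_seed = 1), p)
#' glance(fit)
#' @export
train <- function(W0, stimuli, schedule, params,
                  variant = c("topk", "pool", "random"),
                  rp = resource_params(), train_odors = NULL,
                  probe_odors = NULL, record_every = 10,
                  random_target = NULL,
                  di_average = c("divergent", "all"), air_every = 4) {
  variant <- match.arg(variant)
  di_average <- match.arg(di_average)
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(schedule, "training_schedule"),
            nrow(W0) == params$n_mc, ncol(W0) == params$n_gc,
            n_channels(stimuli) == params$n_mc)

  seed <- schedule$rng_seed %||% params$rng_seed
  if (!is.null(seed)) set.seed(seed)

  odor_names <- colnames(stimuli$patterns)
  if (is.null(train_odors)) train_odors <- odor_names
  if (is.numeric(train_odors)) train_odors <- odor_names[train_odors]
  if (is.null(probe_odors)) probe_odors <- train_odors[1:min(2,
                                                      length(train_odors))]
  if (is.numeric(probe_odors)) probe_odors <- odor_names[probe_odors]

  train_mat <- vapply(train_odors, function(o) presented_stimulus(stimuli, o),
                      numeric(params$n_mc))
  air <- presented_stimulus(stimuli, "air")
  probe_mat <- cbind(vapply(probe_odors,
                            function(o) presented_stimulus(stimuli, o),
                            numeric(params$n_mc)),
                     air = air)

  idx <- schedule_indices(schedule, length(train_odors))
  if (variant == "pool") {
    train_mat <- cbind(train_mat, air = air)
    idx <- schedule_with_air(idx, air_index = ncol(train_mat),
                             every = air_every)
  }

  if (variant == "random") {
    if (is.null(random_target))
      stop("train: variant = 'random' requires random_target")
    res <- train_random(W0, idx, train_mat, probe_mat, params, record_every,
                        random_target)
  } else {
    pool_flag <- as.integer(variant == "pool")
    eff_gamma <- if (variant == "pool") rp$gamma else params$gamma
    eff_dt <- if (variant == "pool") rp$dt else params$dt
    lam_f <- if (variant == "pool") rp$lambda_f else params$lambda_f
    lam_r <- if (variant == "pool") rp$lambda_r else params$lambda_r
    res <- cpp_train(W0, train_mat, as.integer(idx), probe_mat,
                     as.integer(record_every), eff_gamma, params$g_thr,
                     params$tau_m, params$g0, params$g1, lam_f, lam_r,
                     eff_dt, params$k,
                     params$solver_h * params$tau_m, params$solver_tol,
                     params$solver_t_max * params$tau_m, pool_flag,
                     rp$kappa_form, rp$r_form, rp$kappa_rem, rp$r_rem,
                     rp$r0, rp$p0, as.integer(params$n_conn + rp$p0))
  }

  rates <- res$probe_rates
  dimnames(rates) <- list(NULL, colnames(probe_mat), NULL)
  steps <- as.integer(res$steps)

  metrics <- purrr::map_dfr(seq_along(steps), function(r) {
    row <- if (length(probe_odors) >= 2)
      summarize_discrimination(rates[, 1, r], rates[, 2, r],
                               rates[, "air", r], params$theta, di_average)
    else
      tibble::tibble(n_responsive = NA_integer_, n_divergent = NA_integer_,
                     mean_di_prime = NA_real_, fisher_opt = NA_real_)
    dplyr::bind_cols(tibble::tibble(step = steps[r]), row,
                     tibble::tibble(mean_degree = mean(res$degrees[, r])))
  })

  structure(list(W = res$W, metrics = metrics, probe_rates = rates,
                 steps = steps, degrees = res$degrees,
                 pool = res$pool, params = params, variant = variant,
                 rp = if (variant == "pool") rp else NULL,
                 train_odors = train_odors, probe_odors = probe_odors,
                 schedule = schedule,
                 solver_iterations = res$solver_iterations %||% NA_real_),
            class = "plasticity_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random-control training loop (no steady-state solve needed per trial, only
# at the metric records).
train_random <- function(W, idx, train_mat, probe_mat, params, record_every,
                         random_target) {
  n <- length(idx)
  ramp <- params$n_conn + (random_target - params$n_conn) * seq_len(n) / n
  rec_steps <- unique(c(0, if (record_every <= n)
    seq(record_every, n, by = record_every), n))
  rates <- array(0, c(params$n_mc, ncol(probe_mat), length(rec_steps)))
  degs <- matrix(0L, params$n_gc, length(rec_steps))
  warm <- vector("list", ncol(probe_mat))

  record <- function(r) {
    for (p in seq_len(ncol(probe_mat))) {
      st <- solve_steady_state(probe_mat[, p], W, params, M0 = warm[[p]],
                               stimulus_id = colnames(probe_mat)[p])
      warm[[p]] <<- st$M
      rates[, p, r] <<- st$M
    }
    degs[, r] <<- colSums(W)
  }

  r <- 1
  record(r)
  for (s in seq_len(n)) {
    W <- random_control_step(W, ramp[s])
    if (r < length(rec_steps) && s == rec_steps[r + 1]) {
      r <- r + 1
      record(r)
    }
  }
  list(W = W, probe_rates = rates, steps = rec_steps, degrees = degs,
       pool = NULL, solver_iterations = NA_real_)
}

#' @export
print.plasticity_fit <- function(x, ...) {
  cat("<plasticity_fit> variant:", x$variant, "|",
      max(x$steps), "trials on odors",
      paste(x$train_odors, collapse = ", "), "\n")
  last <- x$metrics[nrow(x$metrics), ]
  cat("  final: ", last$n_responsive, " responsive, ", last$n_divergent,
      " divergent MCs; <di'> = ", signif(last$mean_di_prime, 4),
      "; F_opt = ", signif(last$fisher_opt, 4), "\n", sep = "")
  invisible(x)
}
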