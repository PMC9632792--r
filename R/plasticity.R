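#' Resilience of a spine as a function of GC activity
#'
#' The bidirectional resilience function
#' \eqn{\phi(G) = [G - G^{(0)}]_+ \, (G - G^{(1)})}: zero for
#' \eqn{G \le G^{(0)}} (inert spines, which preserves previously learned
#' connectivity while an odor is absent), negative on
#' \eqn{(G^{(0)}, G^{(1)})} (removal for weakly driven GCs) and positive above
#' \eqn{G^{(1)}} (formation for strongly driven GCs).
#'
#' @param G Nonnegative GC rate (vectorized).
#' @param params A [model_params()] object supplying `g0` and `g1`.
#' @return Numeric vector of resilience values.
#' @examples
#' p <- model_params()
#' resilience(c(1, 2, 4), p) # 0, (2-1)(2-4) = -2, 0
#' @export
resilience <- function(G, params) {
  pmax(G - params$g0, 0) * (G - params$g1)
}

#' Per-pair formation/removal rate matrix
#'
#' The single rate function \eqn{R_{ij} = M_i \, \phi(G_j)} evaluated at a
#' steady state: positive entries drive formation, negative entries removal.
#'
#' @param state A `network_state` from [solve_steady_state()].
#' @param params A [model_params()] object.
#' @return Matrix of dimension `length(M)` x `length(G)`.
#' @export
rate_matrix <- function(state, params) {
  outer(state$M, resilience(state$G, params))
}

#' Formation and removal probabilities of each potential synapse
#'
#' Poisson event probabilities over one trial of duration `dt`:
#' \eqn{P^+_{ij} = 1 - e^{-\lambda_f [R_{ij}]_+ \Delta t}} for absent synapses
#' and \eqn{P^-_{ij} = 1 - e^{-\lambda_r [-R_{ij}]_+ \Delta t}} for present
#' ones. At most one of the two is nonzero for any pair.
#'
#' @param R Rate matrix from [rate_matrix()].
#' @param params A [model_params()] object supplying `lambda_f`, `lambda_r`
#'   and `dt`.
#' @return List with matrices `p_plus` and `p_minus`, both in `[0, 1)`.
#' @examples
#' p <- model_params()
#' event_probabilities(matrix(c(-100, 0, 100), 1), p)
#' @export
event_probabilities <- function(R, params) {
  list(p_plus = 1 - exp(-params$lambda_f * pmax(R, 0) * params$dt),
       p_minus = 1 - exp(-params$lambda_r * pmax(-R, 0) * params$dt))
}

#' Top-k homeostasis
#'
#' For every GC carrying more than `k` synapses, removes the excess synapses
#' with the smallest rate values \eqn{R_{ij}}; ties are broken uniformly at
#' random with the run RNG. The removed pairs are returned so a plasticity
#' step can exclude them from re-formation within the same trial.
#'
#' @param W Binary connectivity matrix.
#' @param R Rate matrix (same dimension as `W`).
#' @param k Maximum synapses per GC.
#' @return List with the pruned matrix `W` and a two-column integer matrix
#'   `removed` of (MC, GC) indices.
#' @examples
#' set.seed(1)
#' W <- matrix(1, 5, 1)
#' R <- matrix(c(5, 4, 3, 2, 1), 5, 1)
#' apply_topk(W, R, k = 3)$removed
#' @export
apply_topk <- function(W, R, k) {
  stopifnot(all(dim(W) == dim(R)))
  res <- cpp_apply_topk(W, R, as.integer(k))
  colnames(res$removed) <- c("mc", "gc")
  res
}

#' One structural-plasticity trial (top-k variant)
#'
#' Runs the full per-trial update for one stimulus presentation: (1) steady
#' state for `S`; (2) rate matrix \eqn{R_{ij} = M_i \phi(G_j)}; (3) top-k
#' homeostasis; (4) stochastic formation of absent synapses with
#' \eqn{P^+} and removal of present ones with \eqn{P^-}, never re-creating a
#' synapse the homeostasis sub-step just removed.
#'
#' @param W Binary connectivity matrix.
#' @param S Stimulus vector.
#' @param params A [model_params()] object.
#' @param stimulus_id Optional label for error messages.
#' @return Updated binary connectivity matrix.
#' @export
plasticity_step <- function(W, S, params, stimulus_id = NULL) {
  st <- solve_steady_state(S, W, params, stimulus_id = stimulus_id)
  cpp_step_topk(W, st$M, st$G, params$g0, params$g1, params$lambda_f,
                params$lambda_r, params$dt, as.integer(params$k))
}

#' One trial of the activity-independent random control model
#'
#' Moves every GC's synapse count to `target_density` by adding synapses at
#' uniformly random absent positions or deleting uniformly random present
#' ones. The update ignores MC and GC activity entirely; it models spine
#' density controlled by a global (e.g. neuromodulatory) signal.
#'
#' @param W Binary connectivity matrix.
#' @param target_density Target synapse count per GC; scalar or vector of
#'   length `ncol(W)`. Must not exceed `nrow(W)`.
#' @return Updated binary connectivity matrix.
#' @examples
#' set.seed(1)
#' W <- matrix(0, 10, 4)
#' colSums(random_control_step(W, 5))
#' @export
random_control_step <- function(W, target_density) {
  target <- round(rep_len(target_density, ncol(W)))
  if (any(target > nrow(W)) || any(target < 0))
    stop("random_control_step: target_density must be in [0, n_mc]")
  deg <- colSums(W)
  for (j in which(deg != target)) {
    d <- target[j] - deg[j]
    if (d > 0) {
      absent <- which(W[, j] == 0)
      W[absent[sample.int(length(absent), d)], j] <- 1
    } else {
      present <- which(W[, j] == 1)
      W[present[sample.int(length(present), -d)], j] <- 0
    }
  }
  W
}

#' Training schedule
#'
#' Describes how training stimuli are sequenced across trials: strict
#' alternation (the default for two-odor tasks) or uniform random draws from
#' the training set (the default for larger ensembles).
#'
#' @param n_steps Number of trials.
#' @param policy `"alternating"` or `"random"`.
#' @param rng_seed Optional integer seed; [train()] seeds the RNG with it so
#'   the whole run is reproducible.
#' @return A `training_schedule` object.
#' @export
training_schedule <- function(n_steps, policy = c("alternating", "random"),
                              rng_seed = NULL) {
  policy <- match.arg(policy)
  stopifnot(n_steps > 0)
  structure(list(n_steps = as.integer(n_steps), policy = policy,
                 rng_seed = if (is.null(rng_seed)) NULL
                            else as.integer(rng_seed)),
            class = "training_schedule")
}

# Materialize a schedule as 1-based indices into the training stimulus set.
schedule_indices <- function(schedule, n_train) {
  if (schedule$policy == "alternating")
    rep_len(seq_len(n_train), schedule$n_steps)
  else
    sample.int(n_train, schedule$n_steps, replace = TRUE)
}

#' Insert air trials into a trial sequence
#'
#' The resource-pool model re-equilibrates its pools during odor-free
#' periods; these are modeled as explicit "air" trials (uniform spontaneous
#' input) inserted after every `every` training trials.
#'
#' @param trials Integer vector of training-stimulus indices.
#' @param air_index Index that denotes the air stimulus.
#' @param every Insert one air trial after this many training trials.
#' @return Integer vector with air trials interleaved.
#' @examples
#' schedule_with_air(rep(1:2, 4), air_index = 0)
#' @export
schedule_with_air <- function(trials, air_index, every = 4) {
  n <- length(trials)
  if (n == 0) return(integer(0))
  out <- integer(0)
  for (start in seq(1, n, by = every)) {
    grp <- trials[start:min(start + every - 1, n)]
    out <- c(out, grp, if (length(grp) == every) air_index)
  }
  out
}
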