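# Training protocols: each runs a multi-phase simulation and returns a report
# object whose components are tibbles, ready for dplyr/ggplot2.

# Combine pattern matrices from several stimulus sets into one set so that a
# single train() call can train on one subset and probe another.
combine_sets <- function(..., air_level) {
  mats <- lapply(list(...), as.matrix)
  stimulus_set(do.call(cbind, mats), air_level)
}

# Mixture patterns for the hard task: p:(1-p) and (1-p):p blends of the two
# base odors, stored as patterns (air is added at presentation).
mixture_pair <- function(set, p = 0.6, odors = 1:2,
                         names = c("mixAB", "mixBA")) {
  a <- set$patterns[, odors[1]]
  b <- set$patterns[, odors[2]]
  pats <- cbind(p * a + (1 - p) * b, (1 - p) * a + p * b)
  colnames(pats) <- names
  stimulus_set(pats, set$air_level)
}

# Per-MC response scatter (before vs after a training phase) for a probe pair.
response_scatter <- function(fit) {
  rates <- fit$probe_rates
  n_rec <- dim(rates)[3]
  tibble::tibble(
    mc = seq_len(dim(rates)[1]),
    resp_a_before = odor_response(rates[, 1, 1], rates[, "air", 1]),
    resp_b_before = odor_response(rates[, 2, 1], rates[, "air", 1]),
    resp_a_after = odor_response(rates[, 1, n_rec], rates[, "air", n_rec]),
    resp_b_after = odor_response(rates[, 2, n_rec], rates[, "air", n_rec])
  ) |>
    dplyr::mutate(diff_before = abs(.data$resp_a_before - .data$resp_b_before),
                  diff_after = abs(.data$resp_a_after - .data$resp_b_after))
}

#' Easy/hard discrimination-task protocol
#'
#' Pre-trains the network on a separate odor pair, then trains on the task
#' pair: the two dissimilar base odors (easy task) or their 60:40 / 40:60
#' mixtures (hard task). Reports the metric time courses and the per-MC
#' response differences before and after training.
#'
#' @param task `"easy"` or `"hard"`.
#' @param params A [model_params()] object.
#' @param variant Plasticity variant passed to [train()] (`"topk"` or
#'   `"pool"`).
#' @param base Two-odor [stimulus_set()] of the dissimilar base odors
#'   (default: the simplified Gaussian pair).
#' @param pretrain Two-odor [stimulus_set()] used for pre-training (default: a
#'   Gaussian pair at other positions).
#' @param mixture_p Strong-component fraction of the hard-task mixtures.
#' @param pretrain_steps,train_steps Trials per phase.
#' @param record_every Metric stride.
#' @param rp [resource_params()] for the pool variant.
#' @param seed Integer seed for the whole protocol.
#' @param W0 Optional initial connectivity (default: random with `n_conn`
#'   synapses per GC).
#' @return An `easy_hard_report`: the task fit and pre-training fit, the
#'   before/after metric rows, and the per-MC response scatter.
#' @export
run_easy_hard <- function(task = c("easy", "hard"), params = model_params(),
                          variant = c("topk", "pool"), base = NULL,
                          pretrain = NULL, mixture_p = 0.6,
                          pretrain_steps = 1500, train_steps = 3000,
                          record_every = 10, rp = resource_params(),
                          seed = 1, W0 = NULL) {
  task <- match.arg(task)
  variant <- match.arg(variant)
  set.seed(seed)
  if (is.null(base)) base <- simplified_stimuli(n_mc = params$n_mc)
  if (is.null(pretrain))
    pretrain <- simplified_stimuli(n_mc = params$n_mc, centers = c(35, 185),
                                   names = c("P1", "P2"),
                                   air_level = base$air_level)
  task_set <- if (task == "easy") base
              else mixture_pair(base, p = mixture_p)
  all_set <- combine_sets(pretrain, task_set, air_level = base$air_level)
  task_odors <- colnames(task_set$patterns)
  pre_odors <- colnames(pretrain$patterns)

  if (is.null(W0)) W0 <- init_connectivity(params)
  pre_fit <- train(W0, all_set, training_schedule(pretrain_steps), params,
                   variant = variant, rp = rp, train_odors = pre_odors,
                   probe_odors = task_odors, record_every = pretrain_steps)
  fit <- train(pre_fit$W, all_set, training_schedule(train_steps), params,
               variant = variant, rp = rp, train_odors = task_odors,
               probe_odors = task_odors, record_every = record_every)

  structure(list(task = task, variant = variant, pre_fit = pre_fit,
                 fit = fit, before = fit$metrics[1, ],
                 after = fit$metrics[nrow(fit$metrics), ],
                 scatter = response_scatter(fit), W_pre = pre_fit$W,
                 W_after = fit$W, params = params, seed = seed),
            class = "easy_hard_report")
}

#' @export
print.easy_hard_report <- function(x, ...) {
  cat("<easy_hard_report>", x$task, "task,", x$variant, "variant\n")
  cat(sprintf("  responsive %d -> %d | divergent %d -> %d | <di'> %.3f -> %.3f\n",
              x$before$n_responsive, x$after$n_responsive,
              x$before$n_divergent, x$after$n_divergent,
              x$before$mean_di_prime, x$after$mean_di_prime))
  invisible(x)
}

#' Odor-familiarization protocol
#'
#' Pre-trains with two background odors, then trains with the backgrounds
#' plus one additional "familiar" odor (drawn uniformly at random each
#' trial), and quantifies for each MC-odor pair the change index
#' \eqn{CI = (r_{after} - r_{before}) / (r_{after} + r_{before})} of the
#' response to the familiar odor and to novel probe odors never used in
#' training. Under the activity-dependent variants the familiar odor's
#' responses drop the most and a subset of MCs is disinhibited (positive CI);
#' the `"random"` control produces no disinhibition.
#'
#' @param stimuli A [stimulus_set()] containing all odors. Default: a
#'   synthetic surrogate glomerular set in which odor 1 is the familiar odor
#'   and novel odors span a range of similarities to it.
#' @param familiar,backgrounds,novels Odor names (or indices) giving the
#'   roles. Defaults match the default surrogate set.
#' @param params A [model_params()] object.
#' @param variant `"topk"`, `"pool"` or `"random"`.
#' @param rp [resource_params()] for the pool variant.
#' @param random_target Final mean GC degree of the random-control ramp.
#' @param pretrain_steps,train_steps Trials per phase.
#' @param seed Integer seed.
#' @param W0 Optional initial connectivity.
#' @return A `familiarization_report` with per-MC-odor change indices
#'   (`pairs`), a per-odor summary (`odors`: mean CI and similarity to the
#'   familiar odor), and the fraction of responsive MCs with positive CI for
#'   the familiar odor.
#' @export
run_familiarization <- function(stimuli = NULL, familiar = NULL,
                                backgrounds = NULL, novels = NULL,
                                params = model_params(),
                                variant = c("topk", "pool", "random"),
                                rp = resource_params(),
                                random_target = round(1.2 * params$n_conn),
                                pretrain_steps = 1500, train_steps = 3000,
                                seed = 1, W0 = NULL) {
  variant <- match.arg(variant)
  set.seed(seed)
  if (is.null(stimuli)) {
    # odor 1 = familiar; 11 novels spanning similarity 0.85 .. 0; 2 backgrounds
    stimuli <- surrogate_glomerular_set(
      14, n_mc = params$n_mc,
      similarity = c(1, seq(0.85, 0, length.out = 11), 0.3, 0.2))
    colnames(stimuli$patterns) <- c("F", paste0("N", 1:11), "B1", "B2")
    familiar <- "F"
    novels <- paste0("N", 1:11)
    backgrounds <- c("B1", "B2")
  }
  stopifnot(!is.null(familiar), !is.null(backgrounds), !is.null(novels))

  if (is.null(W0)) W0 <- init_connectivity(params)
  probe <- c(familiar, novels)

  pre_fit <- train(W0, stimuli, training_schedule(pretrain_steps), params,
                   variant = if (variant == "random") "random" else variant,
                   rp = rp, train_odors = backgrounds, probe_odors = probe,
                   record_every = pretrain_steps,
                   random_target = params$n_conn)
  fit <- train(pre_fit$W, stimuli,
               training_schedule(train_steps, policy = "random"), params,
               variant = variant, rp = rp,
               train_odors = c(backgrounds, familiar), probe_odors = probe,
               record_every = train_steps, random_target = random_target)

  rates <- fit$probe_rates
  n_rec <- dim(rates)[3]
  pairs <- purrr::map_dfr(probe, function(o) {
    rb <- odor_response(rates[, o, 1], rates[, "air", 1])
    ra <- odor_response(rates[, o, n_rec], rates[, "air", n_rec])
    tibble::tibble(odor = o, mc = seq_along(rb),
                   resp_before = rb, resp_after = ra,
                   responsive = pmax(rb, ra) > params$theta,
                   ci = change_index(ra, rb))
  })

  fam_pat <- presented_stimulus(stimuli, familiar)
  odors <- pairs |>
    dplyr::filter(.data$responsive, !is.na(.data$ci)) |>
    dplyr::group_by(.data$odor) |>
    dplyr::summarise(mean_ci = mean(.data$ci),
                     frac_positive_ci = mean(.data$ci > 0),
                     n_mc = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(similarity = purrr::map_dbl(.data$odor, function(o)
      stimulus_similarity(presented_stimulus(stimuli, o), fam_pat)),
      role = ifelse(.data$odor == familiar, "familiar", "novel"))

  structure(list(variant = variant, pairs = pairs, odors = odors,
                 familiar = familiar, novels = novels,
                 backgrounds = backgrounds, fit = fit, pre_fit = pre_fit,
                 params = params, seed = seed),
            class = "familiarization_report")
}

#' @export
print.familiarization_report <- function(x, ...) {
  fam <- x$odors[x$odors$role == "familiar", ]
  nov <- x$odors[x$odors$role == "novel", ]
  cat("<familiarization_report>", x$variant, "variant\n")
  cat(sprintf("  familiar odor: <CI> = %.3f, %.1f%% of responsive MCs with CI > 0\n",
              fam$mean_ci, 100 * fam$frac_positive_ci))
  cat(sprintf("  novel odors:   <CI> = %.3f (mean over %d odors)\n",
              mean(nov$mean_ci), nrow(nov)))
  invisible(x)
}

#' Amplitude re-exposure protocol
#'
#' Pre-trains with two dissimilar odors, then re-trains with only the first
#' odor presented at a swept amplitude. Because the resilience function is
#' negative only at intermediate GC activity, the fraction of pre-trained
#' connections retained is non-monotonic in the amplitude: connections
#' persist at small amplitude (inert spines), are removed at intermediate
#' amplitude, and are stabilized again at large amplitude.
#'
#' @param amplitudes Training amplitudes, as multiples of the pre-training
#'   amplitude.
#' @param params A [model_params()] object.
#' @param base Two-odor base [stimulus_set()] (simplified Gaussians by
#'   default; `retrain_odor` names the re-exposed odor).
#' @param retrain_odor Name/index of the re-trained odor.
#' @param pretrain_steps,train_steps Trials per phase.
#' @param seed Integer seed.
#' @param W0 Optional initial connectivity.
#' @return An `amplitude_report` whose `sweep` tibble has one row per
#'   amplitude: fraction of pre-trained synapses (on MCs activated by the
#'   odor) retained, and the mean change in those MCs' response to the odor.
#' @export
run_amplitude_retrain <- function(amplitudes = c(0.05, 0.1, 0.25, 0.5, 1),
                                  params = model_params(), base = NULL,
                                  retrain_odor = 1, pretrain_steps = 1500,
                                  train_steps = 1500, seed = 1, W0 = NULL) {
  set.seed(seed)
  if (is.null(base)) base <- simplified_stimuli(n_mc = params$n_mc)
  odor_names <- colnames(base$patterns)
  if (is.numeric(retrain_odor)) retrain_odor <- odor_names[retrain_odor]

  if (is.null(W0)) W0 <- init_connectivity(params)
  pre_fit <- train(W0, base, training_schedule(pretrain_steps), params,
                   probe_odors = odor_names[1:2],
                   record_every = pretrain_steps)
  W_pre <- pre_fit$W

  # MCs activated by the re-trained odor at the pre-trained network
  st_odor <- solve_steady_state(presented_stimulus(base, retrain_odor), W_pre,
                                params, stimulus_id = retrain_odor)
  st_air <- solve_steady_state(presented_stimulus(base, "air"), W_pre, params,
                               stimulus_id = "air")
  resp_pre <- odor_response(st_odor$M, st_air$M)
  active <- resp_pre > params$theta

  sweep <- purrr::map_dfr(amplitudes, function(a) {
    scaled <- base
    scaled$patterns[, retrain_odor] <- a * base$patterns[, retrain_odor]
    fit <- train(W_pre, scaled, training_schedule(train_steps), params,
                 train_odors = retrain_odor,
                 probe_odors = rep(retrain_odor, 2),
                 record_every = train_steps)
    n_rec <- dim(fit$probe_rates)[3]
    # response to the odor at its original amplitude, after re-training
    st_after <- solve_steady_state(presented_stimulus(base, retrain_odor),
                                   fit$W, params, stimulus_id = retrain_odor)
    air_after <- solve_steady_state(presented_stimulus(base, "air"), fit$W,
                                    params, stimulus_id = "air")
    resp_post <- odor_response(st_after$M, air_after$M)
    pre_syn <- W_pre[active, , drop = FALSE]
    tibble::tibble(
      amplitude = a,
      retained_frac = sum(fit$W[active, , drop = FALSE] * pre_syn) /
        sum(pre_syn),
      mean_response_change = mean(resp_post[active] - resp_pre[active]))
  })

  structure(list(sweep = sweep, W_pre = W_pre, active = active,
                 pre_fit = pre_fit, params = params, seed = seed,
                 retrain_odor = retrain_odor),
            class = "amplitude_report")
}

#' @export
print.amplitude_report <- function(x, ...) {
  cat("<amplitude_report> re-exposure of odor", x$retrain_odor, "\n")
  print(as.data.frame(x$sweep), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Interference / forgetting protocol
#'
#' Trains odor pair 1, then odor pair 2 (optionally overlapping pair 1 in
#' channel space), then re-trains pair 1, while tracking the Fisher
#' discriminant of pair 1 throughout. Overlapping interference erases the
#' pair-1 connectivity (forgetting) and re-training restores it faster than
#' the forgetting took; non-overlapping pair-2 training leaves pair 1 intact.
#'
#' Both pairs are hard (similar) pairs by default — 60:40 / 40:60 mixtures of
#' two Gaussian components — since learning must first raise the pair-1
#' discriminability for forgetting to be visible.
#'
#' @param overlap If `TRUE` (default) the second pair's components overlap
#'   the first pair's channels.
#' @param params A [model_params()] object.
#' @param pair1,pair2 Two-odor [stimulus_set()]s; defaults are mixture pairs
#'   built from Gaussian components, with pair-2 components placed per
#'   `overlap`.
#' @param steps Trials per phase.
#' @param record_every Metric stride.
#' @param seed Integer seed.
#' @param W0 Optional initial connectivity.
#' @return An `interference_report` with the per-phase pair-1 Fisher
#'   discriminant trajectory (`trajectory`), phase summaries, and the fitted
#'   phases.
#' @export
run_interference <- function(overlap = TRUE, params = model_params(),
                             pair1 = NULL, pair2 = NULL, steps = 1500,
                             record_every = 10, seed = 1, W0 = NULL) {
  set.seed(seed)
  scale <- params$n_mc / 240
  if (is.null(pair1))
    pair1 <- mixture_pair(
      simplified_stimuli(n_mc = params$n_mc, centers = scale * c(60, 100),
                         width = 12 * scale),
      names = c("A1", "A2"))
  if (is.null(pair2)) {
    centers <- if (overlap) scale * c(120, 160) else scale * c(170, 210)
    pair2 <- mixture_pair(
      simplified_stimuli(n_mc = params$n_mc, centers = centers,
                         width = 12 * scale,
                         air_level = pair1$air_level),
      names = c("B1", "B2"))
  }
  all_set <- combine_sets(pair1, pair2, air_level = pair1$air_level)
  p1 <- colnames(pair1$patterns)
  p2 <- colnames(pair2$patterns)

  if (is.null(W0)) W0 <- init_connectivity(params)
  phases <- list()
  probes <- c(p1, p2) # pair-1 metrics in `metrics`; pair 2 recovered below
  phases$learn <- train(W0, all_set, training_schedule(steps), params,
                        train_odors = p1, probe_odors = probes,
                        record_every = record_every)
  phases$interfere <- train(phases$learn$W, all_set,
                            training_schedule(steps), params,
                            train_odors = p2, probe_odors = probes,
                            record_every = record_every)
  phases$relearn <- train(phases$interfere$W, all_set,
                          training_schedule(steps), params,
                          train_odors = p1, probe_odors = probes,
                          record_every = record_every)

  trajectory <- purrr::imap_dfr(phases, function(f, ph) {
    rates <- f$probe_rates
    tibble::tibble(
      phase = ph, step = f$steps,
      fisher_pair1 = vapply(seq_along(f$steps), function(r)
        fisher_opt(rates[, p1[1], r], rates[, p1[2], r]), numeric(1)),
      fisher_pair2 = vapply(seq_along(f$steps), function(r)
        fisher_opt(rates[, p2[1], r], rates[, p2[2], r]), numeric(1)))
  })
  structure(list(overlap = overlap, trajectory = trajectory,
                 phases = phases, params = params, seed = seed),
            class = "interference_report")
}

#' Steps needed to reach (or fall below) a Fisher-discriminant criterion
#'
#' Helper for interference analyses: first recorded step in a phase at which
#' `fisher_opt` crosses `criterion` in the given direction, or `NA` if never.
#'
#' @param fit A `plasticity_fit`.
#' @param criterion Fisher-discriminant level.
#' @param direction `"above"` (learning) or `"below"` (forgetting).
#' @return Step count (integer) or `NA`.
#' @export
steps_to_criterion <- function(fit, criterion,
                               direction = c("above", "below")) {
  direction <- match.arg(direction)
  m <- fit$metrics
  hit <- if (direction == "above") m$fisher_opt >= criterion
         else m$fisher_opt <= criterion
  hit[1] <- FALSE # the phase's starting level does not count
  if (!any(hit)) return(NA_integer_)
  m$step[which(hit)[1]]
}

#' @export
print.interference_report <- function(x, ...) {
  cat("<interference_report>", if (x$overlap) "overlapping" else
    "non-overlapping", "pair 2\n")
  ends <- x$trajectory |>
    dplyr::group_by(.data$phase) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  print(as.data.frame(ends[, c("phase", "step", "fisher_pair1",
                               "fisher_pair2")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
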