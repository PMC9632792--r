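#' Gaussian model stimulus
#'
#' Simplified odor pattern: a scaled Gaussian bump over the MC index axis,
#' \eqn{S_i = a \exp(-(i - c)^2 / (2 w^2))}.
#'
#' @param n_mc Number of MC channels.
#' @param center Peak position (in MC index units, 1-based).
#' @param width Gaussian standard deviation in channels; must be positive.
#' @param amplitude Peak value; nonnegative.
#' @return Numeric pattern vector of length `n_mc` (air not included).
#' @examples
#' s <- gaussian_stimulus(240, center = 85, width = 21.2, amplitude = 2)
#' which.max(s)
#' @export
gaussian_stimulus <- function(n_mc, center, width, amplitude = 1) {
  if (width <= 0) stop("gaussian_stimulus: width must be positive")
  if (amplitude < 0) stop("gaussian_stimulus: amplitude must be nonnegative")
  amplitude * exp(-(seq_len(n_mc) - center)^2 / (2 * width^2))
}

#' Stimulus set
#'
#' Container bundling a matrix of odor patterns (channels x odors, without
#' the air baseline) with the air level. Patterns may contain negative values
#' (calibrated naturalistic-style maps); rectification happens when a
#' presented stimulus is assembled by [mix_stimuli()] / [presented_stimulus()].
#'
#' @param patterns Numeric matrix, one column per odor, or a named list of
#'   pattern vectors.
#' @param air_level Uniform spontaneous input added to every presentation
#'   (0.2 for simplified stimuli, 0.1 for naturalistic-style ones).
#' @return A `stimulus_set` object.
#' @export
stimulus_set <- function(patterns, air_level) {
  if (is.list(patterns)) patterns <- do.call(cbind, patterns)
  patterns <- as.matrix(patterns)
  if (is.null(colnames(patterns)))
    colnames(patterns) <- paste0("odor", seq_len(ncol(patterns)))
  if (any(!is.finite(patterns))) stop("stimulus_set: patterns must be finite")
  stopifnot(air_level >= 0)
  structure(list(patterns = patterns, air_level = air_level),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", ncol(x$patterns), " odors x ", nrow(x$patterns),
      " channels, air level ", x$air_level, "\n", sep = "")
  cat("  odors:", paste(colnames(x$patterns), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.stimulus_set <- function(x, ...) x$patterns

#' Number of channels / odor names of a stimulus set
#' @param x A `stimulus_set`.
#' @rdname stimulus_set
#' @export
n_channels <- function(x) nrow(x$patterns)

#' Simplified two-odor training set
#'
#' Two Gaussian bumps whose half-maximum activations span MC indices of about
#' 60--110 and 110--160, the standard geometry of the simplified tasks, plus
#' the uniform air baseline.
#'
#' @param n_mc Number of MC channels.
#' @param centers Peak positions of the two bumps.
#' @param width Shared Gaussian width (default gives a 50-channel full width
#'   at half maximum).
#' @param amplitude Peak amplitude of both bumps.
#' @param air_level Uniform spontaneous input.
#' @param names Odor labels.
#' @return A `stimulus_set` with two odors.
#' @export
simplified_stimuli <- function(n_mc = 240, centers = c(85, 135),
                               width = 25 / sqrt(2 * log(2)), amplitude = 2,
                               air_level = 0.2, names = c("A", "B")) {
  pats <- vapply(centers, function(c0)
    gaussian_stimulus(n_mc, c0, width, amplitude), numeric(n_mc))
  colnames(pats) <- names
  stimulus_set(pats, air_level)
}

#' Assemble a presented mixture stimulus
#'
#' Builds the input actually presented to the network for a binary mixture
#' with concentration `p` of odor A:
#' \eqn{S = [p \tilde S^{(A)} + (1-p) \tilde S^{(B)} + \tilde S^{(air)}]_+}.
#'
#' @param a,b Odor pattern vectors of equal length.
#' @param p Mixture fraction of `a`, in `[0, 1]`.
#' @param air_level Uniform air input added before rectification.
#' @return Nonnegative stimulus vector.
#' @examples
#' mix_stimuli(c(1, 0), c(0, 1), p = 0.6, air_level = 0.1)
#' @export
mix_stimuli <- function(a, b, p, air_level) {
  if (length(a) != length(b)) stop("mix_stimuli: patterns differ in length")
  if (!is.finite(p) || p < 0 || p > 1)
    stop("mix_stimuli: p must lie in [0, 1]")
  pmax(p * a + (1 - p) * b + air_level, 0)
}

#' Presented stimulus for a single odor
#'
#' Pattern plus air baseline, rectified: the special case `p = 1` of
#' [mix_stimuli()].
#'
#' @param set A `stimulus_set`.
#' @param odor Odor name or column index; use `"air"` for the pure air
#'   stimulus.
#' @return Nonnegative stimulus vector.
#' @export
presented_stimulus <- function(set, odor) {
  if (identical(odor, "air")) return(rep(set$air_level, n_channels(set)))
  pmax(set$patterns[, odor] + set$air_level, 0)
}

#' Calibrate a raw glomerular activation map
#'
#' Re-calibrates a raw z-score pattern so that its 40th percentile maps to
#' zero (so ~60% of channels are activated by a strong presentation) and
#' normalizes by the maximum:
#' \eqn{\tilde S = (S - S^{(40\%)}) / \max(S - S^{(40\%)})}. Values below the
#' percentile stay negative; clipping happens only when a presented stimulus
#' is assembled.
#'
#' @param z Raw activation vector (length >= 2, not all equal).
#' @param percentile Percentile mapped to zero (default 0.4).
#' @param type Quantile convention passed to [stats::quantile()]; the default
#'   (7) interpolates linearly between order statistics.
#' @return Calibrated pattern with maximum exactly 1.
#' @examples
#' preprocess_naturalistic(0:9)
#' @export
preprocess_naturalistic <- function(z, percentile = 0.4, type = 7) {
  if (length(z) < 2 || diff(range(z)) == 0)
    stop("preprocess_naturalistic: need at least 2 distinct values")
  s <- z - stats::quantile(z, percentile, type = type, names = FALSE)
  m <- max(s)
  if (m <= 0) stop("preprocess_naturalistic: nonpositive maximum after shift")
  s / m
}

#' Downsample a long activation map by block averaging
#'
#' Reduces a raw map (e.g. 2074 glomerular data points) to `n_out` channels by
#' averaging consecutive blocks.
#'
#' @param z Numeric vector.
#' @param n_out Target length.
#' @return Numeric vector of length `n_out`.
#' @export
downsample_pattern <- function(z, n_out = 240) {
  stopifnot(n_out >= 1, length(z) >= n_out)
  edges <- floor(seq(0, length(z), length.out = n_out + 1))
  vapply(seq_len(n_out), function(b)
    mean(z[(edges[b] + 1):edges[b + 1]]), numeric(1))
}

# Smoothed standardized Gaussian field on a circular channel axis.
smooth_field <- function(n, smoothing) {
  half <- ceiling(3 * smoothing)
  kern <- exp(-(-half:half)^2 / (2 * smoothing^2))
  kern <- kern / sum(kern)
  x <- as.vector(stats::filter(stats::rnorm(n), kern, circular = TRUE))
  (x - mean(x)) / stats::sd(x)
}

#' Synthetic surrogate for a set of glomerular activation maps
#'
#' Generates spatially correlated odor patterns that emulate calibrated
#' glomerular activation maps: smooth random fields re-calibrated so the 40th
#' percentile is zero (roughly 60% of channels activated by a strong
#' presentation) and the maximum is 1. Pairwise Pearson similarity is
#' controlled through a one-factor construction: pattern `i` has empirical
#' correlation exactly `similarity[i]` with the reference pattern (odor 1),
#' and patterns `i`, `j` correlate as `similarity[i] * similarity[j]`. This is
#' a synthetic stand-in for imaged activation maps, not a reproduction of any
#' particular odorant.
#'
#' @param n_odors Number of odors (>= 1).
#' @param n_mc Number of channels.
#' @param similarity Target Pearson correlation with the reference odor;
#'   scalar or vector of length `n_odors` (first element is forced to 1).
#'   Values must lie in `[-1, 1]`.
#' @param smoothing Spatial correlation length (channels) of the underlying
#'   random fields.
#' @param air_level Uniform spontaneous input stored in the set.
#' @param rng_seed Optional seed; the same seed yields the identical set.
#' @return A `stimulus_set` of calibrated patterns.
#' @examples
#' s <- surrogate_glomerular_set(3, similarity = c(1, 0.7, 0), rng_seed = 1)
#' round(cor(as.matrix(s)), 3)
#' @export
surrogate_glomerular_set <- function(n_odors, n_mc = 240, similarity = 0,
                                     smoothing = 4, air_level = 0.1,
                                     rng_seed = NULL) {
  stopifnot(n_odors >= 1)
  sim <- rep_len(similarity, n_odors)
  sim[1] <- 1
  if (any(abs(sim) > 1))
    stop("surrogate_glomerular_set: similarity targets must lie in [-1, 1]")
  if (n_odors > n_mc)
    stop("surrogate_glomerular_set: cannot orthogonalize more odors than ",
         "channels")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  z0 <- smooth_field(n_mc, smoothing)
  pats <- matrix(NA_real_, n_mc, n_odors)
  basis <- matrix(z0, n_mc, 1) # empirically orthonormal columns (up to 1/n)
  for (i in seq_len(n_odors)) {
    a <- sim[i]
    if (abs(a) == 1) {
      x <- a * z0
    } else {
      z <- smooth_field(n_mc, smoothing)
      # empirical Gram-Schmidt against reference and previous noise fields so
      # pairwise correlations follow the one-factor targets exactly
      for (b in seq_len(ncol(basis)))
        z <- z - stats::cov(z, basis[, b]) / stats::var(basis[, b]) *
          basis[, b]
      z <- (z - mean(z)) / stats::sd(z)
      basis <- cbind(basis, z)
      x <- a * z0 + sqrt(1 - a^2) * z
    }
    pats[, i] <- preprocess_naturalistic(x)
  }
  colnames(pats) <- if (n_odors == 1) "odor1"
                    else c("odor1", paste0("odor", 2:n_odors))
  stimulus_set(pats, air_level)
}
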