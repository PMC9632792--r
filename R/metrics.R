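#' Odor response of each MC
#'
#' Response is the change in steady-state activity induced by an odor
#' relative to the activity under pure air: \eqn{r_i = M_i^{odor} -
#' M_i^{air}}. Negative values indicate odor-evoked inhibition below the air
#' baseline.
#'
#' @param m_odor,m_air MC rate vectors of equal length.
#' @return Numeric response vector.
#' @export
odor_response <- function(m_odor, m_air) {
  if (length(m_odor) != length(m_air))
    stop("odor_response: rate vectors differ in length")
  m_odor - m_air
}

#' Classify MCs as responsive and divergent
#'
#' An MC is responsive if its response to at least one of the two task odors
#' exceeds `theta`; it is divergent if its responses to the two odors differ
#' by more than `theta` (the air baseline cancels in the difference).
#'
#' @param r_a,r_b Response vectors for the two odors (from [odor_response()]).
#' @param theta Positive classification threshold.
#' @return List of logical vectors `responsive` and `divergent`.
#' @examples
#' classify_cells(c(0.3, 0.3), c(0.05, 0.25), theta = 0.2)
#' @export
classify_cells <- function(r_a, r_b, theta) {
  if (length(r_a) != length(r_b))
    stop("classify_cells: response vectors differ in length")
  stopifnot(theta > 0)
  list(responsive = pmax(r_a, r_b) > theta,
       divergent = abs(r_a - r_b) > theta)
}

#' Per-cell discriminability d-prime
#'
#' \eqn{d_i' = |M_i^{(A)} - M_i^{(B)}| / \sqrt{M_i^{(A)} + M_i^{(B)}}}: the
#' rate difference normalized by the pooled Poisson variability (the firing
#' rate is used as a proxy for the spike-count variance). Cells silent under
#' both odors get 0 by convention.
#'
#' @param m_a,m_b Nonnegative MC rate vectors.
#' @return Vector of per-cell d-prime values.
#' @examples
#' di_prime(4, 1) # 3 / sqrt(5)
#' @export
di_prime <- function(m_a, m_b) {
  if (any(m_a < 0) || any(m_b < 0))
    stop("di_prime: rates must be nonnegative")
  s <- m_a + m_b
  ifelse(s > 0, abs(m_a - m_b) / sqrt(s), 0)
}

#' Optimal Fisher discriminant of two population patterns
#'
#' Linear-readout separability of the two MC activity patterns under
#' independent Poisson variability:
#' \eqn{F_{opt} = \sum_i (M_i^{(A)} - M_i^{(B)})^2 / (M_i^{(A)} + M_i^{(B)})},
#' with silent pairs contributing 0. Satisfies
#' \eqn{F_{opt} = \sum_i (d_i')^2}, so it never decreases when MCs are added.
#'
#' @param m_a,m_b Nonnegative MC rate vectors.
#' @return Scalar Fisher discriminant (>= 0).
#' @examples
#' fisher_opt(c(4, 1), c(1, 4)) # 18/5
#' @export
fisher_opt <- function(m_a, m_b) {
  sum(di_prime(m_a, m_b)^2)
}

#' Change index of an MC-odor response across training
#'
#' \eqn{CI = (r_{after} - r_{before}) / (r_{after} + r_{before})}; negative
#' values mean increased inhibition, positive values disinhibition. Pairs
#' whose responses sum to zero are excluded (returned as `NA`), not
#' propagated as NaN.
#'
#' @param resp_after,resp_before Odor responses after and before training.
#' @return Change index in `[-1, 1]` for nonnegative responses; `NA` where
#'   the denominator vanishes.
#' @examples
#' change_index(3, 1) # 0.5
#' @export
change_index <- function(resp_after, resp_before) {
  s <- resp_after + resp_before
  ifelse(s == 0, NA_real_, (resp_after - resp_before) / s)
}

#' Pearson similarity of two stimuli
#'
#' @param s_a,s_b Stimulus vectors of equal length (>= 2) with nonzero
#'   variance.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
stimulus_similarity <- function(s_a, s_b) {
  if (length(s_a) != length(s_b) || length(s_a) < 2)
    stop("stimulus_similarity: need equal lengths >= 2")
  if (stats::sd(s_a) == 0 || stats::sd(s_b) == 0)
    stop("stimulus_similarity: zero-variance stimulus")
  stats::cor(s_a, s_b)
}

#' One-row discriminability summary of a probe pair
#'
#' Computes the standard per-record metrics from the steady-state MC rates
#' for two odors and air: responsive and divergent counts, the mean d-prime
#' and the optimal Fisher discriminant.
#'
#' @param m_a,m_b,m_air Steady-state MC rate vectors.
#' @param theta Classification threshold.
#' @param di_average Which average populates the `mean_di_prime` column:
#'   over `"divergent"` cells only (the default; 0 when there are none) or
#'   over `"all"` MCs. The all-MC average is always reported as
#'   `mean_di_prime_all`; it is the stabler trend statistic when divergent
#'   counts are near zero.
#' @return A one-row [tibble::tibble()] with columns `n_responsive`,
#'   `n_divergent`, `mean_di_prime`, `mean_di_prime_all`, `fisher_opt`.
#' @export
summarize_discrimination <- function(m_a, m_b, m_air, theta,
                                     di_average = c("divergent", "all")) {
  di_average <- match.arg(di_average)
  r_a <- odor_response(m_a, m_air)
  r_b <- odor_response(m_b, m_air)
  cls <- classify_cells(r_a, r_b, theta)
  di <- di_prime(m_a, m_b)
  mdi <- if (di_average == "all") mean(di)
         else if (any(cls$divergent)) mean(di[cls$divergent]) else 0
  tibble::tibble(n_responsive = sum(cls$responsive),
                 n_divergent = sum(cls$divergent),
                 mean_di_prime = mdi,
                 mean_di_prime_all = mean(di),
                 fisher_opt = fisher_opt(m_a, m_b))
}
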