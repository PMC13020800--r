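#' Forward-simulate condition-wise response amplitudes
#'
#' Applies the Gaussian duration tuning model vertex-wise to produce a
#' 24-condition beta table: for each vertex and condition,
#' `beta = baseline_true + gain_true * exp(-(d - mu_true)^2 / (2 sigma_true^2))`
#' plus i.i.d. Gaussian noise. The model is position invariant, so before
#' noise the four positions of a duration share one value.
#'
#' @param truth a `ground_truth_field` from [plant_field()].
#' @param stim a `stimulus_spec`; its durations must lie within the truth
#'   field's configured preference range.
#' @param noise_sd additive Gaussian noise standard deviation, psc (>= 0).
#' @param seed integer RNG seed.
#' @return a `beta_table`: data.frame with `vertex_id` and one column per
#'   condition (named as in `stim$conditions$name`), in psc.
#' @examples
#' p <- make_patch(2, 2, 1)
#' tr <- plant_field(p, "constant", list(mu = 0.5), seed = 1)
#' b <- simulate_betas(tr, noise_sd = 0, seed = 1)
#' b$d500_p1  # peak response: gain 1 at the preferred duration
#' @export
simulate_betas <- function(truth, stim = stimulus_spec(), noise_sd = 0,
                           seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  support <- attr(truth, "support") %||% c(0.2, 0.8)
  if (min(stim$durations) < support[1] - 1e-9 ||
      max(stim$durations) > support[2] + 1e-9) {
    stop("stimulus durations fall outside the truth field's support")
  }
  n <- nrow(truth)
  d <- stim$conditions$duration_s
  clean <- truth$baseline_true +
    truth$gain_true * exp(-outer(truth$mu_true, d, "-")^2 /
                            (2 * truth$sigma_true^2))
  noisy <- if (noise_sd > 0) {
    clean + with_seed(seed, matrix(stats::rnorm(n * length(d), 0, noise_sd),
                                   n, length(d)))
  } else clean
  colnames(noisy) <- stim$conditions$name
  out <- cbind(data.frame(vertex_id = truth$vertex_id), as.data.frame(noisy))
  structure(out, noise_sd = noise_sd, seed = seed,
            class = c("beta_table", "data.frame"))
}

#' Simulate duration-categorization behavior
#'
#' Generates trial-level "comparison longer than reference" responses for
#' the duration-discrimination task: on each trial a comparison duration is
#' shown and the probability of a "longer" response follows a logistic in
#' duration, `P(longer | d) = plogis(slope * (d - pse))`, where `pse` is the
#' planted point of subjective equality.
#'
#' @param pse point of subjective equality, seconds.
#' @param slope logistic steepness, 1/seconds (> 0).
#' @param n_per_duration trials per comparison duration (>= 1).
#' @param durations comparison durations, seconds.
#' @param subject_id subject label.
#' @param seed integer RNG seed.
#' @return a `behavior_table`: data.frame with `subject`, `trial`,
#'   `duration_s`, `response_longer` (0/1), balanced across durations.
#' @examples
#' b <- simulate_behavior(0.55, 20, n_per_duration = 10, seed = 1)
#' table(b$duration_s)
#' @export
simulate_behavior <- function(pse, slope, n_per_duration,
                              durations = c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8),
                              subject_id = "s01", seed = 1L) {
  if (slope <= 0) stop("slope must be positive")
  if (n_per_duration < 1) stop("n_per_duration must be >= 1")
  d <- rep(durations, each = n_per_duration)
  p <- stats::plogis(slope * (d - pse))
  resp <- with_seed(seed, as.integer(stats::runif(length(d)) < p))
  structure(data.frame(subject = subject_id, trial = seq_along(d),
                       duration_s = d, response_longer = resp,
                       stringsAsFactors = FALSE),
            pse = pse, slope = slope, seed = seed,
            class = c("behavior_table", "data.frame"))
}
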