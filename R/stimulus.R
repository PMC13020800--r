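#' Stimulus design specification
#'
#' Describes the duration-discrimination design: the set of comparison
#' durations, the four display positions, and the affine map from seconds to
#' the model's arbitrary-unit axes. The model space is a 100 x 100 grid
#' (space x duration, both in units 1..100). Durations map affinely at
#' 150 units/s with 0.2 s at unit 10 and 0.8 s at unit 100, so every design
#' duration falls on an integer duration-unit column of the stimulus tensor
#' and tensor-based prediction is exact.
#'
#' Conditions are enumerated duration-major: for each duration in ascending
#' order, the four positions in order, giving 24 conditions named
#' `d{duration_ms}_p{1..4}`.
#'
#' @param durations comparison durations in seconds, strictly increasing.
#' @param positions position labels (length 4 by default).
#' @return a `stimulus_spec` list with elements `durations`, `positions`,
#'   `conditions` (data.frame: name, duration_s, position), `n_units`,
#'   `unit_per_s`, `unit_offset` (unit = unit_per_s * d + unit_offset).
#' @examples
#' stim <- stimulus_spec()
#' head(stim$conditions)
#' @export
stimulus_spec <- function(durations = c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8),
                          positions = paste0("p", 1:4)) {
  if (any(diff(durations) <= 0)) stop("durations must be strictly increasing")
  n_units <- 100L
  unit_per_s <- 150
  unit_offset <- -20
  conditions <- data.frame(
    name = paste0("d", rep(round(durations * 1000), each = length(positions)),
                  "_", rep(positions, times = length(durations))),
    duration_s = rep(durations, each = length(positions)),
    position = rep(positions, times = length(durations)),
    stringsAsFactors = FALSE
  )
  structure(list(durations = durations, positions = positions,
                 conditions = conditions, n_units = n_units,
                 unit_per_s = unit_per_s, unit_offset = unit_offset),
            class = "stimulus_spec")
}

#' Seconds to model-axis units
#' @param d durations in seconds.
#' @param stim a `stimulus_spec`.
#' @return axis units (150 units/s; 0.2 s -> 10, 0.8 s -> 100).
#' @export
duration_to_unit <- function(d, stim = stimulus_spec()) {
  stim$unit_per_s * d + stim$unit_offset
}

#' Build the 100 x 100 x 24 stimulus indicator tensor
#'
#' Slice k marks the (space-unit, duration-unit) support of condition k:
#' the 25-unit spatial band of the condition's position crossed with the
#' single duration-unit column of its mapped duration. Each slice is
#' normalized to total mass 1, so summing a position-invariant pRF image
#' over a slice returns exactly the Gaussian tuning value at that
#' condition's duration.
#'
#' @param stim a `stimulus_spec`.
#' @return numeric array `c(100, 100, 24)` (space x duration x condition).
#' @export
build_stimulus_tensor <- function(stim = stimulus_spec()) {
  n <- stim$n_units
  n_pos <- length(stim$positions)
  band <- n %/% n_pos
  tens <- array(0, dim = c(n, n, nrow(stim$conditions)))
  for (k in seq_len(nrow(stim$conditions))) {
    u <- duration_to_unit(stim$conditions$duration_s[k], stim)
    if (abs(u - round(u)) > 1e-9 || u < 1 || u > n) {
      stop(sprintf("duration %.3f s maps off the unit grid", stim$conditions$duration_s[k]))
    }
    p <- match(stim$conditions$position[k], stim$positions)
    rows <- ((p - 1L) * band + 1L):(p * band)
    tens[rows, round(u), k] <- 1 / length(rows)
  }
  tens
}

#' Predict condition amplitudes through the stimulus tensor
#'
#' Fidelity machinery mirroring the modeling pipeline: the pRF is rendered
#' as a 100 x 100 image (uniform over space, Gaussian over duration units),
#' multiplied by the stimulus tensor, and summed over the first two axes to
#' yield the 24 condition predictions. Agrees with [predict_conditions()]
#' to machine precision.
#'
#' @param params numeric vector/list with `mu_d`, `sigma_d`, `gain`,
#'   `baseline`.
#' @param stim a `stimulus_spec`.
#' @param tensor optional precomputed tensor from [build_stimulus_tensor()].
#' @return numeric vector of 24 predicted amplitudes (psc).
#' @export
predict_via_tensor <- function(params, stim = stimulus_spec(), tensor = NULL) {
  if (is.null(tensor)) tensor <- build_stimulus_tensor(stim)
  mu_u <- duration_to_unit(params[["mu_d"]], stim)
  sigma_u <- stim$unit_per_s * params[["sigma_d"]]
  if (sigma_u <= 0) stop("sigma_d must be positive")
  u <- seq_len(stim$n_units)
  prf_img <- matrix(rep(exp(-(u - mu_u)^2 / (2 * sigma_u^2)),
                        each = stim$n_units),
                    nrow = stim$n_units)
  nr <- apply(tensor * as.vector(prf_img), 3L, sum)
  params[["baseline"]] + params[["gain"]] * nr
}
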