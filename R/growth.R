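#' Deterministic clone size
#'
#' Size in cells of a clone with fitness `s` acquired at age `atma`,
#' evaluated at age `t`: \eqn{x(t) = e^{s (t - atma)}} for `t >= atma`
#' and 0 before acquisition. A clone starts from a single cell at its
#' acquisition age and grows exponentially at the net per-year rate `s`.
#'
#' @param s Per-year fitness (net growth rate), `s >= 0`.
#' @param atma Age at the time of mutation acquisition, years.
#' @param t Ages at which to evaluate (vectorized).
#' @return Numeric vector of clone sizes (cells).
#' @examples
#' clone_size(0.1, 50, 120)  # exp(7)
#' @export
clone_size <- function(s, atma, t) {
  if (any(s < 0)) condition_error("fitness `s` must be >= 0", "clonedyn_parameter_error")
  ifelse(t < atma, 0, exp(s * (t - atma)))
}

#' Isolated-growth VAF prediction
#'
#' Deterministic VAF of a clone growing alone against the wild-type pool:
#' \deqn{VAF(t) = x(t) / (d (N + x(t))), \quad x(t) = e^{s (t - atma)}}
#' with `d` the diploid factor. The prediction is 0 before acquisition,
#' strictly increasing in `t` for `s > 0`, and saturates at `1/d` (0.5 for
#' heterozygous diploid) once the clone dwarfs the wild-type pool.
#'
#' @param s Per-year fitness.
#' @param atma Acquisition age, years.
#' @param t Query ages (vectorized).
#' @param params A [ch_params()] object.
#' @return Predicted VAF in `[0, 1/diploid_factor]`.
#' @examples
#' predict_isolated(0.3, 20, 120)          # ~0.50: clone saturates
#' predict_isolated(0, 50, 120)            # single quiescent cell
#' @export
predict_isolated <- function(s, atma, t, params = ch_params()) {
  x <- clone_size(s, atma, t)
  x / (params$diploid_factor * (params$N + x))
}

#' Maximum clone size at age 120 (MACS120)
#'
#' A single growth-potential metric combining fitness and timing: the
#' clone size a mutation is predicted to reach by the maximum human life
#' span, \deqn{MACS120 = e^{s (120 - ATMA)}.} Both the raw value and its
#' logarithm `s * (120 - atma)` are returned; the log scale is the
#' recommended covariate for downstream regression because the raw value
#' spans many orders of magnitude.
#'
#' @param s Per-year fitness (vectorized).
#' @param atma Acquisition age in years (vectorized).
#' @param horizon Horizon age (default 120).
#' @return A data.frame with columns `macs120` and `log_macs120`.
#' @examples
#' macs120(0.1, 50)   # exp(7) ~ 1096.6 cells
#' macs120(0, 30)     # a neutral clone stays at 1 cell
#' @export
macs120 <- function(s, atma, horizon = 120) {
  if (any(s < 0)) condition_error("fitness `s` must be >= 0", "clonedyn_parameter_error")
  if (any(atma > horizon))
    warning("acquisition after the prediction horizon: MACS120 < 1")
  lm120 <- s * (horizon - atma)
  data.frame(macs120 = exp(lm120), log_macs120 = lm120)
}
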