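#' Growth-model parameters
#'
#' Fixed quantities of the deterministic clone-growth model: the wild-type
#' hematopoietic stem-cell pool size `N`, the prediction horizon `max_age`
#' (the maximum human life span used for MACS120), the diploid factor in the
#' VAF denominator, and the sequencing-error VAF floor used for observations
#' that predate a variant's acquisition.
#'
#' A heterozygous mutation in a diploid genome is carried on one of two
#' chromosome copies, so a clone of size \eqn{x} among \eqn{N} wild-type
#' cells is observed at VAF \eqn{x / (2 (N + x))}; `diploid_factor = 2`
#' encodes this normalization and makes the isolated model saturate at
#' VAF 0.5.
#'
#' @param N Wild-type stem-cell count (default 100000).
#' @param max_age Horizon age in years for clone-size prediction (default 120).
#' @param diploid_factor Multiplier in the VAF denominator (default 2,
#'   heterozygous diploid).
#' @param error_floor VAF attributed to sequencing error before a mutation
#'   exists (default 1e-4).
#' @return An object of class `ch_params`.
#' @examples
#' p <- ch_params()
#' p$N
#' @export
ch_params <- function(N = 1e5, max_age = 120, diploid_factor = 2,
                      error_floor = 1e-4) {
  if (!is.numeric(N) || length(N) != 1L || N < 1)
    stop("`N` must be a single number >= 1")
  if (!is.numeric(max_age) || length(max_age) != 1L || max_age <= 0)
    stop("`max_age` must be a single positive number")
  if (!is.numeric(diploid_factor) || diploid_factor <= 0)
    stop("`diploid_factor` must be positive")
  if (!is.numeric(error_floor) || error_floor < 0 || error_floor >= 1)
    stop("`error_floor` must be in [0, 1)")
  structure(list(N = as.numeric(N), max_age = as.numeric(max_age),
                 diploid_factor = as.numeric(diploid_factor),
                 error_floor = as.numeric(error_floor)),
            class = "ch_params")
}

#' Fitness-grid specification
#'
#' The posterior over clone fitness is computed on a uniform grid of
#' per-year growth rates with a uniform prior. Acquisition ages are profiled
#' on a separate grid in `atma_step`-year increments.
#'
#' @param s_max Upper end of the fitness grid (per-year rate; default 1).
#' @param s_step Grid spacing (default 0.005).
#' @param atma_step Step of the acquisition-age profiling grid in years
#'   (default 1).
#' @return An object of class `ch_grid` with the grid values in `$s`.
#' @examples
#' g <- ch_grid()
#' length(g$s)
#' @export
ch_grid <- function(s_max = 1, s_step = 0.005, atma_step = 1) {
  if (s_max < 0 || s_step <= 0 || (s_max > 0 && s_step > s_max))
    stop("need s_max >= 0 and 0 < s_step <= s_max")
  if (atma_step <= 0) stop("`atma_step` must be positive")
  s <- if (s_max == 0) 0 else seq(0, s_max, by = s_step)
  structure(list(s = s, s_max = s_max, s_step = s_step,
                 atma_step = atma_step),
            class = "ch_grid")
}

#' @exportS3Method base::print
print.ch_params <- function(x, ...) {
  cat("Clone growth parameters: N =", format(x$N, big.mark = ","),
      "wild-type cells; horizon age", x$max_age,
      "; diploid factor", x$diploid_factor,
      "; error-floor VAF", x$error_floor, "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.ch_grid <- function(x, ...) {
  cat("Fitness grid: ", length(x$s), " points on [0, ", x$s_max,
      "] (step ", x$s_step, "); ATMA profiled in ", x$atma_step,
      "-year steps\n", sep = "")
  invisible(x)
}
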