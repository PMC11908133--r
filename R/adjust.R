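#' Two-stage Benjamini-Hochberg adjustment
#'
#' The two-stage adaptive step-up FDR procedure: a first Benjamini-Hochberg
#' pass at level `q / (1 + q)` estimates the number of true nulls
#' `m0 = m - r1` from its rejection count `r1`, and the second pass runs
#' Benjamini-Hochberg at the adaptive level `q m / m0`. Returned as
#' adjusted p-values (the BH adjustment scaled by `m0 / m`), clamped to be
#' no smaller than the raw p-value and monotone in it.
#'
#' @param p Numeric vector of raw p-values.
#' @param q Target FDR level used for the null-proportion estimate
#'   (default 0.05).
#' @return Vector of adjusted p-values.
#' @export
bky_adjust <- function(p, q = 0.05) {
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (!m) return(out)
  r1 <- sum(stats::p.adjust(p[ok], method = "BH") <= q / (1 + q))
  m0 <- m - r1
  adj <- if (m0 == 0) rep(0, m) else stats::p.adjust(p[ok], method = "BH") * m0 / m
  out[ok] <- pmin(1, pmax(adj, p[ok]))
  out
}
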