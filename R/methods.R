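# S3 methods for the ch_fit estimator.

#' @exportS3Method base::print
print.ch_fit <- function(x, ...) {
  k <- nrow(x$variants)
  cat("Clonal dynamics fit",
      if (!is.na(x$participant_id)) paste0("for participant ", x$participant_id),
      "\n")
  cat(sprintf("  %d variant(s) in %d clone(s); log evidence %.3f%s%s\n",
              k, length(x$structure), x$log_evidence,
              if (x$tie) " [evidence tie]" else "",
              if (!x$exhaustive) " [greedy, non-exhaustive]" else ""))
  for (b in seq_along(x$structure)) {
    cl <- x$clones[[b]]
    cat(sprintf("  clone %d: {%s}  s_MAP = %.3f (lead %s)\n", b,
                paste(cl$variants, collapse = ", "), cl$map_s, cl$lead))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.ch_fit <- function(object, level = 0.95, ...) {
  alpha <- (1 - level) / 2
  cl_tab <- do.call(rbind, lapply(seq_along(object$clones), function(b) {
    cl <- object$clones[[b]]
    cdf <- cumsum(cl$posterior$mass)
    data.frame(clone = b, variants = paste(cl$variants, collapse = ","),
               lead = cl$lead, s_map = cl$map_s,
               s_lo = cl$posterior$s[which(cdf >= alpha)[1]],
               s_hi = cl$posterior$s[which(cdf >= 1 - alpha)[1]],
               log_evidence = cl$log_evidence,
               stringsAsFactors = FALSE)
  }))
  out <- list(participant_id = object$participant_id, clones = cl_tab,
              variants = object$variants, level = level,
              n_candidates = nrow(object$candidates),
              log_evidence = object$log_evidence, tie = object$tie)
  class(out) <- "summary.ch_fit"
  out
}

#' @exportS3Method base::print
print.summary.ch_fit <- function(x, ...) {
  cat("Selected clonal structure (", nrow(x$clones), " clone(s), ",
      x$n_candidates, " candidate structure(s) scored)\n", sep = "")
  print(x$clones, row.names = FALSE, digits = 4)
  cat("\nPer-variant estimates:\n")
  print(x$variants[, c("variant", "clone", "s", "atma", "macs120", "lead")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-variant coefficients of a clonal-dynamics fit
#'
#' @param object A [ch_fit()] object.
#' @param ... Unused.
#' @return Data.frame with `variant`, `clone`, `s` (MAP fitness), `atma`,
#'   `macs120`, `log_macs120`.
#' @export
coef.ch_fit <- function(object, ...) {
  object$variants[, c("variant", "clone", "s", "atma", "macs120", "log_macs120")]
}

#' Predict VAF trajectories from a fit
#'
#' @param object A [ch_fit()] object.
#' @param ages Query ages (default: observed ages plus the horizon).
#' @param type `"context"` (competition-aware, default) or `"isolated"`.
#' @param ... Unused.
#' @return Data.frame of per-variant predicted VAFs.
#' @export
predict.ch_fit <- function(object, ages = NULL,
                           type = c("context", "isolated"), ...) {
  type <- match.arg(type)
  if (is.null(ages)) {
    ages <- sort(unique(c(unlist(lapply(object$trajectories, `[[`, "age")),
                          object$params$max_age)))
  }
  pr <- predict_context(object, ages)
  if (type == "isolated") pr$vaf <- pr$vaf_isolated else pr$vaf <- pr$vaf_context
  pr
}

#' @export
logLik.ch_fit <- function(object, ...) {
  vt <- object$variants
  atma <- vt$atma
  names(atma) <- vt$variant
  ok <- !any(is.na(atma))
  val <- if (ok)
    structure_loglik(object$trajectories, object$structure,
                     vapply(object$clones, `[[`, numeric(1), "map_s"),
                     atma, object$params)
  else NA_real_
  structure(val, df = length(object$clones) + nrow(vt), class = "logLik")
}

#' Pearson residuals of a clonal-dynamics fit
#'
#' Observed minus fitted VAF scaled by the binomial standard error at the
#' fitted (context-aware) VAF.
#'
#' @param object A [ch_fit()] object.
#' @param ... Unused.
#' @return Data.frame with `variant`, `age`, `observed`, `fitted`,
#'   `residual`.
#' @export
residuals.ch_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$trajectories), function(v) {
    tr <- object$trajectories[[v]]
    pr <- predict_context(object, tr$age)
    fit <- pr$vaf_context[pr$variant == v]
    obs <- tr$alt_reads / tr$depth
    se <- sqrt(pmax(fit * (1 - fit), 1e-12) / tr$depth)
    data.frame(variant = v, age = tr$age, observed = obs, fitted = fit,
               residual = ifelse(is.na(fit), NA, (obs - fit) / se))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate read counts from a fitted model
#'
#' Parametric-bootstrap draws: binomial alt-read counts at the observed
#' ages and depths with success probability given by the fitted
#' context-aware VAF.
#'
#' @param object A [ch_fit()] object.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` named lists of trajectory data.frames.
#' @export
simulate.ch_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    sim <- object$trajectories
    for (v in names(sim)) {
      tr <- sim[[v]]
      pr <- predict_context(object, tr$age)
      p <- pmax(pr$vaf_context[pr$variant == v], object$params$error_floor)
      if (any(is.na(p))) next
      tr$alt_reads <- stats::rbinom(nrow(tr), tr$depth, p)
      tr$vaf <- tr$alt_reads / tr$depth
      sim[[v]] <- tr
    }
    sim
  })
}

#' Plot observed trajectories and model fits
#'
#' Observed VAFs (points) with the fitted competition-aware deterministic
#' curves (solid) and isolated-growth curves (dashed) per variant, in the
#' style of longitudinal clonal-hematopoiesis trajectory panels.
#'
#' @param x A [ch_fit()] object.
#' @param to_age Right edge of the age axis (default: horizon age).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ch_fit <- function(x, to_age = NULL, ...) {
  to_age <- to_age %||% x$params$max_age
  ages <- unlist(lapply(x$trajectories, `[[`, "age"))
  grid_t <- seq(min(ages), to_age, length.out = 200)
  pr <- predict_context(x, grid_t)
  vt <- x$variants
  cols <- grDevices::hcl.colors(max(3L, nrow(vt)), "Dark 3")
  obs_v <- unlist(lapply(x$trajectories, function(tr) tr$alt_reads / tr$depth))
  ylim <- c(0, max(obs_v, pr$vaf_context, na.rm = TRUE) * 1.05)
  graphics::plot(NA, xlim = c(min(ages), to_age), ylim = ylim,
                 xlab = "age (years)", ylab = "VAF",
                 main = if (!is.na(x$participant_id))
                   paste("Participant", x$participant_id) else "Clonal fit", ...)
  for (i in seq_len(nrow(vt))) {
    v <- vt$variant[i]
    tr <- x$trajectories[[v]]
    sub <- pr[pr$variant == v, ]
    graphics::points(tr$age, tr$alt_reads / tr$depth, col = cols[i], pch = 19)
    graphics::lines(sub$age, sub$vaf_context, col = cols[i])
    graphics::lines(sub$age, sub$vaf_isolated, col = cols[i], lty = 2)
  }
  graphics::legend("topleft", legend = vt$variant, col = cols[seq_len(nrow(vt))],
                   pch = 19, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
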