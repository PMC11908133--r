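#' Estimate the age at the time of mutation acquisition (ATMA)
#'
#' Given a variant's trajectory and its inferred (MAP) fitness, finds the
#' acquisition age that maximizes the binomial log-likelihood of the
#' observed read counts under the isolated deterministic growth model —
#' the most probable time in the past when the clone was a single cell.
#' The search is continuous on `[0, age of first observation]` to a
#' tolerance of 1e-6 years; an optimum at the interval boundary is clamped
#' and flagged.
#'
#' @param trajectory Trajectory data.frame (columns `age`, `alt_reads`,
#'   `depth`).
#' @param s MAP fitness for the variant's clone. Identifiability requires
#'   `s > 0`: at `s <= s_min` ATMA is returned missing with flag
#'   `"unidentifiable"`.
#' @param params A [ch_params()] object.
#' @param s_min Fitness below which ATMA is declared unidentifiable
#'   (default 1e-12, i.e. only `s = 0`).
#' @return A list with `atma` (years or `NA`) and `flag` (`NA`,
#'   `"unidentifiable"`, `"all-zero"`, `"boundary-lower"` or
#'   `"boundary-upper"`).
#' @examples
#' p <- ch_params()
#' v <- predict_isolated(0.1, 50, c(70, 76, 82), p)
#' tr <- data.frame(age = c(70, 76, 82), alt_reads = v * 2000, depth = 2000)
#' estimate_atma(tr, 0.1, p)$atma  # ~50
#' @export
estimate_atma <- function(trajectory, s, params = ch_params(), s_min = 1e-12) {
  tv <- traj_vectors(trajectory)
  if (!length(tv$t)) return(list(atma = NA_real_, flag = "all-zero"))
  if (s <= s_min) return(list(atma = NA_real_, flag = "unidentifiable"))
  if (all(tv$k == 0)) return(list(atma = NA_real_, flag = "all-zero"))
  upper <- min(tv$t)
  # No error-floor here: the isolated-model likelihood must be free to
  # follow arbitrarily small clone sizes so that a single-cell observation
  # dates acquisition to the observation age itself. The combinatorial
  # constant is dropped: it is independent of the acquisition age and its
  # magnitude would swamp the informative terms in double precision for
  # weakly identified trajectories.
  obj <- function(a) {
    p <- pmin(pmax(predict_isolated(s, a, tv$t, params), 1e-12), 1 - 1e-12)
    -sum(tv$k * log(p) + (tv$n - tv$k) * log1p(-p))
  }
  opt <- stats::optimize(obj, c(0, upper), tol = 1e-6)
  cand <- c(opt$minimum, 0, upper)
  vals <- c(opt$objective, obj(0), obj(upper))
  a <- cand[which.min(vals)]
  flag <- NA_character_
  if (a <= 1e-6) { a <- 0; flag <- "boundary-lower" }
  if (a >= upper - 1e-6) { a <- upper; flag <- "boundary-upper" }
  list(atma = a, flag = flag)
}

#' Competition-aware VAF prediction
#'
#' Predicts every variant's VAF at query ages under the mutational-context
#' model, in which all of a participant's clones compete for the same
#' stem-cell pool:
#' \deqn{VAF_j(t) = x_j(t) / (d (N + \sum_b x^{lead}_b(t)))}
#' with the sum running over the clones (blocks) of the selected structure
#' and \eqn{x^{lead}_b} the size of clone `b`'s lead variant. For a
#' participant with a single one-variant clone this reduces exactly to the
#' isolated model. Variants with missing ATMA are excluded (VAF `NA`) and
#' their clones contribute nothing to the denominator.
#'
#' @param fit A [ch_fit()] object.
#' @param t Query ages (vectorized).
#' @param params Growth parameters; defaults to those stored in `fit`.
#' @return A data.frame with one row per variant x age: `variant`, `age`,
#'   `vaf_context`, `vaf_isolated`.
#' @export
predict_context <- function(fit, t, params = NULL) {
  params <- params %||% fit$params
  vt <- fit$variants
  leads <- vt[vt$lead, , drop = FALSE]
  denom <- function(tt) {
    tot <- 0
    for (i in seq_len(nrow(leads)))
      if (!is.na(leads$atma[i]))
        tot <- tot + clone_size(leads$s[i], leads$atma[i], tt)
    tot
  }
  dx <- denom(t)
  out <- do.call(rbind, lapply(seq_len(nrow(vt)), function(i) {
    if (is.na(vt$atma[i]))
      return(data.frame(variant = vt$variant[i], age = t,
                        vaf_context = NA_real_, vaf_isolated = NA_real_))
    x <- clone_size(vt$s[i], vt$atma[i], t)
    data.frame(variant = vt$variant[i], age = t,
               vaf_context = x / (params$diploid_factor * (params$N + dx)),
               vaf_isolated = predict_isolated(vt$s[i], vt$atma[i], t, params))
  }))
  rownames(out) <- NULL
  out
}

#' Compare isolated and context-aware VAF forecasts across a cohort
#'
#' For every fitted variant, computes the difference between the isolated
#' and competition-aware VAF predictions at the horizon age (delta =
#' isolated minus context, non-negative because competition can only
#' shrink a variant's VAF). Summaries: the mean absolute delta and the
#' fraction of participants whose largest per-variant delta exceeds
#' `threshold`.
#'
#' @param fits Named list of [ch_fit()] objects.
#' @param t Horizon age (default 120).
#' @param threshold Per-participant exceedance threshold on |delta| in VAF
#'   units (default 0.20).
#' @return A list with `table` (per-variant rows: participant, variant,
#'   isolated, context, delta) and `summary` (`mean_abs_delta`,
#'   `frac_participants_over`).
#' @export
compare_isolated_vs_context <- function(fits, t = 120, threshold = 0.20) {
  rows <- list()
  for (pid in names(fits)) {
    pr <- predict_context(fits[[pid]], t)
    pr <- pr[!is.na(pr$vaf_context), , drop = FALSE]
    if (!nrow(pr)) next
    rows[[pid]] <- data.frame(participant_id = pid, variant = pr$variant,
                              isolated = pr$vaf_isolated,
                              context = pr$vaf_context,
                              delta = pr$vaf_isolated - pr$vaf_context)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), variant = character(0),
               isolated = numeric(0), context = numeric(0), delta = numeric(0))
  rownames(tab) <- NULL
  per_part <- if (nrow(tab))
    tapply(abs(tab$delta), tab$participant_id, max) else numeric(0)
  list(table = tab,
       summary = list(
         mean_abs_delta = if (nrow(tab)) mean(abs(tab$delta)) else NA_real_,
         frac_participants_over = if (length(per_part))
           mean(per_part > threshold) else NA_real_))
}

#' Participant-level clonal-hematopoiesis metrics
#'
#' The three scalar summaries carried into the survival and blood-marker
#' stages: maximum observed VAF over all variants and visits, maximum MAP
#' fitness over clones, and maximum MACS120 over clones (with its log).
#' Clone-level MACS120 uses the clone's lead-variant ATMA. Participants
#' with no variants get zeros and `flag = "no-variants"`.
#'
#' @param participant A `ch_participant`.
#' @param fit The participant's [ch_fit()] (or `NULL` when no variants).
#' @return One-row data.frame: `participant_id`, `cohort`, `sex`,
#'   `age_first_obs`, `max_vaf`, `max_fitness`, `macs120`, `log_macs120`,
#'   `flag`.
#' @export
participant_metrics <- function(participant, fit = NULL) {
  base <- data.frame(participant_id = participant$participant_id,
                     cohort = participant$cohort, sex = participant$sex,
                     age_first_obs = participant$age_first_obs,
                     stringsAsFactors = FALSE)
  if (is.null(fit) || !length(participant$trajectories)) {
    return(cbind(base, max_vaf = 0, max_fitness = 0, macs120 = 0,
                 log_macs120 = 0, flag = "no-variants"))
  }
  mv <- max(unlist(lapply(participant$trajectories,
                          function(tr) tr$alt_reads / tr$depth)))
  vt <- fit$variants
  leads <- vt[vt$lead, , drop = FALSE]
  clone_macs <- ifelse(is.na(leads$atma), 1,
                       exp(leads$s * (fit$params$max_age - ifelse(is.na(leads$atma), 0, leads$atma))))
  cbind(base, max_vaf = mv, max_fitness = max(vt$s),
        macs120 = max(clone_macs), log_macs120 = log(max(clone_macs)),
        flag = NA_character_)
}

#' Cohort metrics table with z-scores
#'
#' Stacks [participant_metrics()] over a cohort and appends z-scored
#' columns (`z_max_vaf`, `z_max_fitness`, `z_macs120`, `z_age`). MACS120 is
#' z-scored on the log scale: the raw value spans many orders of magnitude
#' and a linear z-score would be dominated by the largest clone.
#'
#' @param participants Named list of `ch_participant` objects.
#' @param fits Named list of [ch_fit()] objects (subset of participants).
#' @return A data.frame, one row per participant.
#' @export
cohort_metrics <- function(participants, fits) {
  rows <- lapply(names(participants), function(pid)
    participant_metrics(participants[[pid]], fits[[pid]]))
  tab <- do.call(rbind, rows)
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  tab$z_max_vaf <- zs(tab$max_vaf)
  tab$z_max_fitness <- zs(tab$max_fitness)
  tab$z_macs120 <- zs(tab$log_macs120)
  tab$z_age <- zs(tab$age_first_obs)
  tab
}
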