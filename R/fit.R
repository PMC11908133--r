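# Core estimator: clonal structure selection + per-clone fitness posteriors.
#
# Model: a clone acquired at age `atma` grows deterministically as
# x(t) = exp(s (t - atma)); observed alt-read counts are Binomial(depth, VAF)
# with VAF = x_j / (d (N + x_lead)), where x_lead is the size of the block's
# lead variant (the highest mean observed VAF in the block). Fitness is
# scored on a uniform grid with a uniform prior; acquisition ages are
# profiled on a 1-year grid (followers constrained to be acquired no
# earlier than their block's lead). Model evidence for a candidate
# structure is the grid-summed marginal likelihood, which factorizes over
# blocks because each block's emission depends only on its own lead.

traj_vectors <- function(traj) {
  ok <- traj$depth > 0
  if (!all(ok)) warning("dropping observation(s) with zero depth")
  list(t = traj$age[ok], k = traj$alt_reads[ok], n = traj$depth[ok],
       mean_vaf = if (any(ok)) mean(traj$alt_reads[ok] / traj$depth[ok]) else 0)
}

lead_of_block <- function(block, trajs) {
  mv <- vapply(block, function(v) traj_vectors(trajs[[v]])$mean_vaf, numeric(1))
  block[order(-mv, block)][1]
}

# ATMA profiling grid for one block: 0 .. latest observation age.
atma_grid_for <- function(trajs, block, step) {
  last <- max(unlist(lapply(block, function(v) trajs[[v]]$age)))
  seq(0, floor(last), by = step)
}

# Clone-size matrix [n_s x n_a]: exp(s (t - a)), 0 before acquisition.
size_grid <- function(s, a, t) {
  x <- exp(s %o% (t - a))
  x[, t < a] <- 0
  x
}

# Log-likelihood matrix [n_s x n_a] for a lead variant (its own size is the
# denominator competitor): p = x / (df (N + x)).
ll_grid_lead <- function(tv, s, a, params) {
  total <- matrix(sum(lchoose_cont(tv$n, tv$k)), length(s), length(a))
  for (j in seq_along(tv$t)) {
    x <- size_grid(s, a, tv$t[j])
    p <- pmin(pmax(x / (params$diploid_factor * (params$N + x)),
                   params$error_floor), 1 - 1e-12)
    total <- total + tv$k[j] * log(p) + (tv$n[j] - tv$k[j]) * log1p(-p)
  }
  total
}

# Profiled follower log-likelihood [n_s x n_a(lead)]: for each fitness and
# lead acquisition age, the best follower acquisition age a_f >= a_lead,
# with emission denominator driven by the lead size.
ll_grid_follower <- function(tv, s, a, params, nuisance = "profile") {
  n_s <- length(s); n_a <- length(a)
  lch <- sum(lchoose_cont(tv$n, tv$k))
  # per-observation numerator/denominator size matrices [n_s x n_a]
  Xn <- lapply(tv$t, function(t) size_grid(s, a, t))
  best <- matrix(-Inf, n_s, n_a)
  denom <- lapply(Xn, function(x)
    params$diploid_factor * (params$N + x))    # lead sizes enter here
  for (i_f in seq_len(n_a)) {
    ll <- 0
    for (j in seq_along(tv$t)) {
      p <- pmin(pmax(Xn[[j]][, i_f] / denom[[j]],
                     params$error_floor), 1 - 1e-12)
      ll <- ll + tv$k[j] * log(p) + (tv$n[j] - tv$k[j]) * log1p(-p)
    }
    # ll is [n_s x n_a(lead)]; follower age a[i_f] is invalid for leads
    # acquired later
    ll[, a > a[i_f]] <- -Inf
    best <- if (nuisance == "profile") pmax(best, ll)
            else logaddexp(best, ll)
  }
  if (nuisance != "profile") best <- best - log(n_a)
  best + lch
}

# elementwise log(exp(a) + exp(b)) without overflow
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

# Fit one block: profile (or marginalize) the log-likelihood over
# acquisition ages, posterior over the fitness grid, block evidence.
fit_block <- function(trajs, block, grid, params, nuisance = "profile") {
  s <- grid$s
  a <- atma_grid_for(trajs, block, grid$atma_step)
  lead <- lead_of_block(block, trajs)
  tv_lead <- traj_vectors(trajs[[lead]])
  ll <- ll_grid_lead(tv_lead, s, a, params)            # [n_s x n_a]
  for (f in setdiff(block, lead)) {
    llf <- ll_grid_follower(traj_vectors(trajs[[f]]), s, a, params,
                            nuisance = nuisance)
    ll <- ll + llf
  }
  prof <- if (nuisance == "profile") apply(ll, 1, max)
          else apply(ll, 1, logsumexp) - log(length(a))
  i_map <- which.max(prof)
  mass <- exp(prof - max(prof))
  mass <- mass / sum(mass)
  list(variants = block, lead = lead,
       map_s = s[i_map],
       posterior = data.frame(s = s, mass = mass),
       profile_ll = prof,
       log_evidence = logsumexp(prof) - log(length(s)))
}

#' Log-likelihood of trajectories under a candidate clonal structure
#'
#' Evaluates the binomial read-count log-likelihood of a participant's
#' trajectories given a partition of variants into clones, one fitness per
#' clone, and one acquisition age per variant. The model VAF is the
#' competition-aware form: variant `j`'s VAF at age `t` is
#' \eqn{x_j(t) / (d (N + \sum_b x^{lead}_b(t)))}, summing the lead-variant
#' size of every clone in the denominator. Observations at ages before a
#' variant's acquisition contribute through the sequencing-error floor VAF.
#'
#' @param trajectories Named list of trajectory data.frames (one per
#'   variant label, as in a `ch_participant`).
#' @param partition List of character vectors (blocks) covering the
#'   variant labels exactly once.
#' @param s_per_clone Numeric vector of fitness values, one per block.
#' @param atma_per_variant Named numeric vector of acquisition ages.
#' @param params A [ch_params()] object.
#' @return The log-likelihood (0 for an empty trajectory set).
#' @export
structure_loglik <- function(trajectories, partition, s_per_clone,
                             atma_per_variant, params = ch_params()) {
  if (!length(trajectories)) return(0)
  labs <- unlist(partition)
  if (anyDuplicated(labs) || !setequal(labs, names(trajectories)))
    condition_error("partition must cover every variant exactly once",
                    "clonedyn_parameter_error")
  if (any(s_per_clone < 0))
    condition_error("fitness values must be >= 0", "clonedyn_parameter_error")
  leads <- vapply(partition, lead_of_block, character(1), trajs = trajectories)
  denom_x <- function(t) {
    tot <- 0
    for (b in seq_along(partition))
      tot <- tot + clone_size(s_per_clone[b], atma_per_variant[[leads[b]]], t)
    tot
  }
  ll <- 0
  for (b in seq_along(partition)) for (v in partition[[b]]) {
    tv <- traj_vectors(trajectories[[v]])
    if (!length(tv$t)) next
    x <- clone_size(s_per_clone[b], atma_per_variant[[v]], tv$t)
    p <- pmax(x / (params$diploid_factor * (params$N + denom_x(tv$t))),
              params$error_floor)
    ll <- ll + sum(ll_binom(tv$k, tv$n, p))
  }
  if (is.nan(ll)) condition_error("log-likelihood is NaN", "clonedyn_numeric_error")
  ll
}

#' Fit one candidate clonal structure
#'
#' Computes, for each clone of `partition`, the posterior over the fitness
#' grid (acquisition ages profiled out in 1-year steps, with a clone's
#' non-lead variants constrained to be acquired no earlier than its lead)
#' and the grid-summed log evidence of the structure under a uniform prior
#' on fitness.
#'
#' @param trajectories Named list of trajectory data.frames.
#' @param partition List of blocks (character vectors of variant labels).
#' @param params A [ch_params()] object.
#' @param grid A [ch_grid()] object.
#' @param nuisance How acquisition ages are removed when scoring fitness:
#'   `"profile"` (default, maximized out) or `"marginalize"` (summed out
#'   under a uniform prior on the acquisition-age grid).
#' @return A list with `clones` (per-block fits: `variants`, `lead`,
#'   `map_s`, `posterior`, `log_evidence`) and the structure's total
#'   `log_evidence`.
#' @export
fit_structure <- function(trajectories, partition, params = ch_params(),
                          grid = ch_grid(),
                          nuisance = c("profile", "marginalize")) {
  nuisance <- match.arg(nuisance)
  clones <- lapply(partition, fit_block, trajs = trajectories,
                   grid = grid, params = params, nuisance = nuisance)
  list(clones = clones,
       log_evidence = sum(vapply(clones, `[[`, numeric(1), "log_evidence")))
}

#' Fit clonal dynamics for one participant
#'
#' The package's core estimator. Enumerates candidate clonal structures
#' (all set partitions for up to `max_exhaustive` variants; a greedy
#' agglomerative search above that), scores each by grid-summed marginal
#' likelihood, selects the maximum-evidence structure, and reports the
#' per-clone fitness posteriors, maximum a posteriori (MAP) fitness, the
#' per-variant age at the time of mutation acquisition (ATMA, estimated by
#' continuous maximum likelihood under the isolated growth model at the
#' MAP fitness), and MACS120. Evidence ties are broken toward the
#' partition with more independent clones, then canonical order.
#'
#' @param participant A `ch_participant` (from [build_trajectories()]) or a
#'   named list of trajectory data.frames.
#' @param params A [ch_params()] object.
#' @param grid A [ch_grid()] object.
#' @param max_exhaustive Exhaustive-enumeration limit (default 8).
#' @param nuisance Acquisition-age handling during structure scoring,
#'   `"profile"` (default) or `"marginalize"`; see [fit_structure()].
#' @return An object of class `ch_fit` with components `structure` (list of
#'   blocks), `clones` (per-clone posterior summaries), `variants` (per-
#'   variant table: clone index, MAP fitness, ATMA, MACS120), `candidates`
#'   (evidence of every scored structure) and the data the fit used.
#' @seealso [predict.ch_fit()], [estimate_atma()], [macs120()]
#' @examples
#' traj <- data.frame(participant_id = "P1", cohort = "synthetic",
#'                    gene = "JAK2", variant = "V617F",
#'                    age = c(70, 76, 82), alt_reads = c(40, 110, 300),
#'                    unique_alt_reads = NA, depth = 2000,
#'                    vaf = NA, gnomad_p = NA)
#' traj$vaf <- traj$alt_reads / traj$depth
#' fit <- ch_fit(list("JAK2:V617F" = traj), grid = ch_grid(s_step = 0.01))
#' coef(fit)
#' @export
ch_fit <- function(participant, params = ch_params(), grid = ch_grid(),
                   max_exhaustive = 8,
                   nuisance = c("profile", "marginalize")) {
  nuisance <- match.arg(nuisance)
  trajs <- if (inherits(participant, "ch_participant"))
    participant$trajectories else participant
  if (!length(trajs))
    condition_error("participant has no trajectories to fit",
                    "clonedyn_parameter_error")
  labels <- names(trajs)
  if (is.null(labels) || anyDuplicated(labels))
    condition_error("trajectories must be a uniquely named list",
                    "clonedyn_parameter_error")
  k <- length(labels)
  exhaustive <- k <= max_exhaustive
  if (exhaustive) {
    parts <- enumerate_structures(labels, max_exhaustive)
    fits <- lapply(parts, fit_structure, trajectories = trajs,
                   params = params, grid = grid, nuisance = nuisance)
  } else {
    gr <- greedy_structure_search(trajs, labels, params, grid, nuisance)
    parts <- gr$parts
    fits <- gr$fits
  }
  ev <- vapply(fits, `[[`, numeric(1), "log_evidence")
  nb <- vapply(parts, length, integer(1))
  keys <- vapply(parts, partition_key, character(1), variants = labels)
  # max evidence; ties -> more blocks, then canonical (rgs) order
  ord <- order(-ev, -nb, keys)
  best <- ord[1]
  tie <- sum(abs(ev - ev[best]) < 1e-9) > 1L
  sel <- fits[[best]]
  structure_sel <- parts[[best]]

  vt <- data.frame(variant = labels, clone = NA_integer_, s = NA_real_,
                   atma = NA_real_, atma_flag = NA_character_,
                   macs120 = NA_real_, log_macs120 = NA_real_,
                   lead = FALSE, stringsAsFactors = FALSE)
  for (b in seq_along(structure_sel)) {
    cl <- sel$clones[[b]]
    for (v in cl$variants) {
      i <- match(v, vt$variant)
      vt$clone[i] <- b
      vt$s[i] <- cl$map_s
      at <- estimate_atma(trajs[[v]], cl$map_s, params,
                          s_min = min(grid$s) + 1e-12)
      vt$atma[i] <- at$atma
      vt$atma_flag[i] <- at$flag
      if (!is.na(at$atma)) {
        m <- macs120(cl$map_s, at$atma, horizon = params$max_age)
        vt$macs120[i] <- m$macs120
        vt$log_macs120[i] <- m$log_macs120
      }
      vt$lead[i] <- v == cl$lead
    }
  }
  res <- list(participant_id = if (inherits(participant, "ch_participant"))
                participant$participant_id else NA_character_,
              trajectories = trajs,
              structure = structure_sel,
              clones = sel$clones,
              variants = vt,
              log_evidence = ev[best],
              candidates = data.frame(key = keys, n_blocks = nb,
                                      log_evidence = ev,
                                      stringsAsFactors = FALSE),
              tie = tie, exhaustive = exhaustive,
              params = params, grid = grid)
  class(res) <- "ch_fit"
  res
}

# Greedy agglomerative structure search for many-variant participants:
# start from singletons, merge the block pair that most increases evidence,
# stop when no merge improves.
greedy_structure_search <- function(trajs, labels, params, grid,
                                    nuisance = "profile") {
  current <- lapply(labels, function(v) v)
  fit_cur <- fit_structure(trajs, current, params, grid, nuisance)
  parts <- list(current); fits <- list(fit_cur)
  repeat {
    if (length(current) == 1L) break
    best_gain <- 0; best <- NULL
    for (i in seq_len(length(current) - 1L)) for (j in (i + 1L):length(current)) {
      cand <- current[-c(i, j)]
      cand[[length(cand) + 1L]] <- c(current[[i]], current[[j]])
      f <- fit_structure(trajs, cand, params, grid, nuisance)
      parts[[length(parts) + 1L]] <- cand
      fits[[length(fits) + 1L]] <- f
      gain <- f$log_evidence - fit_cur$log_evidence
      if (gain > best_gain + 1e-12) { best_gain <- gain; best <- length(parts) }
    }
    if (is.null(best)) break
    current <- parts[[best]]
    fit_cur <- fits[[best]]
  }
  list(parts = parts, fits = fits)
}

#' Fit clonal dynamics for a whole cohort
#'
#' Applies [ch_fit()] to every participant with at least one trajectory.
#'
#' @param participants Named list of `ch_participant` objects.
#' @param ... Passed to [ch_fit()].
#' @return Named list of `ch_fit` objects (participants without variants
#'   are skipped; they re-enter at the metrics stage).
#' @export
ch_fit_cohort <- function(participants, ...) {
  has <- vapply(participants, function(p) length(p$trajectories) > 0, logical(1))
  fits <- lapply(participants[has], ch_fit, ...)
  names(fits) <- names(participants)[has]
  fits
}
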