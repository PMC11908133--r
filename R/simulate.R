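# Synthetic-cohort generator: forward model of the inference target with
# known ground truth, emulating three longitudinal aging-cohort designs.

#' Simulate latent clone sizes
#'
#' One clone's size (cells) at the sample ages, either deterministically
#' (`x(t) = exp(s (t - atma))`, the model the estimator inverts) or as one
#' realization of a linear birth-death process with per-cell birth rate
#' `1 + s` and death rate 1 started from a single cell at `atma`,
#' rejection-conditioned on non-extinction by the first sample age (clones
#' observed in data necessarily survived). Ages before `atma` yield size 0.
#'
#' @param s Per-year net fitness, `s >= 0`.
#' @param atma Acquisition age, years.
#' @param sample_ages Sorted ages at which to report the size.
#' @param params A [ch_params()] object.
#' @param mode `"deterministic"` (default) or `"birth_death"`.
#' @param birth_rate,death_rate Per-cell rates for the birth-death mode
#'   (defaults `1 + s` and 1 per cell-year; only the net rate is
#'   identifiable from trajectories, these set the noise timescale).
#' @param condition Condition the birth-death realization on survival to
#'   the first sample age (default `TRUE`).
#' @return Numeric vector of clone sizes at `sample_ages`.
#' @examples
#' simulate_clone(0.1, 50, 120)  # exp(7)
#' @export
simulate_clone <- function(s, atma, sample_ages, params = ch_params(),
                           mode = c("deterministic", "birth_death"),
                           birth_rate = 1 + s, death_rate = 1,
                           condition = TRUE) {
  mode <- match.arg(mode)
  if (s < 0) condition_error("fitness `s` must be >= 0", "clonedyn_parameter_error")
  if (!length(sample_ages)) return(numeric(0))
  if (is.unsorted(sample_ages))
    condition_error("`sample_ages` must be sorted", "clonedyn_parameter_error")
  if (mode == "deterministic") return(clone_size(s, atma, sample_ages))
  pre <- sample_ages < atma
  out <- numeric(length(sample_ages))
  if (any(!pre))
    out[!pre] <- bd_gillespie(atma, sample_ages[!pre], birth_rate, death_rate,
                              condition)
  out
}

cohort_designs <- list(
  LBC = list(baseline = c(69.5, 70.5), offsets = c(0, 6, 12), depth = 2000,
             female_frac = 0.5),
  SardiNIA = list(baseline = c(50, 70), offsets = c(0, 5, 10, 15, 20),
                  depth = 1000, female_frac = 0.57),
  WHI = list(baseline = c(50, 79), offsets = c(0, 1, 3, 6, 9, 15.4),
             depth = 1500, female_frac = 1))

#' Cohort visit design template
#'
#' Visit-age templates for the three emulated sampling designs: `LBC`
#' (3 waves near ages 70/76/82), `SardiNIA` (5 waves over 20 years) and
#' `WHI` (postmenopausal women enrolled at ages 50-79 with visits at years
#' 1/3/6/9 plus a late-life visit), each with a template sequencing depth.
#'
#' @param template One of `"LBC"`, `"SardiNIA"`, `"WHI"`.
#' @return A list with `baseline` (age range), `offsets` (visit offsets in
#'   years), `depth` (template mean depth) and `female_frac`.
#' @export
cohort_design <- function(template = c("LBC", "SardiNIA", "WHI")) {
  template <- match.arg(template)
  cohort_designs[[template]]
}

draw_depths <- function(n, mean_depth, dispersion = 20) {
  pmax(1L, stats::rnbinom(n, mu = mean_depth, size = dispersion))
}

#' Simulate one participant with known ground truth
#'
#' Forward model of the estimator: latent clone sizes follow the growth
#' model (deterministic by default), each variant's model VAF follows the
#' competition-aware formula (denominator `N` plus the lead-variant size
#' of every clone), and observed alt-read counts are
#' `Binomial(depth, VAF)` with per-visit depths drawn from a negative
#' binomial around the design's template depth. Within a clone, variants
#' share the fitness and non-lead variants are acquired later, so their
#' sizes never exceed the lead's.
#'
#' @param scenario List of clones; each clone is a list with `s` (fitness)
#'   and `variants`, a data.frame with columns `gene`, `variant`, `atma`.
#' @param design A [cohort_design()] list (or one of its names).
#' @param participant_id Identifier string.
#' @param cohort Cohort label written to the observation rows.
#' @param visit_ages Optional explicit visit ages (otherwise drawn from the
#'   design template).
#' @param depth_dispersion Negative-binomial size parameter (default 20).
#' @param sex `"F"` or `"M"` (drawn from the design if missing).
#' @param params A [ch_params()] object.
#' @param mode Latent-size mode passed to [simulate_clone()]; in
#'   `"birth_death"` mode the clone lead is stochastic and followers scale
#'   by the deterministic within-clone ratio.
#' @return A list with `participant` (a `ch_participant`), `observations`
#'   (the table rows) and `truth` (per-variant ground truth: clone index,
#'   fitness, ATMA, lead flag).
#' @export
simulate_participant <- function(scenario, design = "LBC",
                                 participant_id = "SIM1",
                                 cohort = "synthetic",
                                 visit_ages = NULL,
                                 depth_dispersion = 20, sex = NULL,
                                 params = ch_params(),
                                 mode = "deterministic") {
  if (is.character(design)) design <- cohort_design(design)
  if (is.null(visit_ages)) {
    b <- stats::runif(1, design$baseline[1], design$baseline[2])
    visit_ages <- b + design$offsets
  }
  if (is.null(sex))
    sex <- if (stats::runif(1) < design$female_frac) "F" else "M"
  labels <- unlist(lapply(scenario, function(cl)
    paste(cl$variants$gene, cl$variants$variant, sep = ":")))
  if (anyDuplicated(labels))
    condition_error("clone variant labels must be distinct",
                    "clonedyn_parameter_error")

  # latent sizes per variant at each visit; clone lead = earliest atma
  sizes <- list(); truth <- list()
  for (b in seq_along(scenario)) {
    cl <- scenario[[b]]
    vd <- cl$variants
    lead_i <- order(vd$atma, vd$variant)[1]
    x_lead <- simulate_clone(cl$s, vd$atma[lead_i], visit_ages, params,
                             mode = mode)
    for (i in seq_len(nrow(vd))) {
      lab <- paste(vd$gene[i], vd$variant[i], sep = ":")
      ratio <- exp(-cl$s * (vd$atma[i] - vd$atma[lead_i]))
      xi <- if (i == lead_i) x_lead else x_lead * ratio
      xi[visit_ages < vd$atma[i]] <- 0
      sizes[[lab]] <- list(x = xi, lead = i == lead_i, clone = b)
      truth[[lab]] <- data.frame(participant_id = participant_id,
                                 gene = vd$gene[i], variant = vd$variant[i],
                                 clone = b, s = cl$s, atma = vd$atma[i],
                                 lead = i == lead_i,
                                 stringsAsFactors = FALSE)
    }
  }
  denom <- params$N
  for (lab in names(sizes)) if (sizes[[lab]]$lead) denom <- denom + sizes[[lab]]$x

  rows <- list()
  for (lab in names(sizes)) {
    vaf <- sizes[[lab]]$x / (params$diploid_factor * denom)
    depth <- draw_depths(length(visit_ages), design$depth, depth_dispersion)
    alt <- stats::rbinom(length(visit_ages), depth, pmin(vaf, 1))
    gv <- strsplit(lab, ":", fixed = TRUE)[[1]]
    rows[[lab]] <- data.frame(participant_id = participant_id, cohort = cohort,
                              gene = gv[1], variant = gv[2], age = visit_ages,
                              alt_reads = alt, unique_alt_reads = pmax(0, alt - 1),
                              depth = depth, vaf = alt / depth,
                              gnomad_p = stats::runif(1, 0, 0.05),
                              stringsAsFactors = FALSE)
  }
  obs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), cohort = character(0),
               gene = character(0), variant = character(0), age = numeric(0),
               alt_reads = numeric(0), unique_alt_reads = numeric(0),
               depth = numeric(0), vaf = numeric(0), gnomad_p = numeric(0))
  rownames(obs) <- NULL
  cov <- data.frame(participant_id = participant_id, cohort = cohort,
                    sex = sex, age_first_obs = min(visit_ages),
                    stringsAsFactors = FALSE)
  part <- build_trajectories(obs, covariates = cov)[[1]]
  list(participant = part, observations = obs,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

default_gene_fitness_profile <- function() {
  cats <- gene_category_table()
  means <- c(ER = 0.09, RS = 0.20, ST = 0.14, TF = 0.12, CS = 0.11)
  data.frame(gene = cats$gene, category = cats$category,
             mean_s = unname(means[cats$category]), sdlog = 0.4,
             stringsAsFactors = FALSE)
}

#' Simulate a longitudinal cohort with ground truth
#'
#' Draws `n_participants` under one of the three cohort designs. Each
#' participant carries 1-3 variants (multi-variant participants co-locate
#' their variants on one clone with probability `p_cooccur`); genes are
#' drawn from the functional-category panel with gene-level fitness drawn
#' log-normally around category means (splicing genes highest, epigenetic
#' regulators lowest). Acquisition ages are placed so the clone is at a
#' detectable VAF by the first visit, as in a carrier cohort. Survival
#' times and censoring come from a proportional-hazards model on the
#' z-scored true metrics.
#'
#' @param template `"LBC"`, `"SardiNIA"` or `"WHI"`.
#' @param n_participants Number of participants (>= 1).
#' @param gene_fitness_profile Data.frame with `gene`, `mean_s`, `sdlog`
#'   (default: category-mean profile).
#' @param p_multi Probabilities of 1, 2 or 3 variants (default
#'   `c(0.75, 0.2, 0.05)`).
#' @param p_cooccur Probability that a multi-variant participant's variants
#'   share one clone (default 0.4).
#' @param log_hazard_coefs,baseline_hazard,censor_rate Passed to
#'   [simulate_survival()].
#' @param params A [ch_params()] object.
#' @param mode Latent-size mode (default deterministic).
#' @return A list of tables: `variants`, `covariates` (with follow-up and
#'   event columns), `truth`, plus `participants` (built records).
#' @export
simulate_cohort <- function(template = c("LBC", "SardiNIA", "WHI"),
                            n_participants,
                            gene_fitness_profile = default_gene_fitness_profile(),
                            p_multi = c(0.75, 0.2, 0.05), p_cooccur = 0.4,
                            log_hazard_coefs = c(z_macs120 = 0.3, z_age = 0.8,
                                                 sexM = 0.3),
                            baseline_hazard = 0.02, censor_rate = 0.7,
                            params = ch_params(), mode = "deterministic") {
  template <- match.arg(template)
  if (n_participants < 1)
    condition_error("`n_participants` must be >= 1", "clonedyn_parameter_error")
  design <- cohort_design(template)
  obs <- list(); covs <- list(); truths <- list(); parts <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("%s_%04d", template, i)
    b <- stats::runif(1, design$baseline[1], design$baseline[2])
    visit_ages <- b + design$offsets
    k <- sample.int(3, 1, prob = p_multi)
    genes <- sample(gene_fitness_profile$gene, k)
    s_draw <- function(g) {
      row <- gene_fitness_profile[gene_fitness_profile$gene == g, ]
      min(stats::rlnorm(1, log(row$mean_s), row$sdlog), 0.6)
    }
    mk_var <- function(g, s) {
      # place acquisition so first-visit VAF is detectable (carrier cohort)
      target <- exp(stats::runif(1, log(0.005), log(0.2))) / 2
      x1 <- target * params$diploid_factor * params$N /
        (1 - target * params$diploid_factor)
      atma <- max(0, visit_ages[1] - log(x1) / s)
      data.frame(gene = g, variant = sprintf("v%s", substr(g, 1, 3)),
                 atma = atma, stringsAsFactors = FALSE)
    }
    if (k > 1 && stats::runif(1) < p_cooccur) {
      s <- s_draw(genes[1])
      vs <- do.call(rbind, lapply(genes, mk_var, s = s))
      vs$variant <- paste0(vs$variant, seq_len(k))
      # followers acquired after the lead
      o <- order(vs$atma)
      vs$atma[o[-1]] <- vs$atma[o[1]] + cumsum(stats::runif(k - 1, 1, 10))
      scen <- list(list(s = s, variants = vs))
    } else {
      scen <- lapply(seq_len(k), function(j) {
        s <- s_draw(genes[j])
        v <- mk_var(genes[j], s)
        v$variant <- paste0(v$variant, j)
        list(s = s, variants = v)
      })
    }
    sim <- simulate_participant(scen, design, participant_id = pid,
                                cohort = template, visit_ages = visit_ages,
                                params = params, mode = mode)
    obs[[i]] <- sim$observations
    covs[[i]] <- data.frame(participant_id = pid, cohort = template,
                            sex = sim$participant$sex, age_first_obs = b,
                            stringsAsFactors = FALSE)
    truths[[i]] <- sim$truth
    parts[[pid]] <- sim$participant
  }
  variants <- do.call(rbind, obs)
  covariates <- do.call(rbind, covs)
  truth <- do.call(rbind, truths)
  rownames(variants) <- rownames(covariates) <- rownames(truth) <- NULL
  metrics <- truth_metrics(truth, covariates, variants, params)
  surv <- simulate_survival(metrics, log_hazard_coefs, baseline_hazard,
                            censor_rate)
  covariates$followup_years <- surv$followup_years[match(covariates$participant_id,
                                                         surv$participant_id)]
  covariates$event <- surv$event[match(covariates$participant_id,
                                       surv$participant_id)]
  list(variants = variants, covariates = covariates, truth = truth,
       metrics = metrics, participants = parts)
}

#' Ground-truth participant metrics
#'
#' The true counterparts of [cohort_metrics()]: per participant, the
#' maximum model VAF over visits, maximum true fitness, and maximum true
#' MACS120 (log scale z-scored).
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param covariates Covariate table.
#' @param variants Observation table (for observed max VAF).
#' @param params A [ch_params()] object.
#' @return Metrics data.frame with z-scored columns.
#' @export
truth_metrics <- function(truth, covariates, variants, params = ch_params()) {
  ids <- covariates$participant_id
  mv <- vapply(ids, function(pid) {
    rows <- variants[variants$participant_id == pid, ]
    if (!nrow(rows)) 0 else max(rows$alt_reads / rows$depth)
  }, numeric(1))
  mf <- vapply(ids, function(pid) {
    rows <- truth[truth$participant_id == pid, ]
    if (is.null(rows) || !nrow(rows)) 0 else max(rows$s)
  }, numeric(1))
  lm120 <- vapply(ids, function(pid) {
    rows <- truth[truth$participant_id == pid & truth$lead, ]
    if (is.null(rows) || !nrow(rows)) 0
    else max(rows$s * (params$max_age - rows$atma))
  }, numeric(1))
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  data.frame(participant_id = ids, cohort = covariates$cohort,
             sex = covariates$sex, age_first_obs = covariates$age_first_obs,
             max_vaf = mv, max_fitness = mf, log_macs120 = lm120,
             macs120 = exp(lm120),
             z_max_vaf = zs(mv), z_max_fitness = zs(mf),
             z_macs120 = zs(lm120), z_age = zs(covariates$age_first_obs),
             stringsAsFactors = FALSE)
}

#' Simulate longitudinal blood markers from the linear mixed model
#'
#' Generates marker values from the association stage's own model:
#' `marker ~ age * maxVAF + maxFitness + MACS120` with a participant
#' random intercept and Gaussian residuals. Metric covariates enter
#' z-scored; age enters centered on the cohort mean visit age.
#'
#' @param metrics Metrics data.frame ([truth_metrics()] or
#'   [cohort_metrics()]).
#' @param visit_ages Named list (by participant) of visit ages, or a
#'   matrix-like recycled vector; every participant needs >= 2 visits.
#' @param fixed_effects Named coefficients: `intercept`, `age`, `maxVAF`,
#'   `age_maxVAF`, `maxFitness`, `MACS120` (missing entries are 0).
#' @param random_intercept_sd,residual_sd Standard deviations (defaults 0.5
#'   and 1).
#' @param marker_name Marker label (default `"marker1"`).
#' @param binary Emit Bernoulli values through a logistic link (default
#'   `FALSE`).
#' @return Long marker data.frame (`participant_id`, `cohort`, `age`,
#'   `marker_name`, `value`).
#' @export
simulate_markers <- function(metrics, visit_ages, fixed_effects = c(),
                             random_intercept_sd = 0.5, residual_sd = 1,
                             marker_name = "marker1", binary = FALSE) {
  fe <- c(intercept = 0, age = 0, maxVAF = 0, age_maxVAF = 0,
          maxFitness = 0, MACS120 = 0)
  fe[names(fixed_effects)] <- fixed_effects
  if (is.numeric(visit_ages))
    visit_ages <- stats::setNames(rep(list(visit_ages),
                                      nrow(metrics)), metrics$participant_id)
  nv <- vapply(visit_ages[metrics$participant_id], length, integer(1))
  if (any(nv < 2))
    condition_error("every participant needs >= 2 marker visits",
                    "clonedyn_parameter_error")
  all_ages <- unlist(visit_ages[metrics$participant_id])
  age_c <- mean(all_ages)
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    ages <- visit_ages[[metrics$participant_id[i]]]
    u <- stats::rnorm(1, 0, random_intercept_sd)
    eta <- fe["intercept"] + fe["age"] * (ages - age_c) +
      fe["maxVAF"] * metrics$z_max_vaf[i] +
      fe["age_maxVAF"] * (ages - age_c) * metrics$z_max_vaf[i] +
      fe["maxFitness"] * metrics$z_max_fitness[i] +
      fe["MACS120"] * metrics$z_macs120[i] + u
    val <- if (binary) stats::rbinom(length(ages), 1, stats::plogis(eta))
           else eta + stats::rnorm(length(ages), 0, residual_sd)
    data.frame(participant_id = metrics$participant_id[i],
               cohort = metrics$cohort[i], age = ages,
               marker_name = marker_name, value = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate survival times under proportional hazards
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(X beta)` on the z-scored covariate columns of
#' `metrics` (plus a `sexM` indicator). Censoring times are drawn
#' independently of the event process from an exponential whose rate is
#' chosen so that, at the baseline hazard, a fraction `censor_rate` of
#' records is censored; the observed time is the minimum of the two.
#'
#' @param metrics Metrics data.frame with z-scored covariate columns.
#' @param log_hazard_coefs Named coefficients on columns of `metrics`
#'   (names like `z_macs120`, `z_max_vaf`, `z_max_fitness`, `z_age`,
#'   `sexM`).
#' @param baseline_hazard Baseline event rate per year (> 0).
#' @param censor_rate Probability a record is censored (default 0.7).
#' @return Data.frame `participant_id`, `followup_years`, `event`.
#' @export
simulate_survival <- function(metrics, log_hazard_coefs = c(),
                              baseline_hazard = 0.02, censor_rate = 0.7) {
  if (baseline_hazard <= 0)
    condition_error("`baseline_hazard` must be positive", "clonedyn_parameter_error")
  if (censor_rate < 0 || censor_rate > 1)
    condition_error("`censor_rate` must be in [0, 1]", "clonedyn_parameter_error")
  n <- nrow(metrics)
  eta <- rep(0, n)
  for (nm in names(log_hazard_coefs)) {
    xcol <- if (nm == "sexM") as.numeric(metrics$sex == "M") else metrics[[nm]]
    if (is.null(xcol))
      condition_error(paste0("unknown hazard covariate: ", nm),
                      "clonedyn_parameter_error")
    eta <- eta + log_hazard_coefs[[nm]] * xcol
  }
  tt <- stats::rexp(n, baseline_hazard * exp(eta))
  cc <- if (censor_rate >= 1) rep(0, n)
        else if (censor_rate <= 0) rep(Inf, n)
        else stats::rexp(n, baseline_hazard * censor_rate / (1 - censor_rate))
  data.frame(participant_id = metrics$participant_id,
             followup_years = pmin(tt, cc), event = as.integer(tt <= cc),
             stringsAsFactors = FALSE)
}
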