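# Shared fixture builders and independent oracles.

make_traj <- function(gene, variant, ages, alt, depth = 2000, pid = "P1",
                      cohort = "synthetic", uao = NA, gnomad = NA) {
  data.frame(participant_id = pid, cohort = cohort, gene = gene,
             variant = variant, age = ages, alt_reads = alt,
             unique_alt_reads = uao, depth = depth, vaf = alt / depth,
             gnomad_p = gnomad, stringsAsFactors = FALSE)
}

# binomial draws around the isolated deterministic VAF
sim_single_traj <- function(s, atma, ages, depth = 2000, gene = "JAK2",
                            variant = "V617F", params = ch_params()) {
  v <- predict_isolated(s, atma, ages, params)
  make_traj(gene, variant, ages, stats::rbinom(length(ages), depth, v), depth)
}

# recovery-study design: 4 waves at 5-year spacing, depth 2000, first-visit
# expected VAF 0.5%
recovery_ages <- c(80, 85, 90, 95)
recovery_atma <- function(s, first_vaf = 0.005, params = ch_params()) {
  x1 <- first_vaf * params$diploid_factor * params$N /
    (1 - first_vaf * params$diploid_factor)
  max(0, recovery_ages[1] - log(x1) / s)
}

# the 5-variant filter toy: exactly 2 variants pass, with reason-coded
# rejections (AO, germline-stable, gnomad)
filter_fixture <- function() {
  rbind(
    make_traj("JAK2", "V617F", c(70, 76, 82), c(40, 80, 160), 2000,
              uao = 10, gnomad = 0.01),
    make_traj("TET2", "T1", 70, 4, 200),                      # AO = 4
    make_traj("DNMT3A", "G1", c(70, 76, 82), c(500, 490, 510), 1000),
    make_traj("ASXL1", "A1", c(70, 76), c(30, 35), 1000, gnomad = 0.5),
    make_traj("SF3B1", "S1", c(70, 76), c(5, 30), 1000))      # 0.005 then 0.03
}

# Independent set-partition enumeration: grow partitions by inserting each
# element into every existing block or a new one (different algorithm from
# the package's restricted-growth-string enumeration).
oracle_partitions <- function(items) {
  parts <- list(list(items[1]))
  for (x in items[-1]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], x)
        nxt[[length(nxt) + 1L]] <- q
      }
      nxt[[length(nxt) + 1L]] <- c(p, list(x))
    }
    parts <- nxt
  }
  parts
}

# Independent nested-loop evidence: same model definition as the package
# (per-block factorized evidence, profiled acquisition ages, uniform grid
# prior) computed with direct loops and scalar arithmetic.
oracle_evidence <- function(trajs, partition, s_grid, params,
                            atma_step = 1) {
  ll_point <- function(k, n, p) {
    p <- min(max(p, params$error_floor), 1 - 1e-12)
    lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
      k * log(p) + (n - k) * log1p(-p)
  }
  total <- 0
  for (block in partition) {
    mean_vaf <- sapply(block, function(v)
      mean(trajs[[v]]$alt_reads / trajs[[v]]$depth))
    lead <- block[order(-mean_vaf, block)][1]
    a_grid <- seq(0, floor(max(sapply(block, function(v) max(trajs[[v]]$age)))),
                  by = atma_step)
    prof <- numeric(length(s_grid))
    for (i_s in seq_along(s_grid)) {
      s <- s_grid[i_s]
      best <- -Inf
      for (a_l in a_grid) {
        tr <- trajs[[lead]]
        ll <- 0
        for (j in seq_len(nrow(tr))) {
          x <- if (tr$age[j] < a_l) 0 else exp(s * (tr$age[j] - a_l))
          ll <- ll + ll_point(tr$alt_reads[j], tr$depth[j],
                              x / (params$diploid_factor * (params$N + x)))
        }
        for (f in setdiff(block, lead)) {
          trf <- trajs[[f]]
          best_f <- -Inf
          for (a_f in a_grid[a_grid >= a_l]) {
            llf <- 0
            for (j in seq_len(nrow(trf))) {
              xl <- if (trf$age[j] < a_l) 0 else exp(s * (trf$age[j] - a_l))
              xf <- if (trf$age[j] < a_f) 0 else exp(s * (trf$age[j] - a_f))
              llf <- llf + ll_point(trf$alt_reads[j], trf$depth[j],
                                    xf / (params$diploid_factor * (params$N + xl)))
            }
            best_f <- max(best_f, llf)
          }
          ll <- ll + best_f
        }
        best <- max(best, ll)
      }
      prof[i_s] <- best
    }
    m <- max(prof)
    total <- total + m + log(sum(exp(prof - m))) - log(length(s_grid))
  }
  total
}

# minimal stand-in fit object for prediction-level tests
fake_fit <- function(variants, params = ch_params()) {
  structure(list(variants = variants, params = params,
                 participant_id = "FAKE"), class = "ch_fit")
}

# z-scored synthetic metrics table for association-stage tests
fake_metrics <- function(n, seed_offset = 0) {
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  data.frame(participant_id = sprintf("M%04d", seq_len(n)),
             cohort = "synthetic",
             sex = sample(c("F", "M"), n, replace = TRUE),
             age_first_obs = stats::runif(n, 55, 85),
             max_vaf = stats::runif(n, 0, 0.4),
             max_fitness = stats::runif(n, 0, 0.4),
             log_macs120 = stats::runif(n, 0, 25),
             stringsAsFactors = FALSE) |>
    within({
      macs120 <- exp(log_macs120)
      z_max_vaf <- zs(max_vaf)
      z_max_fitness <- zs(max_fitness)
      z_macs120 <- zs(log_macs120)
      z_age <- zs(age_first_obs)
    })
}
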