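test_that("ATMA estimation inverts noiseless forward simulation", {
  p <- ch_params()
  for (s in c(0.08, 0.15, 0.25, 0.4)) for (atma in c(10, 30, 50)) {
    ages <- c(70, 76, 82)
    v <- predict_isolated(s, atma, ages, p)
    # identifiability window: below the detection floor or at saturation
    # the trajectory carries essentially no timing information
    if (min(v) < 2e-4 || max(v) > 0.49) next
    tr <- make_traj("G", "v", ages, v * 2000)
    est <- estimate_atma(tr, s, p)
    expect_lt(abs(est$atma - atma), 1e-3)
  }
})

test_that("single-cell VAF dates acquisition to the observation age", {
  p <- ch_params()
  t_obs <- 65
  v1 <- 1 / (p$diploid_factor * (p$N + 1))
  tr <- make_traj("G", "v", t_obs, v1 * 1e6, 1e6)
  est <- estimate_atma(tr, 0.1, p)
  expect_equal(est$atma, t_obs, tolerance = 1e-3)
  expect_equal(est$flag, "boundary-upper")
})

test_that("ATMA boundary clamping and unidentifiable flags", {
  p <- ch_params()
  # VAF too high for the fitness: optimum pinned at birth
  tr <- make_traj("G", "v", 70, 0.2 * 2000)
  est <- estimate_atma(tr, 0.05, p)
  expect_equal(est$atma, 0)
  expect_equal(est$flag, "boundary-lower")
  expect_true(is.na(estimate_atma(tr, 0, p)$atma))
  expect_equal(estimate_atma(tr, 0, p)$flag, "unidentifiable")
  tr0 <- make_traj("G", "v", c(70, 76), c(0, 0))
  expect_equal(estimate_atma(tr0, 0.2, p)$flag, "all-zero")
})

test_that("context-aware predictions collapse to isolated for a lone clone", {
  p <- ch_params()
  vt <- data.frame(variant = "A", clone = 1, s = 0.25, atma = 45,
                   atma_flag = NA, macs120 = NA, log_macs120 = NA, lead = TRUE)
  fit <- fake_fit(vt, p)
  pr <- predict_context(fit, c(70, 90, 120))
  expect_equal(pr$vaf_context, pr$vaf_isolated, tolerance = 1e-15)
})

test_that("two equal clones halve toward the closed-form competitive VAF", {
  p <- ch_params()
  vt <- data.frame(variant = c("A", "B"), clone = c(1, 2), s = 0.3,
                   atma = 40, atma_flag = NA, macs120 = NA,
                   log_macs120 = NA, lead = TRUE)
  fit <- fake_fit(vt, p)
  t <- c(70, 90, 110)
  pr <- predict_context(fit, t)
  x <- clone_size(0.3, 40, t)
  expect_equal(pr$vaf_context[pr$variant == "A"], x / (2 * (p$N + 2 * x)),
               tolerance = 1e-12)
  expect_true(all(pr$vaf_context < pr$vaf_isolated))
})

test_that("block leads enter the competition denominator once per clone", {
  p <- ch_params()
  # one singleton clone and one two-variant clone (lead + later follower)
  vt <- data.frame(variant = c("A", "B", "C"), clone = c(1, 2, 2),
                   s = c(0.2, 0.3, 0.3), atma = c(35, 40, 55),
                   atma_flag = NA, macs120 = NA, log_macs120 = NA,
                   lead = c(TRUE, TRUE, FALSE))
  fit <- fake_fit(vt, p)
  t <- 100
  pr <- predict_context(fit, t)
  xa <- clone_size(0.2, 35, t); xb <- clone_size(0.3, 40, t)
  xc <- clone_size(0.3, 55, t)
  den <- 2 * (p$N + xa + xb)   # leads A and B only, C is not a lead
  expect_equal(pr$vaf_context, c(xa, xb, xc) / den, tolerance = 1e-12)
})

test_that("competition never increases a variant's VAF (randomized sweep)", {
  p <- ch_params()
  set.seed(301)
  for (i in 1:100) {
    n_cl <- sample(2:4, 1)
    vt <- data.frame(variant = paste0("v", seq_len(n_cl)),
                     clone = seq_len(n_cl),
                     s = runif(n_cl, 0.05, 0.5),
                     atma = runif(n_cl, 0, 80), atma_flag = NA,
                     macs120 = NA, log_macs120 = NA, lead = TRUE)
    fit <- fake_fit(vt, p)
    tt <- sort(runif(4, 40, 120))
    pr <- predict_context(fit, tt)
    expect_true(all(pr$vaf_context <= pr$vaf_isolated + 1e-15))
  }
})

test_that("cohort-level isolated-vs-context summary matches brute force", {
  p <- ch_params()
  vt1 <- data.frame(variant = "A", clone = 1, s = 0.25, atma = 30,
                    atma_flag = NA, macs120 = NA, log_macs120 = NA, lead = TRUE)
  vt2 <- data.frame(variant = c("A", "B"), clone = c(1, 2), s = c(0.3, 0.28),
                    atma = c(30, 35), atma_flag = NA, macs120 = NA,
                    log_macs120 = NA, lead = TRUE)
  fits <- list(P1 = fake_fit(vt1, p), P2 = fake_fit(vt2, p))
  cmp <- compare_isolated_vs_context(fits, t = 120)
  # brute-force recomputation
  iso <- function(s, a) predict_isolated(s, a, 120, p)
  x2 <- clone_size(c(0.3, 0.28), c(30, 35), 120)
  ctx2 <- x2 / (2 * (p$N + sum(x2)))
  deltas <- c(0, iso(0.3, 30) - ctx2[1], iso(0.28, 35) - ctx2[2])
  expect_equal(cmp$summary$mean_abs_delta, mean(abs(deltas)), tolerance = 1e-12)
  expect_equal(cmp$summary$frac_participants_over,
               mean(c(0, max(deltas[2:3])) > 0.2), tolerance = 1e-12)
  # single-variant participants have delta exactly 0
  expect_equal(cmp$table$delta[cmp$table$participant_id == "P1"], 0)
  expect_true(all(cmp$table$delta[cmp$table$participant_id == "P2"] > 0))
})

test_that("participant metrics take maxima and flag variant-free records", {
  p <- ch_params()
  obs <- rbind(make_traj("JAK2", "a", c(70, 76), c(100, 300)),
               make_traj("TET2", "b", c(70, 76), c(40, 60)))
  cov <- data.frame(participant_id = c("P1", "P2"), cohort = "LBC",
                    sex = "F", age_first_obs = 70)
  parts <- build_trajectories(obs, covariates = cov)
  fit <- ch_fit(parts$P1)
  m1 <- participant_metrics(parts$P1, fit)
  expect_equal(m1$max_vaf, 300 / 2000)
  expect_equal(m1$max_fitness, max(fit$variants$s))
  leads <- fit$variants[fit$variants$lead, ]
  expect_equal(m1$macs120,
               max(exp(leads$s * (120 - leads$atma))), tolerance = 1e-9)
  m2 <- participant_metrics(parts$P2)
  expect_equal(unname(unlist(m2[c("max_vaf", "max_fitness", "macs120")])),
               c(0, 0, 0))
  expect_equal(m2$flag, "no-variants")
  tab <- cohort_metrics(parts, list(P1 = fit))
  expect_equal(nrow(tab), 2)
  expect_equal(mean(tab$z_max_vaf), 0, tolerance = 1e-12)
})
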