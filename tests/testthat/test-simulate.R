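test_that("birth-death realizations match the conditioned analytic mean", {
  set.seed(101)
  s <- 0.2; b <- 1 + s; d <- 1; atma <- 40; age <- 70
  n_rep <- 4000
  sizes <- replicate(n_rep, simulate_clone(s, atma, age, mode = "birth_death"))
  # conditioned mean of a linear birth-death process from one cell:
  # E[Z(t) | Z(t) > 0] = e^{st} / (1 - alpha(t)),
  # alpha(t) = d (e^{st} - 1) / (b e^{st} - d)
  t <- age - atma
  alpha <- d * (exp(s * t) - 1) / (b * exp(s * t) - d)
  mu <- exp(s * t) / (1 - alpha)
  se <- stats::sd(sizes) / sqrt(n_rep)
  expect_lt(abs(mean(sizes) - mu), 3 * se)
  expect_true(all(sizes == floor(sizes) & sizes >= 0))
})

test_that("birth-death paths are integers without resurrection", {
  set.seed(102)
  ages <- c(50, 60, 70, 80)
  for (i in 1:50) {
    z <- simulate_clone(0.05, 45, ages, mode = "birth_death", condition = FALSE)
    expect_true(all(z >= 0))
    if (any(z == 0)) {
      first0 <- which(z == 0)[1]
      expect_true(all(z[first0:length(z)] == 0))
    }
  }
  expect_equal(simulate_clone(0, 50, 70), 1)  # neutral deterministic clone
  expect_length(simulate_clone(0.1, 50, numeric(0)), 0)
  expect_error(simulate_clone(-1, 50, 70), class = "clonedyn_parameter_error")
})

test_that("participant simulation emits binomial reads around the model VAF", {
  set.seed(103)
  scen <- list(list(s = 0.3, variants = data.frame(gene = "JAK2",
                                                   variant = "V617F", atma = 45)))
  sim <- simulate_participant(scen, "LBC", visit_ages = c(70, 76, 82))
  tr <- sim$participant$trajectories[[1]]
  expect_equal(nrow(tr), 3)
  v_model <- predict_isolated(0.3, 45, c(70, 76, 82))
  expect_true(all(diff(v_model) > 0))
  # at large depth the observed VAF concentrates on the model VAF
  sim_deep <- simulate_participant(scen, list(baseline = c(70, 70.1),
                                              offsets = c(0, 6, 12),
                                              depth = 5e5, female_frac = 0.5),
                                   visit_ages = c(70, 76, 82))
  tr2 <- sim_deep$participant$trajectories[[1]]
  expect_equal(tr2$alt_reads / tr2$depth, v_model, tolerance = 0.05)
})

test_that("two equal independent clones have equal expected VAFs and nested clones are ordered", {
  set.seed(104)
  scen_eq <- list(list(s = 0.2, variants = data.frame(gene = "A", variant = "a", atma = 45)),
                  list(s = 0.2, variants = data.frame(gene = "B", variant = "b", atma = 45)))
  deep <- list(baseline = c(70, 70.1), offsets = c(0, 6, 12), depth = 2e5,
               female_frac = 0.5)
  sim <- simulate_participant(scen_eq, deep, visit_ages = c(70, 76, 82))
  # symmetry of the model VAF (observed reads differ only by binomial noise)
  x <- clone_size(0.2, 45, c(70, 76, 82))
  v_expect <- x / (2 * (1e5 + 2 * x))
  for (tr in sim$participant$trajectories)
    expect_equal(stats::setNames(tr$alt_reads / tr$depth, NULL), v_expect,
                 tolerance = 0.1)
  # nested clone: follower acquired later has smaller model VAF everywhere
  scen_nest <- list(list(s = 0.25, variants = data.frame(
    gene = c("A", "B"), variant = c("a", "b"), atma = c(40, 55))))
  sim2 <- simulate_participant(scen_nest, "LBC", visit_ages = c(70, 76, 82),
                               depth_dispersion = 1e6)
  va <- sim2$participant$trajectories[["A:a"]]
  vb <- sim2$participant$trajectories[["B:b"]]
  xl <- clone_size(0.25, 40, c(70, 76, 82))
  xf <- clone_size(0.25, 55, c(70, 76, 82))
  expect_true(all(xf / (2 * (1e5 + xl)) <= xl / (2 * (1e5 + xl))))
  expect_true(mean(vb$alt_reads) < mean(va$alt_reads))
})

test_that("cohort templates honor their sampling designs and are reproducible", {
  set.seed(105)
  lbc <- simulate_cohort("LBC", 10)
  ages <- split(lbc$variants$age, lbc$variants$participant_id)
  for (a in ages) {
    ua <- sort(unique(a))
    expect_length(ua, 3)
    expect_equal(ua - ua[1], c(0, 6, 12), tolerance = 1e-9)
    expect_true(all(abs(ua - c(70, 76, 82)) < 1.5))
  }
  whi <- simulate_cohort("WHI", 8)
  expect_true(all(whi$covariates$sex == "F"))
  expect_true(all(whi$covariates$age_first_obs >= 50 &
                    whi$covariates$age_first_obs <= 79))
  set.seed(9); c1 <- simulate_cohort("SardiNIA", 5)
  set.seed(9); c2 <- simulate_cohort("SardiNIA", 5)
  expect_identical(c1$variants, c2$variants)
  expect_identical(c1$truth, c2$truth)
  expect_error(simulate_cohort("LBC", 0), class = "clonedyn_parameter_error")
})

test_that("marker simulation follows the mixed-model null and binary flag", {
  set.seed(106)
  m <- fake_metrics(400)
  mk <- simulate_markers(m, c(70, 75, 80), fixed_effects = c(),
                         random_intercept_sd = 0.5, residual_sd = 1)
  expect_equal(mean(mk$value), 0, tolerance = 0.1)
  expect_equal(stats::var(mk$value), 1 + 0.25, tolerance = 0.15)
  mkb <- simulate_markers(m, c(70, 75), binary = TRUE)
  expect_true(all(mkb$value %in% c(0, 1)))
  expect_error(simulate_markers(m, numeric(0)),
               class = "clonedyn_parameter_error")
})

test_that("survival simulation respects censoring and parameter errors", {
  set.seed(107)
  m <- fake_metrics(50)
  s1 <- simulate_survival(m, censor_rate = 1)
  expect_true(all(s1$event == 0))
  s2 <- simulate_survival(m, censor_rate = 0)
  expect_true(all(s2$event == 1))
  expect_error(simulate_survival(m, baseline_hazard = -1),
               class = "clonedyn_parameter_error")
  expect_error(simulate_survival(m, log_hazard_coefs = c(bogus = 1)),
               class = "clonedyn_parameter_error")
})
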