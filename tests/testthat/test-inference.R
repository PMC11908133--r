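test_that("structure log-likelihood peaks at the generating parameters on noiseless data", {
  p <- ch_params()
  ages <- c(70, 76, 82)
  v <- predict_isolated(0.2, 45, ages, p)
  tr <- make_traj("JAK2", "V617F", ages, v * 2000)  # exact expected counts
  trajs <- list("JAK2:V617F" = tr)
  ll_true <- structure_loglik(trajs, list("JAK2:V617F"), 0.2,
                              c("JAK2:V617F" = 45), p)
  ll_pert <- structure_loglik(trajs, list("JAK2:V617F"), 0.3,
                              c("JAK2:V617F" = 45), p)
  expect_gt(ll_true, ll_pert)
  expect_gt(ll_true, structure_loglik(trajs, list("JAK2:V617F"), 0.2,
                                      c("JAK2:V617F" = 40), p))
})

test_that("structure log-likelihood equals the binomial pmf at its mode", {
  p <- ch_params()
  # pick (s, atma) so the model VAF is exactly 0.05 at age 70
  x <- 0.1 * p$N / 0.9
  s <- log(x) / 20
  tr <- make_traj("JAK2", "V617F", 70, 10, 200)
  ll <- structure_loglik(list("JAK2:V617F" = tr), list("JAK2:V617F"),
                         s, c("JAK2:V617F" = 50), p)
  expect_equal(ll, stats::dbinom(10, 200, 0.05, log = TRUE), tolerance = 1e-9)
  expect_equal(structure_loglik(list(), list(), numeric(0), numeric(0), p), 0)
  expect_error(structure_loglik(list("A" = tr), list("A"), -0.1, c(A = 50), p),
               class = "clonedyn_parameter_error")
})

test_that("grid evidence matches the independent nested-loop oracle", {
  p <- ch_params()
  grid <- ch_grid(s_max = 0.95, s_step = 0.05)  # 20-point grid
  set.seed(201)
  ages <- c(70, 76, 82)
  trajs <- list(
    A = sim_single_traj(0.25, 45, ages, gene = "JAK2", variant = "a"),
    B = sim_single_traj(0.15, 30, ages, gene = "TET2", variant = "b"),
    C = sim_single_traj(0.30, 55, ages, gene = "SF3B1", variant = "c"))
  names(trajs) <- c("A", "B", "C")
  for (k in 1:3) {
    sub <- trajs[seq_len(k)]
    for (part in enumerate_structures(names(sub))) {
      pkg <- fit_structure(sub, part, p, grid)$log_evidence
      ora <- oracle_evidence(sub, part, grid$s, p)
      expect_equal(pkg, ora, tolerance = 1e-8)
    }
  }
})

test_that("degenerate grids and flat trajectories behave as contracted", {
  p <- ch_params()
  tr <- make_traj("JAK2", "V617F", c(70, 76, 82), c(0, 0, 0))
  # trajectory at/below the detection floor: no growth signal, so the
  # profiled likelihood is flat in fitness and the MAP sits at the grid
  # minimum
  fit <- ch_fit(list("JAK2:V617F" = tr), grid = ch_grid(s_max = 0.5, s_step = 0.01))
  expect_lte(fit$variants$s, 0.02)
  # one-point grid: posterior mass 1 at that point
  f1 <- fit_structure(list("JAK2:V617F" = tr), list("JAK2:V617F"), p,
                      ch_grid(s_max = 0))
  expect_equal(f1$clones[[1]]$posterior$mass, 1)
})

test_that("posteriors contract with deeper and longer sampling", {
  p <- ch_params()
  iqr_width <- function(fit) {
    po <- fit$clones[[1]]$posterior
    cdf <- cumsum(po$mass)
    po$s[which(cdf >= 0.75)[1]] - po$s[which(cdf >= 0.25)[1]]
  }
  set.seed(202)
  w_small <- w_big <- numeric(10)
  for (i in 1:10) {
    seed <- 300 + i
    set.seed(seed)
    tr1 <- sim_single_traj(0.2, 45, c(80, 85, 90), depth = 500)
    set.seed(seed)
    tr2 <- sim_single_traj(0.2, 45, c(80, 82.5, 85, 87.5, 90, 92.5), depth = 2000)
    w_small[i] <- iqr_width(ch_fit(list(A = tr1)))
    w_big[i] <- iqr_width(ch_fit(list(A = tr2)))
  }
  expect_lt(mean(w_big), mean(w_small))
})

test_that("selection is deterministic with ties broken toward more clones", {
  # a single variant trivially selects the singleton partition
  set.seed(203)
  tr <- sim_single_traj(0.2, 45, c(80, 85, 90))
  fit <- ch_fit(list(A = tr))
  expect_length(fit$structure, 1)
  expect_equal(fit$structure[[1]], "A")
  expect_false(fit$tie)
  # normalized structure probabilities form a proper distribution
  pr <- exp(fit$candidates$log_evidence - max(fit$candidates$log_evidence))
  expect_equal(sum(pr / sum(pr)), 1, tolerance = 1e-12)
  # identical duplicated trajectories: both partitions score identically up
  # to noise; rerunning the same input reproduces the same selection
  fit2 <- ch_fit(fit$trajectories)
  expect_identical(fit2$structure, fit$structure)
})

test_that("marginalizing acquisition ages bounds the profiled evidence", {
  set.seed(205)
  p <- ch_params()
  grid <- ch_grid(s_max = 0.5, s_step = 0.01)
  trajs <- list(A = sim_single_traj(0.2, 45, c(80, 85, 90)),
                B = sim_single_traj(0.25, 55, c(80, 85, 90), gene = "TET2"))
  for (part in enumerate_structures(names(trajs))) {
    prof <- fit_structure(trajs, part, p, grid)$log_evidence
    marg <- fit_structure(trajs, part, p, grid,
                          nuisance = "marginalize")$log_evidence
    expect_lte(marg, prof)  # average over the grid cannot beat the maximum
    expect_true(is.finite(marg))
  }
  fitm <- ch_fit(trajs, grid = grid, nuisance = "marginalize")
  expect_s3_class(fitm, "ch_fit")
})

test_that("the greedy search above the exhaustive limit only merges when evidence improves", {
  set.seed(204)
  trajs <- list(A = sim_single_traj(0.28, 55, c(80, 85, 90), gene = "SF3B1"),
                B = sim_single_traj(0.10, 10, c(80, 85, 90), gene = "DNMT3A"),
                C = sim_single_traj(0.20, 45, c(80, 85, 90), gene = "TET2"))
  fit <- ch_fit(trajs, max_exhaustive = 2)
  expect_false(fit$exhaustive)
  # valid partition covering every variant exactly once
  expect_setequal(unlist(fit$structure), names(trajs))
  # the search starts from singletons and merges only on evidence gain
  singleton_ev <- fit$candidates$log_evidence[fit$candidates$key == "1.2.3"]
  expect_gte(fit$log_evidence, singleton_ev)
})
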