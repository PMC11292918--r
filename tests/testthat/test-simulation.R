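test_that("configuration presets carry the study-design constants", {
  cfg <- dgp_config("A")
  expect_equal(cfg$n_pop, 500000L)
  expect_equal(cfg$n_districts, 1000L)
  expect_equal(cfg$n_strata, 400L)
  expect_equal(cfg$controls_per_case, 3L)
  expect_equal(cfg$beta_true, log(2))
  expect_equal(cfg$intercept, -2)
  expect_equal(cfg$tau_range, c(-2, 2))
  red <- dgp_config("B", preset = "reduced")
  expect_equal(red$n_pop, 20000L)
  expect_equal(red$n_districts, 100L)
  expect_equal(red$n_strata, 100L)
})

test_that("population sampling respects district structure, effect ranges
           and dichotomization", {
  cfg <- reduced_cfg("A")
  pop <- simulate_population(cfg, seed = 101)
  expect_equal(length(pop$y), 20000L)
  expect_equal(sort(unique(pop$district)), 1:100)
  expect_true(all(pop$tau >= -2 & pop$tau <= 2))
  expect_true(all(pop$tau_x >= -2 & pop$tau_x <= 2))
  expect_true(all(pop$Z[, 1] %in% c(0, 1)))
  expect_true(all(pop$Z[, 2] %in% c(0, 1)))
  expect_gt(length(unique(pop$Z[, 3])), 100)
  expect_length(pop$signal_vars, 5L)
})

test_that("the exposure model has the stated null rate, district
           heterogeneity and confounding", {
  # no covariate effect, no district effect: rate 0.5
  cfg0 <- reduced_cfg("A", exposure_coef = 0, exposure_intercept = 0,
                      tau_range = c(0, 0))
  pop0 <- simulate_population(cfg0, seed = 102)
  expect_lt(abs(mean(pop0$x) - 0.5), 0.02)

  cfg <- reduced_cfg("A")
  pop <- simulate_population(cfg, seed = 103)
  rates <- tapply(pop$x, pop$district, mean)
  expect_gt(var(rates), 0.005)  # district heterogeneity in exposure
  # confounding: exposure correlates with continuous signal covariates
  cont_signal <- setdiff(pop$signal_vars, 1:2)
  if (length(cont_signal)) {
    r <- cor(pop$x, pop$Z[, cont_signal[1]])
    expect_gt(abs(r) * sqrt(length(pop$x)), 3)  # |r| > 3 SE(r)
  }
})

test_that("the outcome model reduces to its intercept and the tree DGP has
           a bounded step-function range", {
  cfg0 <- reduced_cfg("A", beta_true = 0, signal_coef = 0,
                      tau_range = c(0, 0))
  pop0 <- simulate_population(cfg0, seed = 104)
  expect_lt(abs(mean(pop0$y) - stats::plogis(-2)), 0.01)

  cfgB <- reduced_cfg("B", n_signal = 10, n_noise = 0)
  popB <- simulate_population(cfgB, seed = 105)
  f <- popB$eta - (cfgB$intercept + popB$tau[popB$district] +
                     cfgB$beta_true * popB$x)
  expect_lte(length(unique(round(f, 10))), 9)  # two 3-level trees summed
})

test_that("population-level logistic fit recovers the true exposure
           effect", {
  cfg <- reduced_cfg("A", n_pop = 15000, n_districts = 50)
  pop <- simulate_population(cfg, seed = 106)
  df <- data.frame(y = pop$y, x = pop$x, pop$Z, d = factor(pop$district))
  fit <- stats::glm(y ~ . - d + d, data = df, family = stats::binomial())
  est <- coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  expect_lt(abs(est - log(2)), 3 * se)
})

test_that("matched studies have the designed dimensions, one case with
           district-matched controls per stratum, and no person reuse", {
  cfg <- reduced_cfg("B")
  set.seed(107)
  pop <- simulate_population(cfg)
  train <- clogitforest:::draw_matched_sample(pop, cfg)
  md <- train$data
  expect_equal(md$n, 100L)
  expect_equal(length(md$y), 400L)
  expect_true(all(md$m == 4L))
  # one case per stratum and a shared district
  for (i in seq_len(md$n)) {
    rows <- md$sstart[i] + seq_len(md$slen[i])
    expect_equal(sum(md$y[rows]), 1L)
    expect_length(unique(pop$district[train$persons[rows]]), 1L)
  }
  expect_false(anyDuplicated(train$persons) > 0)

  sim <- simulate_matched_study(cfg, seed = 108)
  expect_length(intersect(sim$truth$persons, sim$truth$persons_validation), 0)
  expect_equal(sim$validation$n, 100L)
})

test_that("the generator is deterministic given a seed", {
  cfg <- reduced_cfg("C", n_strata = 40, n_pop = 6000)
  s1 <- simulate_matched_study(cfg, seed = 109)
  s2 <- simulate_matched_study(cfg, seed = 109)
  expect_identical(s1$study$Z, s2$study$Z)
  expect_identical(s1$study$y, s2$study$y)
  expect_identical(s1$truth$signal_vars, s2$truth$signal_vars)
})

test_that("signal roles are permuted across replications", {
  cfg <- reduced_cfg("A", n_signal = 3, n_noise = 7, n_strata = 20,
                     n_pop = 4000)
  sets <- vapply(1:6, function(s)
    paste(simulate_matched_study(cfg, seed = s,
                                 validation = FALSE)$truth$signal_vars,
          collapse = ","), character(1))
  expect_gt(length(unique(sets)), 1L)
})

test_that("the evaluation report computes both quality measures", {
  md <- tiny_md(n = 20, m = 4, p = 2, seed = 110)
  ev <- evaluate_predictions(rep(0, 80), md, beta_hat = log(2),
                             beta_true = log(2))
  expect_equal(ev$mean_cond_lik, 0.25)
  expect_equal(ev$beta_abs_error, 0)
  # a near-perfect predictor approaches 1
  eta <- ifelse(md$y == 1L, 30, 0)
  expect_gt(evaluate_predictions(eta, md)$mean_cond_lik, 0.999)
})

test_that("the comparison harness runs end to end", {
  cfg <- reduced_cfg("A", n_strata = 40, n_pop = 6000)
  res <- run_comparison(cfg, methods = "clr0", replications = 1, seed = 111)
  expect_equal(nrow(res), 1L)
  expect_true(is.finite(res$pred_cond_lik))
  expect_true(is.finite(res$beta_abs_error))
  expect_s3_class(attr(res, "summary"), "data.frame")

  md <- simulate_matched_study(cfg, seed = 112)$study
  cv <- cv_cond_likelihood(md, methods = "clr", k = 5, seed = 113)
  expect_equal(nrow(cv), md$n)
  expect_true(all(cv$cond_lik > 0 & cv$cond_lik < 1))
})
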