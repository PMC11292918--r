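#' Configuration of the synthetic matched case-control study generator
#'
#' The generator emulates a district-matched epidemiological design: a
#' hypothetical population is distributed uniformly over districts; each
#' district carries two independent uniform effects, one on disease risk and
#' one on exposure propensity; person-level covariates are standard normal
#' (two of them dichotomized at 0); exposure is drawn from a logistic model
#' in the signal covariates and the district exposure effect; disease is
#' drawn from a logistic model `eta = intercept + tau_district + beta*x +
#' f(z)`; finally a 1:m matched study is sampled by drawing cases from the
#' diseased and district-matched controls from the non-diseased.
#'
#' Three families for the covariate effect `f`:
#' * `"A"`: additive linear (alternating +/- `signal_coef` per signal
#'   variable),
#' * `"B"`: sum of two depth-2 decision trees over the signal variables with
#'   leaf values in `{-tree_effect, 0, tree_effect}`,
#' * `"C"`: sum of bounded smooth transforms (sin, centered quadratic, tanh,
#'   applied cyclically and scaled to comparable variance).
#' Noise variables never enter `f`. In each replication the assignment of
#' variables to signal roles is permuted, so the realized DGP differs per
#' round.
#'
#' @param dgp `"A"`, `"B"` or `"C"`.
#' @param n_signal,n_noise numbers of signal and noise covariates (the
#'   studied mixes are 10/0, 5/5 and 10/20).
#' @param preset `"paper"` (population 500000, 1000 districts, 400 strata)
#'   or `"reduced"` (20000 / 100 / 100, the test scale); individual values
#'   can be overridden.
#' @param n_pop,n_districts,n_strata population size, number of districts,
#'   number of matched sets.
#' @param controls_per_case controls matched to each case (1:m matching).
#' @param beta_true true exposure effect (log odds ratio), default log 2.
#' @param intercept outcome-model intercept (-2: a rare-ish disease,
#'   baseline prevalence about 12%).
#' @param tau_range range of the uniform district effects.
#' @param n_dichotomous how many covariate columns (the first ones, in
#'   storage order) are dichotomized at 0.
#' @param exposure_intercept,exposure_coef logistic exposure model:
#'   `P(x=1) = plogis(exposure_intercept + exposure_coef * sum(z_signal) +
#'   tau_x)`. A nonzero `exposure_coef` makes the signal covariates genuine
#'   confounders.
#' @param signal_coef linear effect size per signal variable in DGP A.
#' @param tree_effect leaf magnitude in DGP B.
#' @return a list of class `dgp_config`.
#' @export
dgp_config <- function(dgp = c("A", "B", "C"), n_signal = 10L, n_noise = 0L,
                       preset = c("paper", "reduced"),
                       n_pop = NULL, n_districts = NULL, n_strata = NULL,
                       controls_per_case = 3L, beta_true = log(2),
                       intercept = -2, tau_range = c(-2, 2),
                       n_dichotomous = 2L, exposure_intercept = 0,
                       exposure_coef = 0.2, signal_coef = 0.4,
                       tree_effect = 0.8) {
  dgp <- match.arg(dgp)
  preset <- match.arg(preset)
  def <- switch(preset,
                paper = list(n_pop = 500000L, n_districts = 1000L,
                             n_strata = 400L),
                reduced = list(n_pop = 20000L, n_districts = 100L,
                               n_strata = 100L))
  cfg <- list(dgp = dgp, n_signal = as.integer(n_signal),
              n_noise = as.integer(n_noise),
              p = as.integer(n_signal + n_noise),
              n_pop = as.integer(n_pop %||% def$n_pop),
              n_districts = as.integer(n_districts %||% def$n_districts),
              n_strata = as.integer(n_strata %||% def$n_strata),
              controls_per_case = as.integer(controls_per_case),
              beta_true = beta_true, intercept = intercept,
              tau_range = tau_range, n_dichotomous = as.integer(n_dichotomous),
              exposure_intercept = exposure_intercept,
              exposure_coef = exposure_coef, signal_coef = signal_coef,
              tree_effect = tree_effect, preset = preset)
  stopifnot(cfg$n_signal <= cfg$p, cfg$n_dichotomous <= cfg$p)
  class(cfg) <- "dgp_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariate effect families; zs = matrix of signal-role columns (role order)
dgp_f <- function(zs, config) {
  ns <- ncol(zs)
  switch(config$dgp,
    A = {
      coefs <- rep_len(c(1, -1), ns) * config$signal_coef
      drop(zs %*% coefs)
    },
    B = {
      e <- config$tree_effect
      role <- function(j) zs[, ((j - 1L) %% ns) + 1L]
      # tree 1: root on role 1, branches on roles 2 and 3
      t1 <- ifelse(role(1) <= 0,
                   ifelse(role(2) <= 0, -e, 0),
                   ifelse(role(3) <= 0, 0, e))
      # tree 2: root on role 4, branches on roles 5 and 6
      t2 <- ifelse(role(4) <= 0.5,
                   ifelse(role(5) <= -0.5, -e, 0),
                   ifelse(role(6) <= 0, 0, e))
      t1 + t2
    },
    C = {
      out <- numeric(nrow(zs))
      for (j in seq_len(ns)) {
        out <- out + switch(((j - 1L) %% 3L) + 1L,
                            0.55 * sin(2 * zs[, j]),
                            0.28 * (zs[, j]^2 - 1),
                            0.52 * tanh(2 * zs[, j]))
      }
      out
    })
}

#' Sample the hypothetical source population
#'
#' Persons are distributed uniformly over districts; district effects on
#' disease (`tau`) and exposure (`tau_x`) are drawn uniformly from
#' `tau_range`; covariates are standard normal with the first
#' `n_dichotomous` columns dichotomized at 0; exposure and disease are then
#' drawn from their logistic models. The assignment of covariate columns to
#' signal roles is permuted per call.
#'
#' @param config a [dgp_config()].
#' @param seed integer seed.
#' @return a list of class `dgp_population` with `district`, `Z`, `x`, `y`,
#'   `eta`, `tau`, `tau_x` and `signal_vars` (columns in role order).
#' @export
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dgp_config"))
  with_seed(seed, {
    np <- config$n_pop
    district <- sample.int(config$n_districts, np, replace = TRUE)
    tau <- stats::runif(config$n_districts, config$tau_range[1],
                        config$tau_range[2])
    tau_x <- stats::runif(config$n_districts, config$tau_range[1],
                          config$tau_range[2])
    Z <- matrix(stats::rnorm(np * config$p), np, config$p,
                dimnames = list(NULL, paste0("z", seq_len(config$p))))
    if (config$n_dichotomous > 0L) {
      for (j in seq_len(config$n_dichotomous)) Z[, j] <- as.numeric(Z[, j] > 0)
    }
    signal_vars <- sample.int(config$p, config$n_signal)
    zs <- Z[, signal_vars, drop = FALSE]

    lin_x <- config$exposure_intercept +
      config$exposure_coef * rowSums(zs) + tau_x[district]
    x <- stats::rbinom(np, 1L, stats::plogis(lin_x))

    eta <- config$intercept + tau[district] + config$beta_true * x +
      dgp_f(zs, config)
    y <- stats::rbinom(np, 1L, stats::plogis(eta))

    structure(list(district = district, Z = Z, x = x, y = y, eta = eta,
                   tau = tau, tau_x = tau_x, signal_vars = signal_vars,
                   config = config),
              class = "dgp_population")
  })
}

# draw one matched study from a population; `exclude` marks persons already
# used (so a validation study never reuses a training person)
draw_matched_sample <- function(pop, config, exclude = logical(length(pop$y)),
                                label_prefix = "s") {
  avail_cases <- which(pop$y == 1L & !exclude)
  if (length(avail_cases) < config$n_strata) {
    stop("population has only ", length(avail_cases),
         " available diseased persons; need ", config$n_strata)
  }
  ctrl_pool <- split(which(pop$y == 0L & !exclude),
                     pop$district[pop$y == 0L & !exclude])
  used <- exclude
  cases <- integer(config$n_strata)
  controls <- vector("list", config$n_strata)
  case_order <- sample(avail_cases)
  ci <- 0L
  for (i in seq_len(config$n_strata)) {
    ok <- FALSE
    for (try in 1:200) {
      ci <- ci + 1L
      if (ci > length(case_order)) stop("ran out of candidate cases while matching")
      cand <- case_order[ci]
      if (used[cand]) next
      pool <- ctrl_pool[[as.character(pop$district[cand])]]
      pool <- pool[!used[pool]]
      if (length(pool) < config$controls_per_case) next
      cases[i] <- cand
      ctr <- pool[sample.int(length(pool), config$controls_per_case)]
      controls[[i]] <- ctr
      used[c(cand, ctr)] <- TRUE
      ok <- TRUE
      break
    }
    if (!ok) stop("could not find enough district-matched controls (stratum ", i, ")")
  }
  rows <- unlist(mapply(function(cs, ct) c(cs, ct), cases, controls,
                        SIMPLIFY = FALSE))
  stratum <- rep(sprintf("%s%04d", label_prefix, seq_len(config$n_strata)),
                 each = config$controls_per_case + 1L)
  df <- data.frame(stratum = stratum, case = pop$y[rows],
                   exposure = pop$x[rows], stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pop$Z[rows, , drop = FALSE]))
  list(data = matched_data(df, "stratum", "case", "exposure"),
       persons = rows,
       district = pop$district[cases])
}

#' Simulate a matched case-control study (training + validation)
#'
#' Runs the full generator pipeline: population, exposure, disease, then a
#' 1:m matched study of `n_strata` strata plus an independent validation
#' study of the same size drawn from the same population without reusing any
#' person.
#'
#' @param config a [dgp_config()].
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @param validation also draw the companion validation study?
#' @return a list of class `simulated_study` with `study` and `validation`
#'   (`matched_data`), and `truth` (true beta, signal variable names in role
#'   order, per-stratum district, person indices).
#' @export
simulate_matched_study <- function(config, seed = NULL, validation = TRUE) {
  stopifnot(inherits(config, "dgp_config"))
  with_seed(seed, {
    pop <- simulate_population(config)
    train <- draw_matched_sample(pop, config)
    val <- if (validation) {
      excl <- logical(length(pop$y))
      excl[train$persons] <- TRUE
      draw_matched_sample(pop, config, exclude = excl, label_prefix = "v")
    }
    structure(list(
      study = train$data,
      validation = if (validation) val$data,
      truth = list(beta_true = config$beta_true,
                   signal_vars = colnames(pop$Z)[pop$signal_vars],
                   district = train$district,
                   district_validation = if (validation) val$district,
                   persons = train$persons,
                   persons_validation = if (validation) val$persons,
                   config = config)
    ), class = "simulated_study")
  })
}

#' Evaluate predictions on a validation study
#'
#' The two study quality measures: the conditional likelihood per stratum
#' averaged across strata (computed on independent validation data), and the
#' absolute error of the exposure-effect estimate (no validation data
#' needed, the truth being known by construction).
#'
#' @param eta per-row linear predictors on the validation data.
#' @param validation a `matched_data` object.
#' @param beta_hat,beta_true optional exposure estimate and truth.
#' @return list with `mean_cond_lik`, `per_stratum` and (when both betas are
#'   given) `beta_abs_error`.
#' @export
evaluate_predictions <- function(eta, validation, beta_hat = NULL,
                                 beta_true = NULL) {
  pl <- pred_cond_likelihood(validation, eta)
  list(mean_cond_lik = pl$mean, per_stratum = pl$per_stratum,
       beta_abs_error = if (!is.null(beta_hat) && !is.null(beta_true))
         abs(beta_hat - beta_true))
}

# fit one named method on a study and score it on the validation data
fit_and_score <- function(method, study, validation, beta_true,
                          ntree = 100L, mtry = "auto", tree = tree_control(),
                          sampling = "subsample") {
  fit <- switch(method,
    clr0 = fit_clr(study, exposure = TRUE, covariates = FALSE),
    clr = fit_clr(study, exposure = TRUE, covariates = TRUE),
    tree = prune_bic(clogit_tree(study, exposure = TRUE, control = tree),
                     study),
    forest = clogit_forest(study, exposure = TRUE,
                           control = forest_control(ntree = ntree,
                                                    mtry = mtry,
                                                    sampling = sampling,
                                                    tree = tree)),
    forest_offset = clogit_forest(study, exposure = TRUE,
                                  control = forest_control(ntree = ntree,
                                                           mtry = mtry,
                                                           sampling = sampling,
                                                           offset = "linear",
                                                           tree = tree)),
    stop("unknown method: ", method))
  eta <- predict(fit, validation)
  beta_hat <- if (inherits(fit, "clogit_forest")) fit$beta_bar else fit$beta_hat
  ev <- evaluate_predictions(eta, validation, beta_hat, beta_true)
  list(fit = fit, pred_cond_lik = ev$mean_cond_lik,
       beta_hat = beta_hat, beta_abs_error = ev$beta_abs_error)
}

#' Compare methods over replicated simulated studies
#'
#' For each replication, simulates a training and a validation study from
#' `config`, fits the requested methods on the training data, and records
#' both quality measures. Methods: `"clr0"` (exposure-only CLR), `"clr"`,
#' `"tree"` (BIC-pruned), `"forest"`, `"forest_offset"`.
#'
#' @param config a [dgp_config()].
#' @param methods character vector of method names.
#' @param replications number of simulation rounds.
#' @param seed integer seed (one substream per replication).
#' @param ntree,mtry,tree,sampling forwarded to the forest / tree fits.
#' @return a data frame (replication, method, pred_cond_lik, beta_hat,
#'   beta_abs_error) with a `summary` attribute of per-method means.
#' @export
run_comparison <- function(config, methods = c("clr", "tree", "forest"),
                           replications = 20L, seed = NULL,
                           ntree = 100L, mtry = "auto",
                           tree = tree_control(), sampling = "subsample") {
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, replications))
  rows <- list()
  for (r in seq_len(replications)) {
    sim <- simulate_matched_study(config, seed = rep_seeds[r])
    for (mth in methods) {
      sc <- with_seed(rep_seeds[r] %% 2147483L + r,
                      fit_and_score(mth, sim$study, sim$validation,
                                    config$beta_true, ntree = ntree,
                                    mtry = mtry, tree = tree,
                                    sampling = sampling))
      rows[[length(rows) + 1L]] <- data.frame(
        replication = r, method = mth,
        pred_cond_lik = sc$pred_cond_lik,
        beta_hat = sc$beta_hat %||% NA_real_,
        beta_abs_error = sc$beta_abs_error %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(cbind(pred_cond_lik, beta_abs_error) ~ method,
                           data = out, FUN = mean, na.action = stats::na.pass)
  attr(out, "summary") <- summ
  out
}

#' Stratum-level k-fold cross-validated predictive conditional likelihood
#'
#' Splits the strata into k folds, iteratively refits each method on k-1
#' folds and scores the held-out strata, so every stratum is scored by a
#' model that never saw it.
#'
#' @param data a `matched_data` object with an exposure column.
#' @param methods method names as in [run_comparison()].
#' @param k number of folds.
#' @param seed integer seed for the fold assignment and the fits.
#' @param ntree,mtry,tree,sampling forwarded to the fits.
#' @return a data frame (stratum, method, cond_lik) with per-method means as
#'   attribute `"summary"`.
#' @export
cv_cond_likelihood <- function(data, methods = c("clr", "forest"), k = 10L,
                               seed = NULL, ntree = 100L, mtry = "auto",
                               tree = tree_control(), sampling = "subsample") {
  folds <- stratum_folds(data, k, seed = seed)
  rows <- list()
  for (fold in seq_len(k)) {
    train <- md_subset_strata(data, which(folds != fold))
    test <- md_subset_strata(data, which(folds == fold))
    for (mth in methods) {
      sc <- with_seed((seed %||% 0L) + fold,
                      fit_and_score(mth, train, test, beta_true = NULL,
                                    ntree = ntree, mtry = mtry, tree = tree,
                                    sampling = sampling))
      eta <- predict(sc$fit, test)
      probs <- stratum_case_probs(test, eta)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = unique(test$stratum), method = mth, cond_lik = probs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(cond_lik ~ method, data = out, FUN = mean)
  attr(out, "summary") <- summ
  out
}
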