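test_that("candidate thresholds are midpoints filtered by bucket size", {
  df <- data.frame(stratum = rep(c("a", "b", "c"), each = 2),
                   case = rep(c(1, 0), 3),
                   zb = c(0, 1, 0, 1, 1, 0),
                   zc = c(1, 2, 4, 1, 2, 4),
                   zk = rep(7, 6))
  md <- matched_data(df, "stratum", "case")
  expect_equal(candidate_splits(md, "zb"), 0.5)
  expect_equal(candidate_splits(md, "zc"), c(1.5, 3.0))
  expect_length(candidate_splits(md, "zk"), 0)
  expect_equal(candidate_splits(md, "zc", min_bucket = 2), c(1.5, 3.0))
  expect_length(candidate_splits(md, "zc", min_bucket = 3), 0)
})

test_that("no informative split reduces the tree to exposure-only CLR", {
  md <- stratum_constant_md(n = 40, m = 4, p = 2, seed = 21)
  tr <- clogit_tree(md, control = tree_control(seed = 1))
  expect_equal(tr$t, 1L)
  clr0 <- fit_clr(md, covariates = FALSE)
  expect_lt(abs(tr$beta_hat - clr0$beta_hat), 1e-6)
  # root-only, no exposure: every stratum scores exactly 1/m
  tr0 <- clogit_tree(md, exposure = FALSE, control = tree_control(seed = 1))
  probs <- stratum_case_probs(md, predict(tr0, md))
  expect_equal(probs, rep(0.25, md$n))
})

test_that("terminal nodes partition the rows and the growth trace is
           strictly monotone", {
  sim <- simulate_matched_study(reduced_cfg("B"), seed = 31)
  tr <- clogit_tree(sim$study, control = tree_control(seed = 2))
  expect_gt(tr$t, 1L)
  # partition property: each row lands in exactly one terminal node
  idx <- clogitforest:::route_rows(tr, sim$study$Z)
  expect_true(all(idx >= 1L & idx <= tr$t))
  ind <- outer(idx, seq_len(tr$t), "==")
  expect_equal(rowSums(ind), rep(1, nrow(sim$study$Z)))
  # new data route too
  idx2 <- clogitforest:::route_rows(tr, sim$validation$Z)
  expect_true(all(idx2 %in% seq_len(tr$t)))
  # accepted splits strictly increase the penalized objective
  obj <- vapply(tr$trace, `[[`, numeric(1), "objective")
  expect_true(all(diff(obj) > tr$control$epsilon))
})

test_that("trees are deterministic given a seed and invariant to row order
           in prediction", {
  sim <- simulate_matched_study(reduced_cfg("B", n_strata = 60,
                                            n_pop = 8000), seed = 41)
  ctl <- tree_control(mtry = 3, seed = 99)
  t1 <- clogit_tree(sim$study, control = ctl)
  t2 <- clogit_tree(sim$study, control = ctl)
  expect_identical(coef(t1), coef(t2))
  expect_identical(predict(t1, sim$validation), predict(t2, sim$validation))

  perm <- sample(nrow(sim$validation$Z))
  nd <- sim$validation
  ndp <- nd
  ndp$Z <- nd$Z[perm, , drop = FALSE]
  ndp$x <- nd$x[perm]
  expect_identical(predict(t1, ndp), predict(t1, nd)[perm])
})

test_that("a hand-built two-level tree routes rows by indicator products", {
  # f has nodes S1..S4 with S1 = {z1 <= 2 and z2 <= -1}
  nodes <- list(
    list(id = 1L, leaf = FALSE, var = "z1", threshold = 2, left = 2L, right = 3L),
    list(id = 2L, leaf = FALSE, var = "z2", threshold = -1, left = 4L, right = 5L),
    list(id = 3L, leaf = FALSE, var = "z3", threshold = 0, left = 6L, right = 7L),
    list(id = 4L, leaf = TRUE, didx = 1L, depth = 2L),
    list(id = 5L, leaf = TRUE, didx = 2L, depth = 2L),
    list(id = 6L, leaf = TRUE, didx = 3L, depth = 2L),
    list(id = 7L, leaf = TRUE, didx = 4L, depth = 2L))
  tree <- structure(list(nodes = nodes, delta = c(1.1, 2.2, 3.3, 4.4),
                         beta_hat = NULL, has_exposure = FALSE, t = 4L,
                         var_names = c("z1", "z2", "z3"), pruned = FALSE),
                    class = "clogit_tree")
  Z <- rbind(c(1, -2, 9), c(1, 0, 9), c(5, 0, -1), c(5, 0, 1))
  colnames(Z) <- c("z1", "z2", "z3")
  expect_equal(predict(tree, list(Z = Z)), c(1.1, 2.2, 3.3, 4.4))
  expect_error(predict(tree, list(Z = Z[, 1:2, drop = FALSE])), "unseen")
})

test_that("trees recover planted tree structure on tree-structured data", {
  hits <- 0
  for (r in 1:12) {
    sim <- simulate_matched_study(reduced_cfg("B"), seed = 600 + r)
    tr <- clogit_tree(sim$study, control = tree_control(seed = r))
    first <- tr$trace[[2]]$var
    hits <- hits + (first %in% sim$truth$signal_vars)
  }
  expect_gte(hits, 9)  # signal variables dominate the first split
})

test_that("BIC pruning selects along the growth path and refits", {
  md <- stratum_constant_md(n = 50, m = 4, p = 2, seed = 51)
  tr <- clogit_tree(md, control = tree_control(seed = 3))
  pruned <- prune_bic(tr, md)
  clr0 <- fit_clr(md, covariates = FALSE)
  # root-only exposure model: BIC = -2 loglik + log(n)
  expect_equal(pruned$bic[1], -2 * clr0$loglik + log(md$n), tolerance = 1e-6)

  # a single strong binary split should survive pruning
  set.seed(61)
  n <- 80; m <- 4
  df <- data.frame(stratum = rep(sprintf("s%02d", 1:n), each = m),
                   zs = rbinom(n * m, 1, 0.5), zn = rnorm(n * m))
  eta <- 2.5 * df$zs
  df$case <- 0L
  for (i in 1:n) {
    rows <- (i - 1) * m + 1:m
    p <- exp(eta[rows]) / sum(exp(eta[rows]))
    df$case[rows[sample.int(m, 1, prob = p)]] <- 1L
  }
  mds <- matched_data(df, "stratum", "case")
  trs <- prune_bic(clogit_tree(mds, exposure = FALSE,
                               control = tree_control(seed = 4)), mds)
  expect_gte(trs$t, 2L)
  expect_equal(trs$trace[[2]]$var, "zs")

  # pure noise: pruned back to the root most of the time (binary noise
  # covariates; the BIC penalty log(n) must beat the best of the candidate
  # split statistics, so n is chosen comfortably above that crossover)
  roots <- 0
  for (r in 1:10) {
    set.seed(700 + r)
    nn <- 150; mm <- 4
    dfn <- data.frame(stratum = rep(sprintf("s%03d", 1:nn), each = mm),
                      case = 0L)
    dfn$case[(1:nn - 1) * mm + sample.int(mm, nn, replace = TRUE)] <- 1L
    for (j in 1:3) dfn[[paste0("z", j)]] <- rbinom(nn * mm, 1, 0.5)
    mdn <- matched_data(dfn, "stratum", "case")
    prn <- prune_bic(clogit_tree(mdn, exposure = FALSE,
                                 control = tree_control(seed = r)), mdn)
    roots <- roots + (prn$t == 1L)
  }
  expect_gte(roots, 8)
})

test_that("deep exposure trees on linear data keep a finite, sane exposure
           effect", {
  betas <- vapply(1:8, function(r) {
    sim <- simulate_matched_study(reduced_cfg("A"), seed = 800 + r)
    clogit_tree(sim$study, control = tree_control(seed = r))$beta_hat
  }, numeric(1))
  expect_true(all(is.finite(betas)))
  expect_true(all(abs(betas - log(2)) < 1))
})
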