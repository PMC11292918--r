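test_that("a single identity-sample tree forest degenerates to the tree", {
  sim <- simulate_matched_study(reduced_cfg("B", n_strata = 60,
                                            n_pop = 8000), seed = 71)
  md <- sim$study
  p <- ncol(md$Z)
  fo <- clogit_forest(md, control = forest_control(ntree = 1, mtry = p,
                                                   sampling = "none",
                                                   seed = 5))
  tr <- clogit_tree(md, control = tree_control(mtry = p, seed = 5))
  expect_equal(fo$beta_bar, tr$beta_hat)
  expect_equal(predict(fo, sim$validation), predict(tr, sim$validation))
})

test_that("the forest exposure estimate is the mean of the per-tree
           estimates and predictions are invariant to tree order", {
  sim <- simulate_matched_study(reduced_cfg("B"), seed = 72)
  fo <- clogit_forest(sim$study, control = forest_control(ntree = 12, seed = 6))
  expect_equal(fo$beta_bar, mean(fo$beta_trees))

  perm <- sample(12)
  fo2 <- fo
  fo2$trees <- fo$trees[perm]
  fo2$inbag <- fo$inbag[perm]
  fo2$oob <- fo$oob[perm]
  fo2$beta_trees <- fo$beta_trees[perm]
  expect_equal(predict(fo2, sim$validation), predict(fo, sim$validation))
})

test_that("subsampling leaves each stratum out-of-bag about 36.8% of the
           time", {
  md <- tiny_md(n = 60, m = 4, p = 3, seed = 73)
  fo <- clogit_forest(md, control = forest_control(
    ntree = 60, seed = 7, tree = tree_control(max_depth = 1)))
  oob_counts <- vapply(seq_len(md$n), function(i)
    sum(vapply(fo$oob, function(o) i %in% o, logical(1))), numeric(1))
  # each tree leaves exactly n - round(0.632 n) strata out
  expect_equal(mean(oob_counts) / 60, 1 - round(0.632 * 60) / 60,
               tolerance = 1e-10)
  # binomial spread around the expectation
  expect_true(all(oob_counts > 5 & oob_counts < 45))
})

test_that("a forest of root-only no-exposure trees scores exactly 1/m", {
  md <- stratum_constant_md(n = 30, m = 4, p = 2, seed = 74)
  fo <- clogit_forest(md, exposure = FALSE,
                      control = forest_control(ntree = 10, seed = 8))
  res <- oob_cond_likelihood(fo, md)
  expect_equal(res$mean, 0.25, tolerance = 1e-12)
  expect_true(all(res$per_stratum[!is.na(res$per_stratum)] > 0 &
                    res$per_stratum[!is.na(res$per_stratum)] < 1))
})

test_that("OOB aggregation only uses trees that never saw the stratum", {
  sim <- simulate_matched_study(reduced_cfg("B"), seed = 75)
  md <- sim$study
  fo <- clogit_forest(md, control = forest_control(ntree = 8, seed = 9))
  eta_oob <- predict(fo, md, scope = "oob")
  base <- clogitforest:::forest_offset_eta(fo, md$Z)
  i <- 3L  # recompute stratum 3 by hand
  rows <- md$sstart[i] + seq_len(md$slen[i])
  keep <- which(vapply(fo$oob, function(o) i %in% o, logical(1)))
  if (length(keep)) {
    manual <- base[rows] +
      rowMeans(vapply(fo$trees[keep], function(tr) predict(tr, md)[rows],
                      numeric(length(rows))))
    expect_equal(eta_oob[rows], manual)
  }
  expect_error(predict(fo, sim$validation, scope = "oob"), "training")
})

test_that("mtry tuning picks deterministically from 2..p", {
  md <- tiny_md(n = 30, m = 3, p = 2, seed = 76)
  ctl <- forest_control(ntree_tune = 5, seed = 10)
  expect_equal(as.integer(tune_mtry(md, ctl)), 2L)  # p = 2: single candidate

  sim <- simulate_matched_study(reduced_cfg("B", n_signal = 3, n_noise = 1,
                                            n_strata = 50, n_pop = 8000),
                                seed = 77)
  ctl2 <- forest_control(ntree_tune = 5, seed = 11)
  m1 <- tune_mtry(sim$study, ctl2)
  m2 <- tune_mtry(sim$study, ctl2)
  expect_identical(as.integer(m1), as.integer(m2))
  expect_true(as.integer(m1) %in% 2:4)
  expect_length(attr(m1, "scores"), 3L)
})

test_that("serial and parallel fits are identical under one seed", {
  sim <- simulate_matched_study(reduced_cfg("B", n_strata = 60,
                                            n_pop = 8000), seed = 78)
  ctl1 <- forest_control(ntree = 6, seed = 12, workers = 1)
  ctl2 <- forest_control(ntree = 6, seed = 12, workers = 2)
  f1 <- clogit_forest(sim$study, control = ctl1)
  f2 <- clogit_forest(sim$study, control = ctl2)
  expect_equal(f1$beta_trees, f2$beta_trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(lapply(f1$trees, coef), lapply(f2$trees, coef))
  expect_identical(predict(f1, sim$validation), predict(f2, sim$validation))
})

test_that("ensemble averaging stabilizes the exposure estimate", {
  sim <- simulate_matched_study(reduced_cfg("A", n_strata = 60,
                                            n_pop = 8000), seed = 79)
  b_small <- vapply(1:6, function(s)
    clogit_forest(sim$study,
                  control = forest_control(ntree = 3, seed = s))$beta_bar,
    numeric(1))
  b_large <- vapply(1:6, function(s)
    clogit_forest(sim$study,
                  control = forest_control(ntree = 30, seed = s))$beta_bar,
    numeric(1))
  expect_lt(var(b_large), var(b_small))
})

test_that("JSON serialization round-trips predictions bit-exactly", {
  sim <- simulate_matched_study(reduced_cfg("B"), seed = 80)
  fo <- clogit_forest(sim$study,
                      control = forest_control(ntree = 5, offset = "linear",
                                               seed = 13))
  path <- tempfile(fileext = ".json")
  forest_to_json(fo, path)
  fo2 <- forest_from_json(path)
  expect_identical(predict(fo2, sim$validation), predict(fo, sim$validation))
  expect_identical(predict(fo2, sim$study, scope = "oob"),
                   predict(fo, sim$study, scope = "oob"))
  expect_identical(fo2$beta_bar, fo$beta_bar)
  expect_error(forest_from_json(sub("\"clogitforest/1\"", "\"other/9\"",
                                    paste(readLines(path), collapse = ""))),
               "schema")
  unlink(path)
})
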