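#' Control parameters for conditional logistic regression forests
#'
#' @param ntree number of trees (500 by default; stability in `beta_bar`
#'   mostly requires "large enough" rather than a tuned value).
#' @param mtry number of candidate split variables per growth iteration: an
#'   integer, `"auto"` (`max(2, floor(sqrt(p)))`, the usual forest default)
#'   or `"tune"` (internal search over 2..p maximizing the out-of-bag
#'   predictive conditional likelihood, see [tune_mtry()]).
#' @param sampling stratum-level resampling mode: `"subsample"` (63.2% of
#'   strata without replacement, the default -- it sidesteps the question of
#'   how to weight bootstrap-duplicated strata), `"bootstrap"` (n strata with
#'   replacement; a stratum's likelihood contribution counts once per draw)
#'   or `"none"` (identity sample, for degenerate single-tree forests).
#' @param offset `"none"` or `"linear"`: with `"linear"`, the linear CLR fit
#'   of all covariates (exposure term excluded from the offset) is computed
#'   on the full training data and passed to every tree as a fixed per-row
#'   offset, so trees only model what the linear fit leaves unexplained.
#' @param tree a [tree_control()] for the base learners (never pruned inside
#'   the forest).
#' @param ntree_tune number of trees per candidate during mtry tuning.
#' @param seed master seed; one independent substream is derived per tree
#'   index, so results are identical for any worker count.
#' @param workers number of parallel workers (forked; serial and parallel
#'   fits are identical under the same seed).
#' @return a list of class `forest_control`.
#' @export
forest_control <- function(ntree = 500L, mtry = "auto",
                           sampling = c("subsample", "bootstrap", "none"),
                           offset = c("none", "linear"),
                           tree = tree_control(), ntree_tune = 50L,
                           seed = NULL, workers = 1L) {
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 sampling = match.arg(sampling), offset = match.arg(offset),
                 tree = tree, ntree_tune = as.integer(ntree_tune),
                 seed = seed, workers = as.integer(workers)),
            class = "forest_control")
}

resolve_mtry <- function(mtry, p) {
  if (identical(mtry, "auto")) return(max(2L, as.integer(floor(sqrt(p)))))
  as.integer(mtry)
}

#' Fit a conditional logistic regression forest
#'
#' Bagged ensemble of conditional logistic regression trees. Each tree is
#' grown, unpruned, on its own stratum-level resample with mtry variable
#' subsampling; the forest prediction is the average of the per-tree linear
#' predictors, and when a dedicated exposure effect is modeled, the forest
#' estimate `beta_bar` is the arithmetic mean of the per-tree estimates.
#' With `offset = "linear"` every tree is grown on top of the linear CLR fit
#' of all covariates (exposure excluded from the offset), so splits only
#' capture non-linearities and interactions.
#'
#' @param data a `matched_data` object.
#' @param exposure model a dedicated linear exposure effect in every tree?
#' @param control a [forest_control()] object.
#' @return an object of class `clogit_forest` with elements `trees`, `inbag`
#'   / `oob` (per-tree stratum index sets), `beta_bar`, `offset_gamma` and
#'   the resolved `mtry`.
#' @export
clogit_forest <- function(data, exposure = !is.null(data$x),
                          control = forest_control()) {
  stopifnot(inherits(data, "matched_data"), inherits(control, "forest_control"))
  p <- ncol(data$Z)
  mtry <- if (identical(control$mtry, "tune")) {
    tune_mtry(data, control, exposure = exposure)
  } else resolve_mtry(control$mtry, p)

  offset_gamma <- NULL
  offset_vec <- NULL
  if (control$offset == "linear") {
    base_fit <- fit_clr(data, exposure = exposure, covariates = TRUE,
                        lambda = control$tree$lambda)
    offset_gamma <- base_fit$gamma_hat
    offset_vec <- drop(data$Z %*% offset_gamma)
  }

  tree_seeds <- with_seed(control$seed,
                          sample.int(.Machine$integer.max - 1L, control$ntree))
  tctl <- control$tree
  tctl$mtry <- mtry
  tctl$seed <- NULL  # trees consume the per-tree substream set below

  fit_one <- function(i) {
    set.seed(tree_seeds[i])
    bag <- draw_inbag(data, control$sampling)
    sub <- md_subset_strata(data, bag$inbag)
    tr <- grow_engine(sub, exposure, tctl,
                      if (is.null(offset_vec)) NULL else offset_vec[sub$parent_rows])
    tr$offset <- NULL  # training offset is reconstructed from offset_gamma
    list(tree = tr, inbag = bag$inbag, oob = bag$oob)
  }
  fits <- if (control$workers > 1L) {
    parallel::mclapply(seq_len(control$ntree), fit_one,
                       mc.cores = control$workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(control$ntree), fit_one)
  }
  for (f in fits) if (inherits(f, "try-error") || is.null(f$tree)) {
    stop("tree fit failed: ", paste(f, collapse = " "))
  }

  trees <- lapply(fits, `[[`, "tree")
  betas <- if (exposure) vapply(trees, `[[`, numeric(1), "beta_hat") else NULL
  structure(list(
    trees = trees,
    inbag = lapply(fits, `[[`, "inbag"),
    oob = lapply(fits, `[[`, "oob"),
    beta_bar = if (exposure) mean(betas) else NULL,
    beta_trees = betas,
    has_exposure = exposure,
    offset_mode = control$offset, offset_gamma = offset_gamma,
    mtry = mtry, control = control,
    var_names = colnames(data$Z), n = data$n,
    stratum_labels = unique(data$stratum)
  ), class = "clogit_forest")
}

# per-row offset implied by the stored linear-offset coefficients
forest_offset_eta <- function(model, Z) {
  if (is.null(model$offset_gamma)) return(numeric(nrow(Z)))
  drop(Z[, names(model$offset_gamma), drop = FALSE] %*% model$offset_gamma)
}

#' Predict from a conditional logistic regression forest
#'
#' Averages the per-tree linear predictors (log-odds scale), consistent with
#' averaging the per-tree exposure estimates. `scope = "oob"` is valid only
#' for the training data and averages, per stratum, only the trees whose
#' in-bag sample excludes that stratum; strata in every in-bag set get `NA`.
#'
#' @param object a `clogit_forest`.
#' @param newdata a `matched_data` object.
#' @param scope `"all"` or `"oob"`.
#' @param ... unused.
#' @return per-row linear predictors.
#' @export
predict.clogit_forest <- function(object, newdata,
                                  scope = c("all", "oob"), ...) {
  scope <- match.arg(scope)
  Z <- newdata$Z
  base <- forest_offset_eta(object, Z)
  per_tree <- vapply(object$trees, function(tr) predict(tr, newdata),
                     numeric(nrow(Z)))
  if (scope == "all") return(base + rowMeans(per_tree))
  if (newdata$n != object$n ||
      !identical(unique(newdata$stratum), object$stratum_labels)) {
    stop("scope = 'oob' is only valid for the training data")
  }
  eta <- rep(NA_real_, nrow(Z))
  for (i in seq_len(newdata$n)) {
    rows <- newdata$sstart[i] + seq_len(newdata$slen[i])
    keep <- vapply(object$oob, function(o) i %in% o, logical(1))
    if (!any(keep)) next  # never out-of-bag: non-evaluable stratum
    eta[rows] <- base[rows] + rowMeans(per_tree[rows, keep, drop = FALSE])
  }
  eta
}

#' Out-of-bag predictive conditional likelihood
#'
#' For each stratum, the conditional probability of the observed case under
#' the OOB-aggregated linear predictor; the mean over evaluable strata is
#' the forest's honest optimality criterion (used for mtry tuning).
#'
#' @param model a `clogit_forest` fitted on `data`.
#' @param data the training `matched_data`.
#' @return list with `per_stratum` (NA for non-evaluable strata) and `mean`.
#' @export
oob_cond_likelihood <- function(model, data) {
  eta <- predict(model, data, scope = "oob")
  probs <- rep(NA_real_, data$n)
  for (i in seq_len(data$n)) {
    rows <- data$sstart[i] + seq_len(data$slen[i])
    if (anyNA(eta[rows])) next
    probs[i] <- stratum_cond_prob(eta[rows], which(data$y[rows] == 1L))
  }
  list(per_stratum = probs, mean = mean(probs, na.rm = TRUE))
}

#' Tune mtry by the out-of-bag predictive conditional likelihood
#'
#' Fits, for every candidate mtry in 2..p, a forest of `ntree_tune` trees
#' under the same seed (so candidates share their resamples) and returns the
#' candidate maximizing the mean OOB predictive conditional likelihood;
#' ties go to the smallest candidate.
#'
#' @param data a `matched_data` object.
#' @param control a [forest_control()]; its `ntree_tune` and `seed` are used.
#' @param exposure as in [clogit_forest()].
#' @return the selected mtry (integer), with the candidate scores attached
#'   as attribute `"scores"`.
#' @export
tune_mtry <- function(data, control = forest_control(),
                      exposure = !is.null(data$x)) {
  p <- ncol(data$Z)
  if (p < 2L) stop("mtry tuning needs at least 2 covariates")
  cands <- 2:p
  if (length(cands) == 1L) return(structure(cands, scores = NA_real_))
  scores <- vapply(cands, function(mt) {
    ctl <- control
    ctl$mtry <- mt
    ctl$ntree <- control$ntree_tune
    fit <- clogit_forest(data, exposure = exposure, control = ctl)
    oob_cond_likelihood(fit, data)$mean
  }, numeric(1))
  best <- cands[which.max(scores)]  # which.max takes the first: smallest tie
  structure(best, scores = stats::setNames(scores, cands))
}

#' @export
coef.clogit_forest <- function(object, ...) {
  if (!object$has_exposure) {
    stop("exploratory forest: no dedicated exposure effect")
  }
  c(exposure = object$beta_bar)
}

#' @export
print.clogit_forest <- function(x, ...) {
  cat("Conditional logistic regression forest: ",
      length(x$trees), " trees, mtry = ", x$mtry,
      ", sampling = ", x$control$sampling, "\n", sep = "")
  if (x$offset_mode == "linear") cat("Linear covariate offset included\n")
  if (x$has_exposure) {
    cat(sprintf("Exposure effect: beta_bar = %.4f (OR = %.3f)\n",
                x$beta_bar, exp(x$beta_bar)))
  } else cat("Exploratory forest (no dedicated exposure effect)\n")
  sizes <- vapply(x$trees, `[[`, integer(1), "t")
  cat(sprintf("Terminal nodes per tree: %.1f (range %d-%d)\n",
              mean(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
summary.clogit_forest <- function(object, data = NULL, ...) {
  out <- list(ntree = length(object$trees), mtry = object$mtry,
              beta_bar = object$beta_bar,
              beta_sd = if (object$has_exposure) stats::sd(object$beta_trees),
              sizes = vapply(object$trees, `[[`, integer(1), "t"),
              oob = if (!is.null(data)) oob_cond_likelihood(object, data)$mean)
  class(out) <- "summary.clogit_forest"
  out
}

#' @export
print.summary.clogit_forest <- function(x, ...) {
  cat("Forest of", x$ntree, "trees (mtry =", x$mtry, ")\n")
  if (!is.null(x$beta_bar))
    cat(sprintf("beta_bar = %.4f (per-tree SD %.4f)\n", x$beta_bar, x$beta_sd))
  cat(sprintf("Terminal nodes per tree: mean %.1f\n", mean(x$sizes)))
  if (!is.null(x$oob))
    cat(sprintf("OOB predictive conditional likelihood: %.4f\n", x$oob))
  invisible(x)
}
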