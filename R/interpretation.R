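#' Permutation variable importance for a conditional logistic forest
#'
#' The importance of a covariate is the drop in mean predictive conditional
#' likelihood (probability units) after its column is permuted across all
#' rows, predictions re-evaluated, and nothing refitted. Two variants:
#' `"oob"` (the default, more robust to overfitting) scores each tree on its
#' own out-of-bag strata and averages the per-tree drops; `"all"` scores the
#' whole forest on all strata. When the forest models the exposure as a
#' separate linear term, the exposure is not part of the forest and gets no
#' importance value. A covariate used in no split of any tree (and absent
#' from any linear offset) scores exactly 0.
#'
#' @param model a `clogit_forest` fitted on `data`.
#' @param data the training `matched_data`.
#' @param variant `"oob"` or `"all"`.
#' @param nperm permutations averaged per variable (default 1 for `"oob"`,
#'   where per-tree averaging already smooths, and 5 for `"all"`).
#' @param seed integer seed for the permutations.
#' @param within_stratum permute within strata instead of globally?
#' @return a data frame of class `clogit_varimp` (variable, importance),
#'   sorted by decreasing importance.
#' @export
variable_importance <- function(model, data, variant = c("oob", "all"),
                                nperm = NULL, seed = NULL,
                                within_stratum = FALSE) {
  stopifnot(inherits(model, "clogit_forest"), inherits(data, "matched_data"))
  variant <- match.arg(variant)
  if (is.null(nperm)) nperm <- if (variant == "oob") 1L else 5L
  vars <- model$var_names
  nobs <- length(data$y)

  permute_col <- function() {
    if (!within_stratum) return(sample.int(nobs))
    idx <- seq_len(nobs)
    for (i in seq_len(data$n)) {
      r <- data$sstart[i] + seq_len(data$slen[i])
      idx[r] <- r[sample.int(length(r))]
    }
    idx
  }

  score_all <- function(Z) {
    nd <- data
    nd$Z <- Z
    mean(stratum_case_probs(data, predict(model, nd, scope = "all")))
  }
  score_oob <- function(Z) {
    nd <- data
    nd$Z <- Z
    base <- forest_offset_eta(model, Z)
    vapply(seq_along(model$trees), function(k) {
      oob <- model$oob[[k]]
      if (!length(oob)) return(NA_real_)
      eta <- base + predict(model$trees[[k]], nd)
      mean(vapply(oob, function(i) {
        r <- data$sstart[i] + seq_len(data$slen[i])
        stratum_cond_prob(eta[r], which(data$y[r] == 1L))
      }, numeric(1)))
    }, numeric(1))
  }

  imp <- with_seed(seed, {
    if (variant == "all") {
      baseline <- score_all(data$Z)
      vapply(vars, function(v) {
        drops <- vapply(seq_len(nperm), function(b) {
          Zp <- data$Z
          Zp[, v] <- Zp[permute_col(), v]
          baseline - score_all(Zp)
        }, numeric(1))
        mean(drops)
      }, numeric(1))
    } else {
      baseline_trees <- score_oob(data$Z)
      vapply(vars, function(v) {
        drops <- vapply(seq_len(nperm), function(b) {
          Zp <- data$Z
          Zp[, v] <- Zp[permute_col(), v]
          mean(baseline_trees - score_oob(Zp), na.rm = TRUE)
        }, numeric(1))
        mean(drops)
      }, numeric(1))
    }
  })

  out <- data.frame(variable = vars, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "variant") <- variant
  attr(out, "nperm") <- nperm
  class(out) <- c("clogit_varimp", "data.frame")
  out
}

#' @export
print.clogit_varimp <- function(x, ...) {
  cat("Permutation variable importance (", attr(x, "variant"),
      " variant, ", attr(x, "nperm"), " permutation(s))\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.clogit_varimp <- function(x, ...) {
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(x$importance), names.arg = rev(x$variable),
                    horiz = TRUE, las = 1,
                    xlab = "drop in predictive conditional likelihood", ...)
  invisible(x)
}

# empirical inverse-CDF (order-statistic) quantile, no interpolation --
# bootstrap intervals at small B are sensitive to the convention, so it is
# fixed here: Q(p) = x_(ceil(B p)) for p in (0, 1]
boot_percentile <- function(draws, probs) {
  s <- sort(draws)
  vapply(probs, function(p) s[max(1L, ceiling(length(s) * p))], numeric(1))
}

#' Nonparametric bootstrap confidence interval for the exposure effect
#'
#' Repeats the whole forest estimation on B stratum-level bootstrap
#' resamples of the training data (including mtry re-tuning when the control
#' says `mtry = "tune"`) and returns the empirical (1-level)/2 and
#' 1-(1-level)/2 quantiles of the B averaged exposure estimates.
#'
#' @param data a `matched_data` object with an exposure column.
#' @param control a [forest_control()] for each refit.
#' @param B number of bootstrap replications (50 was used in the screening
#'   application protocol this follows).
#' @param level confidence level.
#' @param seed integer seed.
#' @param point optional point estimate (`beta_bar` of a full-data fit); when
#'   `NULL` a full-data forest is fitted to provide it.
#' @return an object of class `clogit_boot_ci` with the draws, the interval
#'   on the log-odds scale and the point estimate.
#' @export
boot_ci <- function(data, control = forest_control(), B = 50L, level = 0.95,
                    seed = NULL, point = NULL) {
  stopifnot(inherits(data, "matched_data"), !is.null(data$x), B >= 2L)
  res <- with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, B + 1L)
    if (is.null(point)) {
      ctl <- control
      ctl$seed <- rep_seeds[B + 1L]
      point <- clogit_forest(data, exposure = TRUE, control = ctl)$beta_bar
    }
    draws <- vapply(seq_len(B), function(b) {
      idx <- with_seed(rep_seeds[b], sample.int(data$n, data$n, replace = TRUE))
      boot_data <- md_subset_strata(data, idx)
      ctl <- control
      ctl$seed <- rep_seeds[b]
      fit <- tryCatch(clogit_forest(boot_data, exposure = TRUE, control = ctl),
                      error = function(e) stop("bootstrap replicate ", b,
                                               " failed: ", conditionMessage(e)))
      fit$beta_bar
    }, numeric(1))
    list(point = point, draws = draws)
  })
  alpha <- (1 - level) / 2
  ci <- boot_percentile(res$draws, c(alpha, 1 - alpha))
  structure(list(beta = res$point, draws = res$draws, level = level,
                 lower = ci[1], upper = ci[2], B = B),
            class = "clogit_boot_ci")
}

#' @export
print.clogit_boot_ci <- function(x, ...) {
  cat(sprintf("Exposure effect: beta = %.4f  (adjusted OR = %.3f)\n",
              x$beta, exp(x$beta)))
  cat(sprintf("%.0f%% bootstrap CI (B = %d):\n", 100 * x$level, x$B))
  cat(sprintf("  log-odds scale: %.4f - %.4f\n", x$lower, x$upper))
  cat(sprintf("  odds-ratio scale: %.3f - %.3f\n",
              exp(x$lower), exp(x$upper)))
  invisible(x)
}
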