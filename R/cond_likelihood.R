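#' Conditional probability that the case is the observed one
#'
#' For a single stratum with linear predictors `eta` and one case, returns
#' `exp(eta[case]) / sum(exp(eta))`, the probability (conditional on exactly
#' one case in the stratum) that the case is the subject actually observed to
#' be diseased. Computed with max-subtraction, so adding any constant to all
#' of `eta` leaves the value bitwise unchanged -- the algebraic shadow of the
#' stratum intercepts eliminated by conditioning.
#'
#' @param eta numeric vector of within-stratum linear predictors (log-odds
#'   scale), length at least 2.
#' @param case_index position of the case in `eta`.
#' @return a probability in (0, 1).
#' @export
stratum_cond_prob <- function(eta, case_index) {
  if (length(eta) < 2L) stop("a stratum needs at least 2 members")
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  e <- exp(eta - max(eta))
  e[case_index] / sum(e)
}

# per-stratum probability of the observed case for a full dataset
stratum_case_probs <- function(data, eta) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  vapply(seq_len(data$n), function(i) {
    r <- data$sstart[i] + seq_len(data$slen[i])
    stratum_cond_prob(eta[r], which(data$y[r] == 1L))
  }, numeric(1))
}

#' Conditional log-likelihood of a vector of linear predictors
#'
#' Sum over strata of the log conditional case probability. Equals
#' `n * log(1/m)` when all predictors are equal and all strata have size m,
#' and is invariant to per-stratum constant shifts of `eta`.
#'
#' @param data a `matched_data` object.
#' @param eta numeric vector of per-row linear predictors, aligned with the
#'   rows of `data`.
#' @return a scalar log-likelihood (<= 0).
#' @export
cond_loglik <- function(data, eta) {
  stopifnot(inherits(data, "matched_data"), length(eta) == length(data$y))
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  cpp_cond_loglik(as.numeric(eta), data$sstart, data$slen, data$y)
}

#' Mean predictive conditional likelihood
#'
#' The per-stratum conditional case probabilities and their mean: the
#' probability, averaged over strata, that a model identifies the diseased
#' member of each matched set. The null model scores 1/m (0.25 under 1:3
#' matching).
#'
#' @param data a `matched_data` object.
#' @param eta per-row linear predictors.
#' @return list with `per_stratum` and `mean`.
#' @export
pred_cond_likelihood <- function(data, eta) {
  p <- stratum_case_probs(data, eta)
  list(per_stratum = p, mean = mean(p))
}

#' Fit conditional logistic regression by penalized Newton iteration
#'
#' Maximizes the conditional log-likelihood minus a ridge penalty
#' `lambda/2 * ||theta||^2` over the coefficients of a linear design, using
#' full Newton steps with analytic gradient and Fisher information and
#' step-halving. The default design is `[exposure | covariates]`. The tiny
#' default ridge (`1e-20`) only matters under perfect separation, where it
#' keeps the optimum finite; a divergence guard additionally caps
#' coefficients at 50 on the log-odds scale and flags the fit.
#'
#' @param data a `matched_data` object.
#' @param exposure include the dedicated exposure term? Defaults to `TRUE`
#'   when the data carry an exposure column.
#' @param covariates include the covariate columns linearly? (`TRUE`,
#'   `FALSE`, or a character vector of column names.)
#' @param design optional explicit numeric design matrix overriding
#'   `exposure`/`covariates` (used internally by the trees).
#' @param lambda ridge weight, applied per coefficient via `penalty_mask`.
#' @param penalty_mask logical vector marking which coefficients are
#'   penalized; default all (including the exposure effect).
#' @param offset optional per-row fixed offset on the log-odds scale.
#' @param init optional start values (default zero).
#' @param maxit,tol_obj,tol_grad Newton controls: iteration cap, relative
#'   objective-change tolerance, gradient max-norm tolerance.
#' @return an object of class `clr_fit` with `coefficients`, `beta_hat` (if
#'   an exposure term is present), `gamma_hat`, `loglik`, `converged`,
#'   `flagged` and `iter`.
#' @export
fit_clr <- function(data, exposure = !is.null(data$x), covariates = TRUE,
                    design = NULL, lambda = 1e-20, penalty_mask = NULL,
                    offset = NULL, init = NULL,
                    maxit = 100L, tol_obj = 1e-10, tol_grad = 1e-8) {
  stopifnot(inherits(data, "matched_data"))
  if (is.null(design)) {
    cov_cols <- if (isTRUE(covariates)) colnames(data$Z)
                else if (isFALSE(covariates)) character(0)
                else covariates
    X <- cbind(
      if (exposure) matrix(as.numeric(data$x), ncol = 1,
                           dimnames = list(NULL, "exposure")),
      data$Z[, cov_cols, drop = FALSE]
    )
    if (is.null(X) || ncol(X) == 0L) stop("empty design: nothing to fit")
    has_beta <- exposure
  } else {
    X <- as.matrix(design)
    has_beta <- FALSE
  }
  if (anyNA(X) || any(!is.finite(X))) stop("design contains non-finite values")
  d <- ncol(X)
  if (is.null(penalty_mask)) penalty_mask <- rep(TRUE, d)
  lam <- ifelse(penalty_mask, lambda, 0)
  if (is.null(offset)) offset <- numeric(length(data$y))
  if (is.null(init)) init <- numeric(d)

  fit <- cpp_clr_fit(X, as.numeric(offset), data$sstart, data$slen, data$y,
                     as.numeric(lam), as.numeric(init),
                     as.integer(maxit), tol_obj, tol_grad)
  if (!fit$converged && lambda == 0) {
    stop("Newton iteration failed to converge with lambda = 0; ",
         "the Hessian is likely singular -- use a positive ridge lambda")
  }
  coefs <- drop(fit$coef)
  names(coefs) <- colnames(X)
  structure(list(
    coefficients = coefs,
    beta_hat = if (has_beta) unname(coefs["exposure"]) else NULL,
    gamma_hat = if (has_beta) coefs[setdiff(names(coefs), "exposure")] else coefs,
    loglik = fit$loglik, objective = fit$objective,
    converged = fit$converged, flagged = fit$flagged, iter = fit$iter,
    grad_max = fit$grad_max, lambda = lambda, penalty_mask = penalty_mask,
    var_names = colnames(X), has_exposure = has_beta,
    n = data$n, nobs = length(data$y)
  ), class = "clr_fit")
}

#' @export
coef.clr_fit <- function(object, ...) object$coefficients

#' @export
logLik.clr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("Conditional logistic regression (", x$n, " strata)\n", sep = "")
  if (x$has_exposure) {
    cat(sprintf("Exposure effect: beta = %.4f (OR = %.3f)\n",
                x$beta_hat, exp(x$beta_hat)))
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Conditional log-likelihood: %.4f (%s in %d iterations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$iter))
  if (x$flagged) cat("Note: divergence guard triggered (separation?)\n")
  invisible(x)
}

#' Predict linear predictors from a CLR fit
#'
#' @param object a `clr_fit`.
#' @param newdata a `matched_data` object with the same covariate columns.
#' @param ... unused.
#' @return per-row linear predictor (log-odds scale, stratum intercepts
#'   excluded -- only differences within a stratum are meaningful).
#' @export
predict.clr_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "matched_data"))
  eta <- numeric(length(newdata$y))
  for (v in object$var_names) {
    col <- if (v == "exposure") {
      if (is.null(newdata$x)) stop("model has an exposure term but newdata has no exposure")
      as.numeric(newdata$x)
    } else {
      if (!v %in% colnames(newdata$Z)) stop("unseen variable: ", v)
      newdata$Z[, v]
    }
    eta <- eta + object$coefficients[[v]] * col
  }
  eta
}
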