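#' Control parameters for conditional logistic regression trees
#'
#' @param mtry number of covariates sampled as candidate split variables per
#'   growth iteration; `NULL` means all `p` (no subsampling).
#' @param max_depth maximum node depth. The default 4 (at most 16 terminal
#'   nodes) deliberately bounds the base learners: in a conditional logit,
#'   unbounded trees drive the fit towards within-stratum separation, which
#'   inflates the node effects and the exposure estimate far beyond the
#'   usual benign overfitting of regression forests.
#' @param min_split_n minimum number of observations in a node for it to be
#'   eligible for splitting.
#' @param min_bucket_n minimum number of observations in any child node
#'   (under 1:3 matching a node below ~15 rows carries almost no
#'   conditional-likelihood information of its own).
#' @param epsilon minimum penalized log-likelihood improvement for a split to
#'   be accepted (a numerical guard, not a pruning device).
#' @param lambda ridge weight on the node effects (and, when
#'   `penalize_exposure`, on the exposure effect). The tiny default only
#'   stabilizes separated fits and pins down the shift-invariant node
#'   effects at their minimum-norm representative.
#' @param penalize_exposure apply the ridge to the exposure effect too?
#' @param mtry_per_node draw a fresh mtry subset for every node instead of
#'   once per growth iteration?
#' @param seed integer seed for the mtry draws (`NULL`: use the current RNG
#'   stream, as the forest does).
#' @param search_maxit,search_tol Newton budget per candidate split during
#'   the search; accepted splits are always refit to full convergence.
#' @param maxit,tol_obj,tol_grad convergence controls for full refits.
#' @return a list of class `tree_control`.
#' @export
tree_control <- function(mtry = NULL, max_depth = 4L, min_split_n = 60L,
                         min_bucket_n = 20L, epsilon = 1e-8, lambda = 1e-20,
                         penalize_exposure = TRUE, mtry_per_node = FALSE,
                         seed = NULL, search_maxit = 4L, search_tol = 1e-7,
                         maxit = 100L, tol_obj = 1e-10, tol_grad = 1e-8) {
  structure(list(mtry = mtry, max_depth = max_depth,
                 min_split_n = as.integer(min_split_n),
                 min_bucket_n = as.integer(min_bucket_n),
                 epsilon = epsilon, lambda = lambda,
                 penalize_exposure = penalize_exposure,
                 mtry_per_node = mtry_per_node, seed = seed,
                 search_maxit = as.integer(search_maxit),
                 search_tol = search_tol, maxit = as.integer(maxit),
                 tol_obj = tol_obj, tol_grad = tol_grad),
            class = "tree_control")
}

#' Candidate split thresholds for one variable
#'
#' Midpoints between consecutive distinct observed values among the given
#' rows; candidates whose children would violate `min_bucket` are excluded.
#' A binary variable therefore yields at most one candidate, at 0.5.
#'
#' @param data a `matched_data` object.
#' @param variable covariate name.
#' @param rows row indices defining the node (default: all rows).
#' @param min_bucket minimum child size.
#' @return numeric vector of thresholds (possibly empty).
#' @export
candidate_splits <- function(data, variable, rows = seq_along(data$y),
                             min_bucket = 1L) {
  v <- data$Z[rows, variable]
  sv <- sort(v)
  u <- unique(sv)
  if (length(u) < 2L) return(numeric(0))
  thr <- (u[-length(u)] + u[-1]) / 2
  keep <- vapply(thr, function(th) {
    nl <- sum(v <= th)
    nl >= min_bucket && (length(v) - nl) >= min_bucket
  }, logical(1))
  thr[keep]
}

# grow (or replay) the split sequence; replay_steps non-NULL reproduces a
# recorded prefix instead of searching
grow_engine <- function(data, exposure, control, offset, replay_steps = NULL) {
  nobs <- length(data$y)
  p <- ncol(data$Z)
  x <- if (exposure) as.numeric(data$x) else numeric(0)
  if (exposure && is.null(data$x)) stop("exposure = TRUE but data has no exposure column")
  off <- if (is.null(offset)) numeric(nobs) else as.numeric(offset)
  stopifnot(length(off) == nobs)
  lam_b <- if (control$penalize_exposure) control$lambda else 0
  mtry <- if (is.null(control$mtry)) p else min(control$mtry, p)
  stopifnot(mtry >= 1L)

  nodes <- list(list(id = 1L, leaf = TRUE, didx = 1L, depth = 0L))
  node_of_row <- rep(1L, nobs)
  t <- 1L
  fit <- cpp_tree_refit(node_of_row - 1L, t, x, exposure, off,
                        data$sstart, data$slen, data$y,
                        control$lambda, lam_b, numeric(1), 0,
                        control$maxit, control$tol_obj, control$tol_grad)
  delta <- drop(fit$delta)
  beta <- fit$beta
  trace <- list(list(step = 0L, t = 1L, loglik = fit$loglik,
                     objective = fit$objective))
  flagged <- isTRUE(fit$flagged)
  step <- 0L

  repeat {
    if (!is.null(replay_steps) && step >= length(replay_steps)) break
    counts <- tabulate(node_of_row, t)
    depth_of <- vapply(nodes, function(nd)
      if (isTRUE(nd$leaf)) nd$depth else NA_integer_, integer(1))
    leaf_ids <- vapply(nodes, function(nd)
      if (isTRUE(nd$leaf)) nd$didx else NA_integer_, integer(1))
    depth_of_didx <- integer(t)
    id_of_didx <- integer(t)
    for (j in seq_along(nodes)) {
      if (!is.na(leaf_ids[j])) {
        depth_of_didx[leaf_ids[j]] <- depth_of[j]
        id_of_didx[leaf_ids[j]] <- nodes[[j]]$id
      }
    }

    if (is.null(replay_steps)) {
      eligible <- which(counts >= control$min_split_n &
                          depth_of_didx < control$max_depth)
      if (!length(eligible)) break
      search_one <- function(cand_didx, vars) {
        cpp_search_split(data$Z, node_of_row - 1L, t, x, exposure, off,
                         data$sstart, data$slen, data$y,
                         delta, beta, control$lambda, lam_b, fit$objective,
                         cand_didx - 1L, vars - 1L, control$min_bucket_n,
                         control$search_maxit, control$search_tol,
                         control$tol_grad)
      }
      if (control$mtry_per_node && mtry < p) {
        res <- list(found = FALSE, gain = -Inf)
        for (k in eligible) {
          rk <- search_one(k, sort(sample.int(p, mtry)))
          if (rk$found && rk$gain > res$gain) res <- rk
        }
      } else {
        vars <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
        res <- search_one(eligible, vars)
      }
      if (!isTRUE(res$found) || res$gain <= control$epsilon) break
      k <- res$node + 1L
      v <- res$var + 1L
      thr <- res$threshold
      warm_delta <- drop(res$delta)
      warm_beta <- res$beta
    } else {
      st <- replay_steps[[step + 1L]]
      k <- st$didx
      v <- match(st$var, colnames(data$Z))
      thr <- st$threshold
      warm_delta <- c(delta, delta[k])
      warm_beta <- beta
    }

    # apply the split: left child keeps index k, right child gets t + 1
    pid <- id_of_didx[k]
    pdepth <- depth_of_didx[k]
    in_node <- node_of_row == k
    go_right <- in_node & data$Z[, v] > thr
    node_of_row[go_right] <- t + 1L
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[pid]]$leaf <- FALSE
    nodes[[pid]]$var <- colnames(data$Z)[v]
    nodes[[pid]]$threshold <- thr
    nodes[[pid]]$left <- lid
    nodes[[pid]]$right <- rid
    nodes[[pid]]$didx <- NULL
    nodes[[lid]] <- list(id = lid, leaf = TRUE, didx = k, depth = pdepth + 1L)
    nodes[[rid]] <- list(id = rid, leaf = TRUE, didx = t + 1L,
                         depth = pdepth + 1L)
    t <- t + 1L
    step <- step + 1L

    fit <- cpp_tree_refit(node_of_row - 1L, t, x, exposure, off,
                          data$sstart, data$slen, data$y,
                          control$lambda, lam_b, warm_delta, warm_beta,
                          control$maxit, control$tol_obj, control$tol_grad)
    delta <- drop(fit$delta)
    beta <- fit$beta
    flagged <- flagged || isTRUE(fit$flagged)
    trace[[step + 1L]] <- list(step = step, t = t, didx = k,
                               var = colnames(data$Z)[v], threshold = thr,
                               loglik = fit$loglik, objective = fit$objective)
  }

  structure(list(nodes = nodes, delta = delta,
                 beta_hat = if (exposure) beta else NULL,
                 has_exposure = exposure, t = t,
                 loglik = fit$loglik, objective = fit$objective,
                 trace = trace, control = control,
                 var_names = colnames(data$Z), offset = offset,
                 n = data$n, nobs = nobs, flagged = flagged,
                 pruned = FALSE),
            class = "clogit_tree")
}

#' Fit a conditional logistic regression tree
#'
#' Starts from a model holding only the (conditioned-out) stratum intercepts
#' and, optionally, a linear exposure effect, then grows by global best-first
#' search: each iteration draws an mtry subset of covariates, evaluates every
#' (terminal node, variable, midpoint threshold) candidate by jointly
#' refitting all node effects and the exposure effect on the augmented
#' indicator design, and accepts the split with the largest penalized
#' conditional log-likelihood gain. Growth stops when no admissible split
#' improves the objective by more than `epsilon` or when size constraints
#' bind. The covariate effect is a step function
#' `f(z) = delta_1 I(z in S_1) + ... + delta_t I(z in S_t)` over the terminal
#' nodes, on top of which the exposure enters as `x * beta`.
#'
#' @param data a `matched_data` object.
#' @param exposure model a dedicated linear exposure effect? Defaults to
#'   `TRUE` when the data carry an exposure column; `FALSE` gives the
#'   exploratory (forest-member) form without a separate `beta`.
#' @param control a [tree_control()] object.
#' @param offset optional fixed per-row offset (log-odds scale), e.g. the
#'   linear CLR fit of all covariates.
#' @return an object of class `clogit_tree`.
#' @export
clogit_tree <- function(data, exposure = !is.null(data$x),
                        control = tree_control(), offset = NULL) {
  stopifnot(inherits(data, "matched_data"))
  with_seed(control$seed, grow_engine(data, exposure, control, offset))
}

# terminal-node (delta) index of each row of Z
route_rows <- function(tree, Z) {
  out <- integer(nrow(Z))
  recurse <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (isTRUE(nd$leaf)) { out[rows] <<- nd$didx; return(invisible()) }
    if (!nd$var %in% colnames(Z)) stop("unseen variable: ", nd$var)
    left <- Z[rows, nd$var] <= nd$threshold
    if (any(left)) recurse(nd$left, rows[left])
    if (any(!left)) recurse(nd$right, rows[!left])
  }
  recurse(1L, seq_len(nrow(Z)))
  out
}

#' Predict from a conditional logistic regression tree
#'
#' @param object a `clogit_tree`.
#' @param newdata a `matched_data` object (or plain list with `Z` and
#'   optionally `x`).
#' @param offset optional per-row offset added to the prediction (a tree
#'   grown on an offset does not store new-data offsets itself).
#' @param ... unused.
#' @return per-row linear predictor contribution `x*beta + f(z) + offset`.
#' @export
predict.clogit_tree <- function(object, newdata, offset = NULL, ...) {
  Z <- newdata$Z
  eta <- object$delta[route_rows(object, Z)]
  if (object$has_exposure) {
    if (is.null(newdata$x)) stop("tree has an exposure term but newdata has no exposure")
    eta <- eta + object$beta_hat * as.numeric(newdata$x)
  }
  if (!is.null(offset)) eta <- eta + offset
  eta
}

#' @export
coef.clogit_tree <- function(object, ...) {
  c(if (object$has_exposure) c(exposure = object$beta_hat),
    stats::setNames(object$delta, paste0("delta", seq_along(object$delta))))
}

#' @export
print.clogit_tree <- function(x, digits = 3, ...) {
  cat("Conditional logistic regression tree: ", x$t, " terminal node(s), ",
      x$n, " strata", if (x$pruned) ", BIC-pruned", "\n", sep = "")
  if (x$has_exposure)
    cat(sprintf("Exposure effect: beta = %.4f (OR = %.3f)\n",
                x$beta_hat, exp(x$beta_hat)))
  cat(sprintf("Conditional log-likelihood: %.4f\n", x$loglik))
  rec <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (isTRUE(nd$leaf)) {
      cat(pad, "* node S", nd$didx, ": delta = ",
          format(x$delta[nd$didx], digits = digits), "\n", sep = "")
    } else {
      cat(pad, nd$var, " <= ", format(nd$threshold, digits = digits),
          "\n", sep = "")
      rec(nd$left, indent + 1L)
      cat(pad, nd$var, " > ", format(nd$threshold, digits = digits),
          "\n", sep = "")
      rec(nd$right, indent + 1L)
    }
  }
  rec(1L, 0L)
  invisible(x)
}

#' Prune a tree by the Bayesian information criterion
#'
#' Standalone trees (outside a forest) are pruned by selecting, along the
#' recorded growth sequence, the tree size minimizing
#' `BIC = -2 loglik + df log(n)` with `df = t - 1 + (1 if exposure)` and `n`
#' the number of strata; the coefficients are refit for the selected size.
#' Trees inside a forest are never pruned.
#'
#' @param tree a `clogit_tree` grown on `data`.
#' @param data the training `matched_data`.
#' @return a `clogit_tree` of the BIC-optimal size (its `bic` field holds the
#'   BIC path).
#' @export
prune_bic <- function(tree, data) {
  stopifnot(inherits(tree, "clogit_tree"), inherits(data, "matched_data"))
  ll <- vapply(tree$trace, `[[`, numeric(1), "loglik")
  nsteps <- length(ll) - 1L
  df <- seq.int(0L, nsteps) + as.integer(tree$has_exposure)
  bic <- -2 * ll + df * log(data$n)
  jstar <- which.min(bic) - 1L
  out <- if (jstar == nsteps) tree else {
    grow_engine(data, tree$has_exposure, tree$control, tree$offset,
                replay_steps = tree$trace[seq_len(jstar) + 1L])
  }
  out$pruned <- TRUE
  out$bic <- bic
  out
}
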