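#' Serialize a forest (or tree) to JSON
#'
#' Writes a versioned JSON document holding the control echo, the linear
#' offset coefficients, every tree as a nested (rule, children, delta)
#' object, the per-tree in-bag stratum labels and the averaged exposure
#' effect. Numbers are written at full precision, so a round-trip through
#' [forest_from_json()] reproduces predictions bit-exactly.
#'
#' @param model a `clogit_forest`.
#' @param path output file; `NULL` returns the JSON string.
#' @return the path (or the JSON string), invisibly.
#' @export
forest_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "clogit_forest"))
  doc <- list(
    schema = "clogitforest/1",
    var_names = model$var_names,
    has_exposure = model$has_exposure,
    beta_bar = model$beta_bar,
    offset_mode = model$offset_mode,
    offset_gamma = as.list(model$offset_gamma),
    mtry = unclass(model$mtry)[1],
    sampling = model$control$sampling,
    ntree = length(model$trees),
    n = model$n,
    stratum_labels = model$stratum_labels,
    inbag = lapply(model$inbag, function(i) model$stratum_labels[i]),
    trees = lapply(model$trees, tree_to_list)
  )
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

tree_to_list <- function(tree) {
  node_list <- function(id) {
    nd <- tree$nodes[[id]]
    if (isTRUE(nd$leaf)) {
      list(delta = tree$delta[nd$didx], node = nd$didx)
    } else {
      list(var = nd$var, threshold = nd$threshold,
           left = node_list(nd$left), right = node_list(nd$right))
    }
  }
  list(beta = tree$beta_hat, t = tree$t, loglik = tree$loglik,
       root = node_list(1L))
}

list_to_tree <- function(lst, var_names, has_exposure) {
  nodes <- list()
  delta <- numeric(0)
  build <- function(obj, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id)  # reserve slot before recursing
    if (!is.null(obj$var)) {
      lid <- build(obj$left, depth + 1L)
      rid <- build(obj$right, depth + 1L)
      nodes[[id]] <<- list(id = id, leaf = FALSE, var = obj$var,
                           threshold = obj$threshold, left = lid, right = rid)
    } else {
      didx <- as.integer(obj$node)
      delta[didx] <<- obj$delta
      nodes[[id]] <<- list(id = id, leaf = TRUE, didx = didx, depth = depth)
    }
    id
  }
  build(lst$root, 0L)
  structure(list(nodes = nodes, delta = delta,
                 beta_hat = if (has_exposure) lst$beta else NULL,
                 has_exposure = has_exposure, t = lst$t,
                 loglik = lst$loglik, var_names = var_names,
                 trace = NULL, pruned = FALSE),
            class = "clogit_tree")
}

#' Load a forest from its JSON serialization
#'
#' @param path file written by [forest_to_json()] (or its JSON string).
#' @return a `clogit_forest` sufficient for prediction, OOB scoring and
#'   importance (growth traces are not serialized, so loaded trees cannot be
#'   re-pruned).
#' @export
forest_from_json <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!identical(doc$schema, "clogitforest/1")) {
    stop("unknown model schema: ", doc$schema %||% "<missing>")
  }
  labels <- unlist(doc$stratum_labels)
  inbag <- lapply(doc$inbag, function(l) match(unlist(l), labels))
  has_exposure <- isTRUE(doc$has_exposure)
  trees <- lapply(doc$trees, list_to_tree,
                  var_names = unlist(doc$var_names),
                  has_exposure = has_exposure)
  gamma <- unlist(doc$offset_gamma)
  structure(list(
    trees = trees,
    inbag = inbag,
    oob = lapply(inbag, function(i) setdiff(seq_len(doc$n), i)),
    beta_bar = doc$beta_bar,
    beta_trees = if (has_exposure) vapply(trees, `[[`, numeric(1), "beta_hat"),
    has_exposure = has_exposure,
    offset_mode = doc$offset_mode,
    offset_gamma = if (length(gamma)) gamma,
    mtry = doc$mtry,
    control = forest_control(ntree = doc$ntree, mtry = doc$mtry,
                             sampling = doc$sampling,
                             offset = doc$offset_mode),
    var_names = unlist(doc$var_names),
    n = doc$n,
    stratum_labels = labels
  ), class = "clogit_forest")
}
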