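#' Construct a matched case-control dataset
#'
#' Builds the validated data object used by all fitting functions. The data
#' come in strata (one case matched to one or more controls); rows are
#' reordered so that strata are contiguous, in order of first appearance.
#' Row order within strata is irrelevant to every downstream computation.
#'
#' @param data a data frame with one row per subject.
#' @param stratum name of the stratum identifier column.
#' @param case name of the binary case indicator column (exactly one `1` per
#'   stratum).
#' @param exposure optional name of a binary exposure column, the dedicated
#'   variable whose log odds ratio is modeled as a separate linear effect.
#' @param covariates character vector of covariate column names, or `NULL` to
#'   use all remaining columns.
#' @param kinds optional named character vector giving the kind of each
#'   covariate (`"continuous"`, `"binary"` or `"ordinal"`); inferred when
#'   missing. Ordinal variables must be ordered factors and are recoded to
#'   consecutive integers; trees split them like numeric variables, so no
#'   pre-dichotomization is ever needed.
#'
#' @return an object of class `matched_data` with elements `stratum`
#'   (labels per row), `y`, `x` (or `NULL`), `Z` (numeric covariate matrix),
#'   `var_kind`, `n` (number of strata) and `m` (stratum sizes).
#'
#' @details Missing values are rejected, not imputed. Unordered factors with
#'   more than two levels are not supported; recode them before matching.
#' @export
matched_data <- function(data, stratum, case, exposure = NULL,
                         covariates = NULL, kinds = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(stratum, case, exposure)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(stratum, case, exposure))
  } else {
    missing_cols <- setdiff(covariates, names(data))
    if (length(missing_cols)) stop("covariate column(s) not found: ",
                                   paste(missing_cols, collapse = ", "))
  }

  slab <- as.character(data[[stratum]])
  ord <- order(match(slab, unique(slab)))
  data <- data[ord, , drop = FALSE]
  slab <- slab[ord]

  y <- data[[case]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("case column '", case, "' must be coded 0/1 with no missing values")
  }
  y <- as.integer(y)

  cases_per_stratum <- tapply(y, factor(slab, levels = unique(slab)), sum)
  bad <- names(cases_per_stratum)[cases_per_stratum != 1L]
  if (length(bad)) {
    stop("each stratum must contain exactly one case; offending stratum: ",
         paste(bad, collapse = ", "))
  }
  m <- as.integer(table(factor(slab, levels = unique(slab))))
  if (any(m < 2L)) {
    stop("each stratum needs at least one control; offending stratum: ",
         paste(unique(slab)[m < 2L], collapse = ", "))
  }

  x <- NULL
  if (!is.null(exposure)) {
    x <- data[[exposure]]
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      stop("exposure column '", exposure,
           "' must be coded 0/1 with no missing values")
    }
    x <- as.integer(x)
  }

  Z <- matrix(NA_real_, nrow(data), length(covariates),
              dimnames = list(NULL, covariates))
  var_kind <- character(length(covariates))
  names(var_kind) <- covariates
  for (v in covariates) {
    col <- data[[v]]
    if (anyNA(col)) stop("missing values in covariate '", v,
                         "'; impute or drop before building the dataset")
    if (is.ordered(col)) {
      Z[, v] <- as.integer(col)
      var_kind[v] <- "ordinal"
    } else if (is.factor(col) || is.character(col)) {
      lev <- unique(as.character(col))
      if (length(lev) > 2L) {
        stop("unordered categorical covariate '", v,
             "' with >2 levels is not supported; use an ordered factor")
      }
      Z[, v] <- as.numeric(factor(col, levels = sort(lev))) - 1
      var_kind[v] <- "binary"
    } else {
      col <- as.numeric(col)
      Z[, v] <- col
      var_kind[v] <- if (all(col %in% c(0, 1))) "binary" else "continuous"
    }
  }
  if (!is.null(kinds)) {
    var_kind[names(kinds)] <- unname(kinds)
  }

  structure(list(stratum = slab, y = y, x = x, Z = Z, var_kind = var_kind,
                 n = length(m), m = m,
                 sstart = cumsum(c(0L, m[-length(m)])), slen = m),
            class = "matched_data")
}

#' Read a matched case-control dataset from a delimited text file
#'
#' @param path path to a CSV file with a header row.
#' @param stratum,case,exposure,covariates,kinds column roles, passed to
#'   [matched_data()].
#' @param sep field separator.
#' @return a `matched_data` object.
#' @export
read_matched_csv <- function(path, stratum, case, exposure = NULL,
                             covariates = NULL, kinds = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  matched_data(df, stratum = stratum, case = case, exposure = exposure,
               covariates = covariates, kinds = kinds)
}

#' Write a matched dataset back to CSV
#'
#' Inverse of [read_matched_csv()]: the written file, read back with the same
#' schema, reproduces the stratum structure, outcome, exposure and covariates
#' exactly.
#'
#' @param data a `matched_data` object.
#' @param path output file path.
#' @export
write_matched_csv <- function(data, path) {
  stopifnot(inherits(data, "matched_data"))
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.matched_data <- function(x, ...) {
  df <- data.frame(stratum = x$stratum, case = x$y,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$x)) df$exposure <- x$x
  cbind(df, as.data.frame(x$Z))
}

#' @export
print.matched_data <- function(x, ...) {
  cat("Matched case-control data: ", x$n, " strata, ",
      length(x$y), " subjects (stratum sizes ",
      paste(range(x$m), collapse = "-"), ")\n", sep = "")
  cat("Exposure: ", if (is.null(x$x)) "none" else
    paste0("present (", round(100 * mean(x$x), 1), "% exposed)"), "\n", sep = "")
  cat("Covariates: ", ncol(x$Z), " (",
      paste(sprintf("%s:%s", colnames(x$Z), substr(x$var_kind, 1, 4)),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# run code under a temporary RNG state; NULL seed means "use current stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Assign strata to cross-validation folds
#'
#' Partitioning operates on whole strata: no stratum is ever split across
#' folds, so the conditional-likelihood contribution of a stratum belongs to
#' exactly one fold.
#'
#' @param data a `matched_data` object.
#' @param k number of folds (at most the number of strata).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return integer vector of fold labels (1..k), one per stratum.
#' @export
stratum_folds <- function(data, k, seed = NULL) {
  stopifnot(inherits(data, "matched_data"))
  if (k > data$n) stop("k = ", k, " folds but only ", data$n, " strata")
  with_seed(seed, sample(rep_len(seq_len(k), data$n)))
}

#' Draw an in-bag sample of strata
#'
#' Resampling for bagging happens at the level of whole strata. `"bootstrap"`
#' draws n strata with replacement; `"subsample"` draws round(0.632 n)
#' distinct strata without replacement (0.632 being the expected unique
#' fraction 1 - 1/e of an n-out-of-n bootstrap); `"none"` keeps every stratum
#' in-bag (degenerate, used to reduce a forest to a single tree). The
#' out-of-bag (OOB) set is the complement of the in-bag stratum set.
#'
#' @param data a `matched_data` object.
#' @param mode `"subsample"`, `"bootstrap"` or `"none"`.
#' @param seed integer seed.
#' @return a list with `inbag` (stratum indices, a multiset under bootstrap),
#'   `oob` (distinct out-of-bag stratum indices) and `mode`.
#' @export
draw_inbag <- function(data, mode = c("subsample", "bootstrap", "none"),
                       seed = NULL) {
  stopifnot(inherits(data, "matched_data"))
  mode <- match.arg(mode)
  n <- data$n
  if (n < 2L && mode != "none") stop("need at least 2 strata to resample")
  inbag <- with_seed(seed, switch(mode,
    bootstrap = sample.int(n, n, replace = TRUE),
    subsample = sample.int(n, floor(0.632 * n + 0.5)),  # half-up rounding
    none = seq_len(n)
  ))
  list(inbag = inbag, oob = setdiff(seq_len(n), inbag), mode = mode)
}

# subset (possibly with repetition) whole strata; repeated strata get
# distinct labels so each draw contributes its own likelihood term
md_subset_strata <- function(data, strata_idx) {
  rows <- integer(0)
  lab <- character(0)
  occ <- integer(length(data$m))
  for (i in strata_idx) {
    occ[i] <- occ[i] + 1L
    r <- data$sstart[i] + seq_len(data$slen[i])
    rows <- c(rows, r)
    lab <- c(lab, rep(paste0(data$stratum[r[1]],
                             if (occ[i] > 1L) paste0(".rep", occ[i]) else ""),
                      data$slen[i]))
  }
  m <- data$slen[strata_idx]
  structure(list(stratum = lab, y = data$y[rows],
                 x = if (is.null(data$x)) NULL else data$x[rows],
                 Z = data$Z[rows, , drop = FALSE],
                 var_kind = data$var_kind,
                 n = length(strata_idx), m = m,
                 sstart = cumsum(c(0L, m[-length(m)])), slen = m,
                 parent_rows = rows),
            class = "matched_data")
}
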