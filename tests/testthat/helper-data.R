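# small synthetic matched datasets built in code (no stored fixtures)

# random matched data: n strata of size m, p standard-normal covariates,
# case position uniform, optional exposure with prevalence 0.5
tiny_md <- function(n = 20, m = 4, p = 3, exposure = TRUE, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    df <- data.frame(stratum = rep(sprintf("s%03d", seq_len(n)), each = m))
    y <- integer(n * m)
    y[(seq_len(n) - 1) * m + sample.int(m, n, replace = TRUE)] <- 1L
    df$case <- y
    if (exposure) df$exposure <- rbinom(n * m, 1, 0.5)
    for (j in seq_len(p)) df[[paste0("z", j)]] <- rnorm(n * m)
    matched_data(df, "stratum", "case",
                 exposure = if (exposure) "exposure")
  })
}

# matched data whose covariates are constant within every stratum (no
# informative split exists; conditioning removes all covariate information)
stratum_constant_md <- function(n = 30, m = 4, p = 2, seed = 2) {
  set.seed(seed)
  df <- data.frame(stratum = rep(sprintf("s%03d", seq_len(n)), each = m))
  y <- integer(n * m)
  y[(seq_len(n) - 1) * m + sample.int(m, n, replace = TRUE)] <- 1L
  df$case <- y
  df$exposure <- rbinom(n * m, 1, 0.5)
  for (j in seq_len(p)) {
    df[[paste0("z", j)]] <- rep(rnorm(n), each = m)
  }
  matched_data(df, "stratum", "case", exposure = "exposure")
}

# direct softmax enumeration: probability that member j is the case, from
# first principles (no max-subtraction) -- the oracle for stratum_cond_prob
enum_case_prob <- function(eta, j) exp(eta[j]) / sum(exp(eta))

reduced_cfg <- function(dgp = "A", n_signal = 5, n_noise = 5, ...) {
  dgp_config(dgp, n_signal = n_signal, n_noise = n_noise,
             preset = "reduced", ...)
}
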