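#' Simulation configuration
#'
#' Settings for the lognormal-multinomial community generator. Defaults
#' reproduce the benchmark conditions: 119 samples, 20 contributing and 100
#' non-contributing taxa, contributor coefficients drawn Uniform(-5, 5),
#' multinomial read sampling at a fixed depth.
#'
#' @param n_samples number of communities (default 119).
#' @param n_contributors taxa with nonzero response coefficients (default 20).
#' @param n_noncontributors taxa with coefficient exactly zero (default 100).
#' @param n_correlated number of non-contributors given a pairwise log-scale
#'   correlation `rho` with a contributor (default 0).
#' @param rho pairwise correlation strength in (-1, 1) for those pairs.
#' @param coef_low,coef_high bounds of the uniform contributor-coefficient
#'   distribution (defaults -5, 5).
#' @param n_reads sequencing depth per sample for the multinomial count
#'   draw (default 100000).
#' @param noise_frac response noise variance as a fraction of the variance
#'   of the linear signal (default 0.1), with floor `noise_floor`.
#' @param noise_floor lower bound on the response noise variance.
#' @param abundance_floor minimum mean relative abundance retained when
#'   estimating lognormal parameters from a table (default 0.001 = 0.1%).
#' @param seed integer seed.
#' @param log_mu,log_sigma optional per-taxon mean and SD of log absolute
#'   abundance (recycled/truncated to the taxon count), e.g. from
#'   [estimate_lognormal_params()]. When `NULL` they are drawn once from
#'   Normal(0, 1.5) and Uniform(0.5, 2) under the seeded stream, spreads
#'   typical of filtered 16S communities.
#' @param response_scale `"log"` (default) generates the outcome linearly in
#'   log absolute abundance, matching the fitted model; `"linear"` uses the
#'   absolute abundances themselves.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 119, n_contributors = 20,
                              n_noncontributors = 100, n_correlated = 0,
                              rho = 0.5, coef_low = -5, coef_high = 5,
                              n_reads = 100000, noise_frac = 0.1,
                              noise_floor = 1e-6, abundance_floor = 0.001,
                              seed = 1, log_mu = NULL, log_sigma = NULL,
                              response_scale = c("log", "linear")) {
  response_scale <- match.arg(response_scale)
  if (n_samples < 1 || n_contributors < 0 || n_noncontributors < 0) {
    abort("counts must be positive.")
  }
  if (n_contributors + n_noncontributors < 2) abort("need at least 2 taxa.")
  if (abs(rho) >= 1) abort("`rho` must satisfy |rho| < 1.")
  if (coef_low >= coef_high) abort("`coef_low` must be < `coef_high`.")
  if (n_reads < 1) abort("`n_reads` must be >= 1.")
  if (abundance_floor < 0 || abundance_floor >= 1) {
    abort("`abundance_floor` must lie in [0, 1).")
  }
  if (n_correlated > n_noncontributors) {
    abort("`n_correlated` cannot exceed `n_noncontributors`.")
  }
  if (n_correlated > 0 && n_contributors == 0) {
    abort("correlated non-contributors need at least one contributor.")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_contributors = as.integer(n_contributors),
                 n_noncontributors = as.integer(n_noncontributors),
                 n_correlated = as.integer(n_correlated), rho = rho,
                 coef_low = coef_low, coef_high = coef_high,
                 n_reads = as.integer(n_reads), noise_frac = noise_frac,
                 noise_floor = noise_floor,
                 abundance_floor = abundance_floor, seed = as.integer(seed),
                 log_mu = log_mu, log_sigma = log_sigma,
                 response_scale = response_scale),
            class = "simulation_config")
}

#' Estimate per-taxon lognormal abundance parameters from a table
#'
#' Drops taxa whose mean relative abundance is at or below
#' `abundance_floor`, then returns the mean and SD of the log
#' (zero-replaced) relative abundances of each surviving taxon — the
#' empirical parameters that make simulated communities mimic a real
#' dataset.
#'
#' @param table a [community_table()].
#' @param abundance_floor minimum mean relative abundance (default 0.001).
#' @return list with `log_mu`, `log_sigma` (named numeric vectors) and
#'   `kept_taxa`.
#' @export
estimate_lognormal_params <- function(table, abundance_floor = 0.001) {
  table <- as_community_table(table)
  if (abundance_floor < 0 || abundance_floor >= 1) {
    abort("`abundance_floor` must lie in [0, 1).")
  }
  rel <- relative_abundance(table)
  keep <- colMeans(rel) > abundance_floor
  if (sum(keep) < 2) abort("fewer than 2 taxa survive the abundance floor.")
  lc <- log(rel[, keep, drop = FALSE])
  list(log_mu = colMeans(lc),
       log_sigma = apply(lc, 2, sd),
       kept_taxa = colnames(rel)[keep])
}

# Resolve per-taxon lognormal parameters for a config, drawing defaults
# from the current RNG stream when unspecified. Communities are restricted
# to taxa whose expected relative abundance clears `abundance_floor`
# (default-drawn parameters violating it are redrawn), mirroring the
# abundance filter applied before parameter estimation on real data.
resolve_lognormal_params <- function(config, p) {
  drew <- is.null(config$log_mu) && is.null(config$log_sigma)
  log_mu <- if (is.null(config$log_mu)) rnorm(p, 0, 1.5)
            else rep_len(as.numeric(config$log_mu), p)
  log_sigma <- if (is.null(config$log_sigma)) runif(p, 0.5, 2)
               else rep_len(as.numeric(config$log_sigma), p)
  if (any(log_sigma < 0)) abort("`log_sigma` entries must be >= 0.")
  if (drew && config$abundance_floor > 0) {
    for (it in 1:200) {
      ex <- exp(log_mu + log_sigma^2 / 2)
      low <- ex / sum(ex) <= config$abundance_floor
      if (!any(low)) break
      log_mu[low] <- rnorm(sum(low), 0, 1.5)
      log_sigma[low] <- runif(sum(low), 0.5, 2)
    }
  }
  list(log_mu = log_mu, log_sigma = log_sigma)
}

# correlated pairs: each of the first n_correlated non-contributors is
# paired (cyclically) with a contributor
correlation_pairs <- function(config) {
  if (config$n_correlated == 0) return(NULL)
  contrib <- seq_len(config$n_contributors)
  corr <- config$n_contributors + seq_len(config$n_correlated)
  cbind(contributor = rep_len(contrib, config$n_correlated),
        correlated = corr)
}

#' Simulate absolute abundances
#'
#' Draws log absolute abundances from a multivariate normal whose diagonal
#' comes from the per-taxon lognormal parameters; designated
#' (contributor, correlated non-contributor) pairs get off-diagonal
#' covariance `rho * sigma_j * sigma_k`. Taxa are ordered contributors
#' first, then non-contributors (correlated ones first).
#'
#' @param config a [simulation_config()].
#' @return `n_samples` x `n_taxa` matrix of positive abundances.
#' @export
simulate_abundances <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- config$n_contributors + config$n_noncontributors
  par <- resolve_lognormal_params(config, p)
  Sigma <- diag(par$log_sigma^2, p)
  pairs <- correlation_pairs(config)
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      j1 <- pairs[k, 1]; j2 <- pairs[k, 2]
      cv <- config$rho * par$log_sigma[j1] * par$log_sigma[j2]
      Sigma[j1, j2] <- Sigma[j1, j2] + cv
      Sigma[j2, j1] <- Sigma[j2, j1] + cv
    }
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) {
      abort(sprintf(
        "covariance not positive definite (pair %d-%d shares a contributor?)",
        pairs[1, 1], pairs[1, 2]))
    }
  }
  L <- chol(Sigma)
  Z <- matrix(rnorm(config$n_samples * p), config$n_samples, p)
  logx <- sweep(Z %*% L, 2, par$log_mu, "+")
  x <- exp(logx)
  colnames(x) <- c(sprintf("contrib_%02d", seq_len(config$n_contributors)),
                   if (config$n_noncontributors)
                     sprintf("null_%03d", seq_len(config$n_noncontributors)))
  rownames(x) <- sprintf("sample_%03d", seq_len(config$n_samples))
  x
}

#' Simulate the continuous response from absolute abundances
#'
#' Contributor coefficients are drawn Uniform(`coef_low`, `coef_high`),
#' non-contributors get exactly zero, and the outcome is the linear
#' combination of the (log, by default) absolute abundances plus Gaussian
#' noise whose variance is `noise_frac` times the signal variance.
#'
#' @param abs_abundance matrix from [simulate_abundances()].
#' @param config a [simulation_config()].
#' @return list with `response`, `true_beta`, `contributor_mask`.
#' @export
simulate_response <- function(abs_abundance, config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- ncol(abs_abundance)
  if (config$n_contributors > p) {
    abort("more contributors requested than taxa available.")
  }
  contributor_mask <- as.integer(seq_len(p) <= config$n_contributors)
  true_beta <- numeric(p)
  true_beta[contributor_mask == 1] <-
    runif(config$n_contributors, config$coef_low, config$coef_high)
  predictor <- if (config$response_scale == "log") log(abs_abundance)
               else abs_abundance
  signal <- drop(predictor %*% true_beta)
  noise_var <- max(config$noise_frac * var(signal), config$noise_floor)
  if (noise_var <= 0) abort("response noise variance must be > 0.")
  response <- signal + rnorm(nrow(abs_abundance), 0, sqrt(noise_var))
  names(true_beta) <- colnames(abs_abundance)
  list(response = response, true_beta = true_beta,
       contributor_mask = contributor_mask)
}

#' Close abundances and draw multinomial read counts
#'
#' @param abs_abundance matrix of positive absolute abundances.
#' @param n_reads sequencing depth per sample.
#' @return list with `rel_abundance` (rows sum to 1) and integer `counts`
#'   (rows sum to `n_reads`).
#' @export
simulate_counts <- function(abs_abundance, n_reads) {
  if (n_reads < 1) abort("`n_reads` must be >= 1.")
  tot <- rowSums(abs_abundance)
  if (any(tot <= 0)) abort("a sample has zero total abundance.")
  rel <- abs_abundance / tot
  counts <- vapply(seq_len(nrow(rel)),
                   function(i) rmultinom(1, n_reads, rel[i, ])[, 1],
                   numeric(ncol(rel)))
  counts <- matrix(counts, nrow(rel), ncol(rel), byrow = TRUE,
                   dimnames = dimnames(rel))
  list(rel_abundance = rel, counts = counts)
}

#' Generate a complete simulated dataset
#'
#' Composes [simulate_abundances()], [simulate_response()] and
#' [simulate_counts()] under one seed into a ground-truth-annotated dataset.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_dataset`: `abs_abundance`,
#'   `rel_abundance`, `counts`, `response`, `true_beta`,
#'   `contributor_mask`, `correlated_mask`, `config`.
#' @export
make_dataset <- function(config = simulation_config()) {
  x <- simulate_abundances(config) # also seeds the stream
  resp <- simulate_response(x, config)
  cnt <- simulate_counts(x, config$n_reads)
  p <- ncol(x)
  correlated_mask <- integer(p)
  pairs <- correlation_pairs(config)
  if (!is.null(pairs)) correlated_mask[pairs[, "correlated"]] <- 1L
  structure(list(abs_abundance = x, rel_abundance = cnt$rel_abundance,
                 counts = cnt$counts, response = resp$response,
                 true_beta = resp$true_beta,
                 contributor_mask = resp$contributor_mask,
                 correlated_mask = correlated_mask, config = config),
            class = "simulated_dataset")
}

#' @exportS3Method base::print
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d samples x %d taxa (%d contributors, %d correlated nulls), depth %d\n",
    nrow(x$counts), ncol(x$counts), sum(x$contributor_mask),
    sum(x$correlated_mask), x$config$n_reads))
  invisible(x)
}
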