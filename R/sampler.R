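#' Sampler configuration
#'
#' @param n_burn number of burn-in iterations discarded before draws are
#'   retained (default 1000; chains were found to be well converged by then,
#'   see the methods vignette).
#' @param n_draws number of post-burn-in iterations (default 1000).
#' @param seed integer seed; every random ingredient of the chain flows from
#'   it, so identical seeds give bit-identical traces.
#' @param thin keep every `thin`-th draw (default 1).
#' @param continuous_kernel kernel for the continuous coordinates. The
#'   implemented kernel is an adaptive random-walk Metropolis
#'   (`"adaptive_random_walk"`); `"gradient_based"` is accepted for
#'   forward compatibility and currently maps to the same kernel with a
#'   message.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(n_burn = 1000, n_draws = 1000, seed = 1, thin = 1,
                           continuous_kernel = c("adaptive_random_walk",
                                                 "gradient_based")) {
  continuous_kernel <- match.arg(continuous_kernel)
  if (n_burn < 0) abort("`n_burn` must be >= 0.")
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  if (thin < 1) abort("`thin` must be >= 1.")
  structure(list(n_burn = as.integer(n_burn), n_draws = as.integer(n_draws),
                 seed = as.integer(seed), thin = as.integer(thin),
                 continuous_kernel = continuous_kernel),
            class = "sampler_config")
}

# crude effective sample size from the empirical autocorrelation function,
# truncated at the first non-positive lag
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(NA_real_)
  rho <- drop(acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf)[-1]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

# Shared engine behind run_chain() and fit_clr_ss(): spike-and-slab
# regression of y on a fixed predictor matrix. `marginalize_total` switches
# the latent-total variance/mean terms on (BRACoD) or off (plain clr-SS).
ssvs_fit <- function(y, Xmat, priors, config, standardize = TRUE,
                     marginalize_total = TRUE, mean_rel_abundance = NULL,
                     method = "bracod") {
  n <- length(y)
  if (n < 3) abort("at least 3 samples are required to fit the model.")
  if (nrow(Xmat) != n) abort("predictor matrix and response sizes differ.")
  if (config$continuous_kernel == "gradient_based") {
    rlang::inform(paste("gradient-based kernel not available;",
                        "using the adaptive random-walk kernel."))
  }
  y_center <- if (standardize) mean(y) else 0
  y_scale <- if (standardize) sd(y) else 1
  if (!is.finite(y_scale) || y_scale == 0) {
    abort("response has zero variance; nothing to regress on.")
  }
  ys <- (y - y_center) / y_scale

  set.seed(config$seed)
  p <- ncol(Xmat)
  tau0 <- 0.5
  init_bi <- rnorm(p, 0, sqrt(priors$slab_multiplier_g) * tau0)
  init_be <- rnorm(p, 0, tau0)
  res <- .ssvs_chain_cpp(
    ys, Xmat,
    mu_t = if (marginalize_total) priors$total_mu_t else 0,
    sigma2_t = if (marginalize_total) priors$total_sigma2_t else 0,
    pi_incl = priors$inclusion_prob_prior,
    g = priors$slab_multiplier_g,
    intercept_sd = priors$intercept_prior_sd,
    noise_scale = priors$noise_prior_scale,
    n_burn = config$n_burn, n_draws = config$n_draws, thin = config$thin,
    init_alpha = mean(ys), init_sigma2 = max(var(ys), 1e-8), init_tau = tau0,
    init_bi = init_bi, init_be = init_be, init_z = integer(p))

  colnames(res$beta_included) <- colnames(Xmat)
  colnames(res$beta_excluded) <- colnames(Xmat)
  colnames(res$indicators) <- colnames(Xmat)
  diagnostics <- c(res$diagnostics,
                   list(ess_alpha = ess(res$alpha),
                        ess_sigma2 = ess(res$sigma2),
                        ess_tau2 = ess(res$tau2)))
  structure(list(draws = list(alpha = res$alpha, sigma2 = res$sigma2,
                              tau2 = res$tau2,
                              beta_included = res$beta_included,
                              beta_excluded = res$beta_excluded,
                              indicators = res$indicators),
                 taxon_ids = colnames(Xmat),
                 mean_rel_abundance = mean_rel_abundance,
                 y_center = y_center, y_scale = y_scale,
                 standardized = standardize,
                 priors = priors, config = config,
                 method = method,
                 diagnostics = diagnostics),
            class = "bracod_trace")
}

#' Draw from the posterior of the compositional spike-and-slab model
#'
#' Runs the MCMC chain: an adaptive random-walk Metropolis kernel on the
#' continuous coordinates (intercept, residual variance, spike scale and
#' both coefficient copies) and a Metropolised Gibbs sweep in random order
#' over the binary inclusion indicators. The likelihood is the closed-form
#' marginal over the per-sample latent log total abundance (see
#' [log_marginal_likelihood()]).
#'
#' By default the response is standardized internally for sampling and all
#' reported coefficient summaries are rescaled back to the original response
#' units by [summarize_trace()].
#'
#' @param table a [community_table()] (counts or relative abundances).
#' @param response numeric vector aligned with the table rows, or a
#'   two-column data frame `(sample_id, value)` joined by id.
#' @param priors a [prior_config()].
#' @param config a [sampler_config()].
#' @param standardize standardize the response before sampling (default
#'   `TRUE`).
#' @param zero_policy,zero_frac zero-replacement policy passed to
#'   [log_relative_abundance()].
#' @return a `bracod_trace`: retained post-burn-in draws of all model
#'   quantities plus sampler diagnostics. Summarize with
#'   [summarize_trace()] / [tidy()], inspect with [glance()].
#' @examples
#' sim <- make_dataset(simulation_config(n_samples = 40, n_contributors = 2,
#'                                       n_noncontributors = 8, seed = 1))
#' ct <- community_table(sim$counts)
#' fit <- run_chain(ct, sim$response,
#'                  config = sampler_config(n_burn = 200, n_draws = 200))
#' summarize_trace(fit)
#' @export
run_chain <- function(table, response, priors = prior_config(),
                      config = sampler_config(), standardize = TRUE,
                      zero_policy = "multiplicative", zero_frac = 0.5) {
  table <- as_community_table(table)
  y <- align_response(table, response)
  rel <- relative_abundance(table, zero_policy = zero_policy,
                            zero_frac = zero_frac)
  logC <- log(rel)
  ssvs_fit(y, logC, priors, config, standardize = standardize,
           marginalize_total = TRUE,
           mean_rel_abundance = colMeans(rel), method = "bracod")
}

#' @exportS3Method base::print
print.bracod_trace <- function(x, ...) {
  cat(sprintf("<bracod_trace> method=%s, %d draws x %d taxa (burn-in %d, seed %d)\n",
              x$method, length(x$draws$alpha), length(x$taxon_ids),
              x$config$n_burn, x$config$seed))
  cat(sprintf("  acceptance: sigma %.2f, tau %.2f, beta %.2f, flips %.3f\n",
              x$diagnostics$accept_sigma, x$diagnostics$accept_tau,
              x$diagnostics$accept_beta, x$diagnostics$accept_flip))
  invisible(x)
}

#' Sensitivity of inclusion probabilities to the burn-in length
#'
#' Reruns the chain at several burn-in lengths and compares the per-taxon
#' inclusion probabilities against a long reference burn-in, returning a
#' tidy table suitable for a box plot of `p_hat_diff` by `n_burn`.
#'
#' @inheritParams run_chain
#' @param burn_values integer vector of burn-in lengths to test.
#' @param reference_burn burn-in of the reference run (warns, not errors, if
#'   shorter than `max(burn_values)`).
#' @param seed seed shared by all runs so that only the burn-in differs.
#' @param n_draws retained draws per run.
#' @return tibble with columns `n_burn`, `taxon_id`, `p_hat`, `p_hat_ref`,
#'   `p_hat_diff`.
#' @export
burn_in_sensitivity <- function(table, response, priors = prior_config(),
                                burn_values = c(1000, 5000, 10000),
                                reference_burn = 50000, seed = 1,
                                n_draws = 1000) {
  if (!length(burn_values)) abort("`burn_values` must be non-empty.")
  if (reference_burn < max(burn_values)) {
    warn("`reference_burn` is smaller than max(burn_values).")
  }
  ref <- run_chain(table, response, priors,
                   sampler_config(n_burn = reference_burn, n_draws = n_draws,
                                  seed = seed))
  p_ref <- colMeans(ref$draws$indicators)
  purrr::map_dfr(burn_values, function(b) {
    fit <- run_chain(table, response, priors,
                     sampler_config(n_burn = b, n_draws = n_draws,
                                    seed = seed))
    p_hat <- colMeans(fit$draws$indicators)
    tibble(n_burn = b, taxon_id = ref$taxon_ids, p_hat = unname(p_hat),
           p_hat_ref = unname(p_ref), p_hat_diff = unname(p_hat - p_ref))
  })
}
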