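#' Prior configuration for the spike-and-slab regression
#'
#' Collects the hyperparameters of the model. Each taxon's regression
#' coefficient is a two-component mixture: with prior probability
#' `inclusion_prob_prior` it is drawn from the wide "slab"
#' `Normal(0, g * tau^2)`, otherwise from the narrow "spike"
#' `Normal(0, tau^2)`, where `tau ~ HalfNormal(0, 1)`. The unobserved
#' per-sample log total abundance is integrated out against
#' `Normal(total_mu_t, total_sigma2_t)`.
#'
#' @param inclusion_prob_prior prior inclusion probability of each taxon
#'   (Bernoulli prior on the indicators), default 0.25.
#' @param slab_multiplier_g ratio of slab to spike variance, default 500.
#' @param total_mu_t,total_sigma2_t mean and variance of the latent
#'   log total abundance (natural-log scale). Results depend on them only
#'   through the coefficient sum; defaults 0 and 1.
#' @param intercept_prior_sd standard deviation of the Normal prior on the
#'   intercept (on the standardized-response scale), default 10.
#' @param noise_prior_scale scale of the HalfNormal prior on the residual
#'   standard deviation, default 1.
#' @return a list of class `prior_config`.
#' @export
prior_config <- function(inclusion_prob_prior = 0.25,
                         slab_multiplier_g = 500,
                         total_mu_t = 0,
                         total_sigma2_t = 1,
                         intercept_prior_sd = 10,
                         noise_prior_scale = 1) {
  if (inclusion_prob_prior <= 0 || inclusion_prob_prior >= 1) {
    abort("`inclusion_prob_prior` must lie strictly in (0, 1).")
  }
  for (nm in c("slab_multiplier_g", "total_sigma2_t", "intercept_prior_sd",
               "noise_prior_scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single strictly positive number.", nm))
    }
  }
  structure(list(inclusion_prob_prior = inclusion_prob_prior,
                 slab_multiplier_g = slab_multiplier_g,
                 total_mu_t = total_mu_t,
                 total_sigma2_t = total_sigma2_t,
                 intercept_prior_sd = intercept_prior_sd,
                 noise_prior_scale = noise_prior_scale),
            class = "prior_config")
}

#' One MCMC state of the model
#'
#' Mostly used internally and in tests; [run_chain()] produces a whole trace
#' of these. `beta_included` holds the slab draw and `beta_excluded` the
#' spike draw for every taxon; the binary `p_indicator` selects which one
#' enters the regression (see [effective_coefficients()]).
#'
#' @param alpha intercept.
#' @param sigma2 residual variance (> 0).
#' @param tau2 spike variance (> 0).
#' @param beta_included,beta_excluded numeric vectors, one entry per taxon.
#' @param p_indicator binary (0/1) vector, one entry per taxon.
#' @return a list of class `model_state`.
#' @export
model_state <- function(alpha, sigma2, tau2, beta_included, beta_excluded,
                        p_indicator) {
  p <- length(beta_included)
  if (length(beta_excluded) != p) {
    abort("`beta_excluded` length does not match `beta_included`.")
  }
  if (length(p_indicator) != p) {
    abort("`p_indicator` length does not match `beta_included`.")
  }
  if (!all(p_indicator %in% c(0, 1))) {
    abort("`p_indicator` must be a binary (0/1) vector.")
  }
  structure(list(alpha = alpha, sigma2 = sigma2, tau2 = tau2,
                 beta_included = as.numeric(beta_included),
                 beta_excluded = as.numeric(beta_excluded),
                 p_indicator = as.numeric(p_indicator)),
            class = "model_state")
}

#' Effective regression coefficients of a state
#'
#' The coefficient that actually enters the likelihood is the elementwise
#' mixture `beta = p * beta_included + (1 - p) * beta_excluded`.
#'
#' @param state a [model_state()].
#' @return numeric vector of per-taxon coefficients.
#' @export
effective_coefficients <- function(state) {
  p <- state$p_indicator
  state$beta_included * p + state$beta_excluded * (1 - p)
}

#' Log marginal likelihood with the total abundance integrated out
#'
#' The outcome of sample i is modelled as linear in the log *absolute*
#' abundances, `y_i = alpha + beta' log x_i + eps_i`, with
#' `log x_ij = log c_ij + log T_i` for relative abundances `c_ij` and an
#' unobserved total `T_i`. Integrating `log T_i ~ Normal(mu_t, sigma2_t)`
#' out analytically gives an independent Gaussian likelihood per sample:
#' mean `alpha + beta' log c_i + sum(beta) * mu_t` and variance
#' `sigma2 + sum(beta)^2 * sigma2_t`. When `sum(beta) = 0` the total drops
#' out and the function reduces to a plain Gaussian regression on log
#' relative abundances.
#'
#' @param y numeric response vector (length n).
#' @param logC n x p matrix of log relative abundances (zero-replaced; all
#'   entries must be finite).
#' @param alpha intercept.
#' @param beta numeric coefficient vector (length p).
#' @param sigma2 residual variance (> 0).
#' @param mu_t,sigma2_t prior mean / variance of the latent log total
#'   abundance (`sigma2_t > 0`).
#' @return the scalar log likelihood summed over samples.
#' @examples
#' lml <- log_marginal_likelihood(1, matrix(log(c(0.5, 0.5)), 1), 0, c(1, 1),
#'                                1, 0, 1)
#' round(lml, 4) # -2.2931
#' @export
log_marginal_likelihood <- function(y, logC, alpha, beta, sigma2,
                                    mu_t = 0, sigma2_t = 1) {
  logC <- as.matrix(logC)
  y <- as.numeric(y)
  if (length(y) != nrow(logC)) abort("`y` length must equal `nrow(logC)`.")
  if (length(beta) != ncol(logC)) abort("`beta` length must equal `ncol(logC)`.")
  if (!is.finite(sigma2) || sigma2 <= 0) abort("`sigma2` must be > 0.")
  if (!is.finite(sigma2_t) || sigma2_t <= 0) abort("`sigma2_t` must be > 0.")
  if (any(!is.finite(logC))) {
    abort(paste("`logC` has non-finite entries; replace zero relative",
                "abundances before taking logs (see `relative_abundance()`)."))
  }
  s <- sum(beta)
  mu <- alpha + drop(logC %*% beta) + s * mu_t
  v <- sigma2 + s^2 * sigma2_t
  sum(dnorm(y, mean = mu, sd = sqrt(v), log = TRUE))
}

# log density of HalfNormal(0, scale) evaluated at x >= 0
log_half_normal <- function(x, scale = 1) {
  ifelse(x < 0, -Inf,
         0.5 * log(2 / pi) - log(scale) - x^2 / (2 * scale^2))
}

#' Log prior density of a model state
#'
#' Sums the log prior terms: HalfNormal(0, 1) on `tau = sqrt(tau2)`,
#' Normal spike/slab densities on the two coefficient vectors, Bernoulli
#' terms on the indicators, a Normal prior on the intercept and a
#' HalfNormal prior on the residual standard deviation. States outside the
#' support (`tau2 <= 0` or `sigma2 <= 0`) get `-Inf` with a warning.
#'
#' @param state a [model_state()].
#' @param priors a [prior_config()].
#' @return scalar log prior density (may be `-Inf`).
#' @export
log_prior <- function(state, priors = prior_config()) {
  stopifnot(inherits(state, "model_state"))
  if (!is.finite(state$tau2) || state$tau2 <= 0 ||
      !is.finite(state$sigma2) || state$sigma2 <= 0) {
    warn("state outside prior support (tau2 or sigma2 <= 0); returning -Inf.")
    return(-Inf)
  }
  tau <- sqrt(state$tau2)
  pi0 <- priors$inclusion_prob_prior
  lp <- log_half_normal(tau, 1) +
    dnorm(state$alpha, 0, priors$intercept_prior_sd, log = TRUE) +
    log_half_normal(sqrt(state$sigma2), priors$noise_prior_scale) +
    sum(dnorm(state$beta_included, 0,
              sqrt(priors$slab_multiplier_g) * tau, log = TRUE)) +
    sum(dnorm(state$beta_excluded, 0, tau, log = TRUE)) +
    sum(state$p_indicator * log(pi0) + (1 - state$p_indicator) * log(1 - pi0))
  lp
}

#' Log posterior density (up to a constant) of a model state
#'
#' `log_marginal_likelihood()` plus [log_prior()]; the quantity whose
#' differences drive every Metropolis acceptance ratio in the sampler.
#'
#' @inheritParams log_prior
#' @param y numeric response vector.
#' @param logC matrix of log relative abundances.
#' @return scalar log posterior density.
#' @export
log_posterior <- function(state, y, logC, priors = prior_config()) {
  lp <- log_prior(state, priors)
  if (!is.finite(lp)) return(lp)
  lp + log_marginal_likelihood(y, logC, state$alpha,
                               effective_coefficients(state), state$sigma2,
                               priors$total_mu_t, priors$total_sigma2_t)
}
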