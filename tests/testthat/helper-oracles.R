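# Independent numerical oracles used across the suite.

# Marginal likelihood by adaptive 1-D quadrature over the latent log total,
# per sample, with integration bounds centered on the integrand's peak.
quadrature_lml <- function(y, logC, alpha, beta, sigma2, mu_t, sigma2_t) {
  S <- sum(beta)
  sum(vapply(seq_along(y), function(i) {
    m0 <- alpha + sum(logC[i, ] * beta)
    prec <- 1 / sigma2_t + S^2 / sigma2
    tc <- (mu_t / sigma2_t + S * (y[i] - m0) / sigma2) / prec
    hw <- 12 / sqrt(prec)
    f <- function(t) {
      dnorm(y[i], m0 + S * t, sqrt(sigma2)) * dnorm(t, mu_t, sqrt(sigma2_t))
    }
    log(integrate(f, tc - hw, tc + hw, rel.tol = 1e-12, abs.tol = 0)$value)
  }, numeric(1)))
}

# Exact posterior inclusion probabilities for a 2-taxon problem:
# enumeration over the 4 indicator configurations with semi-analytic
# integration of the continuous parameters -- (intercept, coefficient
# difference) in closed form as a linear-Gaussian model, (coefficient sum,
# sigma, tau) numerically on fine grids. Shares nothing with the sampler
# beyond the model definition.
enumerated_inclusion2 <- function(y, logC, priors, ns_grid = 300,
                                  n_sg = 60, n_tau = 60) {
  g <- priors$slab_multiplier_g
  pi0 <- priors$inclusion_prob_prior
  mu_t <- priors$total_mu_t
  s2t <- priors$total_sigma2_t
  sa2 <- priors$intercept_prior_sd^2
  n <- length(y)
  l1 <- logC[, 1]; l2 <- logC[, 2]
  u <- (l1 + l2) / 2 + mu_t
  w <- (l1 - l2) / 2
  sg_grid <- exp(seq(log(0.03), log(4), length.out = n_sg))
  tau_grid <- exp(seq(log(5e-4), log(4), length.out = n_tau))
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  log_evid <- function(z1, z2) {
    v1 <- if (z1) g else 1
    v2 <- if (z2) g else 1
    terms <- c()
    for (sg in sg_grid) for (tau in tau_grid) {
      t2 <- tau^2
      vs <- (v1 + v2) * t2
      mu_d_s <- (v1 - v2) / (v1 + v2)
      var_d <- 4 * v1 * v2 / (v1 + v2) * t2
      sw <- 6 * sqrt(vs)
      s_seq <- seq(min(-sw, -3), max(sw, 3), length.out = ns_grid)
      ds <- s_seq[2] - s_seq[1]
      inner <- vapply(s_seq, function(s) {
        v <- sg^2 + s^2 * s2t
        yr <- y - s * u
        m0 <- c(0, mu_d_s * s)
        V0d <- c(sa2, var_d)
        MtM <- matrix(c(n, sum(w), sum(w), sum(w^2)), 2)
        A <- MtM / v + diag(1 / V0d)
        h <- c(sum(yr), sum(w * yr)) / v + m0 / V0d
        cc <- sum(yr^2) / v + sum(m0^2 / V0d)
        -n / 2 * log(2 * pi * v) - 0.5 * sum(log(V0d)) - 0.5 * cc -
          0.5 * as.numeric(determinant(A)$modulus) +
          0.5 * sum(h * solve(A, h)) +
          dnorm(s, 0, sqrt(vs), log = TRUE)
      }, numeric(1))
      pri <- log_halfnorm(sg, priors$noise_prior_scale) + log(sg) +
        log_halfnorm(tau, 1) + log(tau)
      terms <- c(terms, lse(inner) + log(ds) + pri)
    }
    lse(terms) + log(diff(log(sg_grid))[1]) + log(diff(log(tau_grid))[1]) +
      (z1 + z2) * log(pi0) + (2 - z1 - z2) * log(1 - pi0)
  }
  le <- c(log_evid(0, 0), log_evid(1, 0), log_evid(0, 1), log_evid(1, 1))
  pr <- exp(le - max(le)); pr <- pr / sum(pr)
  c(p1 = pr[2] + pr[4], p2 = pr[3] + pr[4])
}

log_halfnorm <- function(x, scale) {
  0.5 * log(2 / pi) - log(scale) - x^2 / (2 * scale^2)
}

# small deterministic two-taxon regression problem with signal on taxon 1
toy_two_taxon <- function(n = 30, beta1 = 0.9, noise_sd = 0.5, seed = 42) {
  set.seed(seed)
  c1 <- runif(n, 0.2, 0.8)
  C <- cbind(t1 = c1, t2 = 1 - c1)
  y <- 0.3 + beta1 * log(C[, 1]) + rnorm(n, 0, noise_sd)
  list(C = C, logC = log(C), y = (y - mean(y)) / sd(y))
}
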