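test_that("effective coefficients follow the indicator mixture", {
  st <- model_state(alpha = 0, sigma2 = 1, tau2 = 0.25,
                    beta_included = c(2.0, 9.9),
                    beta_excluded = c(0.01, -0.02),
                    p_indicator = c(1, 0))
  expect_equal(effective_coefficients(st), c(2.0, -0.02))
  st$p_indicator <- c(0, 0)
  expect_equal(effective_coefficients(st), st$beta_excluded)
  st$p_indicator <- c(1, 1)
  expect_equal(effective_coefficients(st), st$beta_included)
  expect_error(model_state(0, 1, 1, c(1, 2), c(1), c(1, 0)), "length")
  expect_error(model_state(0, 1, 1, c(1, 2), c(1, 2), c(1, 2)), "binary")
})

test_that("marginal likelihood matches its closed-form special cases", {
  set.seed(11)
  n <- 6; p <- 4
  C <- matrix(rgamma(n * p, 1), n); C <- C / rowSums(C)
  logC <- log(C)
  y <- rnorm(n)
  # beta = 0: no abundance dependence remains
  expect_equal(log_marginal_likelihood(y, logC, 0.3, rep(0, p), 1.3, 2, 5),
               sum(dnorm(y, 0.3, sqrt(1.3), log = TRUE)))
  # sum(beta) = 0: the total-abundance term cancels entirely
  beta0 <- c(0.7, -0.7, 1.1, -1.1)
  base <- log_marginal_likelihood(y, logC, 0.1, beta0, 0.8, 0, 1)
  for (mu_t in c(-3, 2)) for (s2t in c(0.01, 9)) {
    expect_equal(log_marginal_likelihood(y, logC, 0.1, beta0, 0.8, mu_t, s2t),
                 base, tolerance = 1e-12)
  }
  expect_equal(base, sum(dnorm(y, 0.1 + drop(logC %*% beta0), sqrt(0.8),
                               log = TRUE)))
  # frozen single-sample value, cross-checked against quadrature
  expect_equal(log_marginal_likelihood(1, matrix(log(c(0.5, 0.5)), 1), 0,
                                       c(1, 1), 1, 0, 1),
               -2.2931, tolerance = 1e-4)
  expect_error(log_marginal_likelihood(y, logC, 0, rep(0.1, p), -1, 0, 1),
               "sigma2")
  expect_error(log_marginal_likelihood(y, log(C * (C > 0.2)), 0,
                                       rep(0.1, p), 1, 0, 1), "zero")
})

test_that("marginal likelihood agrees with 1-D quadrature on random draws", {
  set.seed(7)
  worst <- 0
  for (r in 1:50) {
    n <- 5; p <- 3
    C <- matrix(rgamma(n * p, 1), n); C <- C / rowSums(C)
    logC <- log(C)
    alpha <- rnorm(1); beta <- rnorm(p, 0, 1.5)
    sigma2 <- runif(1, 0.2, 2); mu_t <- rnorm(1); s2t <- runif(1, 0.2, 2)
    y <- rnorm(n, 0, 2)
    a <- log_marginal_likelihood(y, logC, alpha, beta, sigma2, mu_t, s2t)
    b <- quadrature_lml(y, logC, alpha, beta, sigma2, mu_t, s2t)
    worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-6)
})

test_that("marginal likelihood converges to the fixed-total limit and is closure-invariant", {
  set.seed(3)
  n <- 5; p <- 3
  C <- matrix(rgamma(n * p, 1), n); C <- C / rowSums(C)
  y <- rnorm(n); beta <- rnorm(p); mu_t <- 0.4
  fixed <- sum(dnorm(y, 0.2 + drop(log(C) %*% beta) + sum(beta) * mu_t,
                     sqrt(0.9), log = TRUE))
  expect_equal(log_marginal_likelihood(y, log(C), 0.2, beta, 0.9, mu_t, 1e-12),
               fixed, tolerance = 1e-8)
  # per-sample rescaling before closure leaves the likelihood unchanged
  k <- runif(n, 0.1, 10)
  C2 <- C * k; C2 <- C2 / rowSums(C2)
  expect_equal(log_marginal_likelihood(y, log(C2), 0.2, beta, 0.9, mu_t, 1.3),
               log_marginal_likelihood(y, log(C), 0.2, beta, 0.9, mu_t, 1.3),
               tolerance = 1e-9)
})

test_that("log prior components behave as specified", {
  pri <- prior_config()
  base <- model_state(alpha = 0.1, sigma2 = 0.8, tau2 = 0.09,
                      beta_included = c(0.5, -0.2),
                      beta_excluded = c(0.01, 0.02),
                      p_indicator = c(0, 0))
  flipped <- base; flipped$p_indicator <- c(1, 0)
  expect_equal(log_prior(flipped, pri) - log_prior(base, pri),
               log(0.25 / 0.75))
  # identical value v under slab vs spike: density ratios in closed form
  g <- pri$slab_multiplier_g; tau2 <- base$tau2; v <- 0.37
  zero <- base; zero$beta_included <- c(0, 0); zero$beta_excluded <- c(0, 0)
  s_slab <- zero; s_slab$beta_included[1] <- v
  s_spike <- zero; s_spike$beta_excluded[1] <- v
  d_slab <- log_prior(s_slab, pri) - log_prior(zero, pri)
  d_spike <- log_prior(s_spike, pri) - log_prior(zero, pri)
  # moving v from the spike to the slab costs 1/2 log(g) at v = 0 and
  # regains v^2/(2 tau^2) (1 - 1/g) of exponent
  expect_equal(d_spike - d_slab, -v^2 / (2 * tau2) * (1 - 1 / g),
               tolerance = 1e-10)
  # holding v in the slab instead of the spike costs half a log-variance
  # ratio at the origin
  at0 <- log(dnorm(0, 0, sqrt(tau2))) - log(dnorm(0, 0, sqrt(g * tau2)))
  expect_equal(at0, 0.5 * log(g), tolerance = 1e-10)
  # HalfNormal term decreases monotonically in tau
  lp <- vapply(c(0.5, 1.5, 3), function(tau) {
    st <- base; st$tau2 <- tau^2
    log_prior(st, pri)
  }, numeric(1))
  expect_true(all(diff(lp) < 0))
  st_bad <- base; st_bad$sigma2 <- -1
  expect_warning(expect_identical(log_prior(st_bad, pri), -Inf), "support")
})
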