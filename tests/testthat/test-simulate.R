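test_that("lognormal parameter estimation filters and recovers", {
  # constant-composition taxon has zero log abundance spread
  m <- matrix(c(5, 10, 20, 5, 10, 20, 10, 20, 40), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  est <- estimate_lognormal_params(community_table(m), abundance_floor = 0)
  expect_equal(unname(est$log_sigma), rep(0, 3), tolerance = 1e-12)

  # taxa at mean relative abundance below the floor are dropped
  m2 <- cbind(major1 = c(600, 500, 550), major2 = c(390, 490, 440),
              minor = c(0.5, 0.6, 0.4))
  rownames(m2) <- paste0("s", 1:3)
  est2 <- estimate_lognormal_params(community_table(m2, is_counts = FALSE),
                                    abundance_floor = 0.001)
  expect_false("minor" %in% est2$kept_taxa)
  expect_error(estimate_lognormal_params(community_table(m2), 0.9), "fewer")

  # parameters of a known lognormal composition are recovered at large n;
  # with many taxa the per-sample total is nearly constant, so log relative
  # abundances carry the absolute-scale parameters up to a shared offset
  set.seed(21)
  n <- 4000; p <- 30
  mu <- c(-3, rep(0, p - 1))
  lx <- sapply(mu, function(m) rnorm(n, m, 0.5))
  ct <- community_table(exp(lx), is_counts = FALSE)
  est3 <- estimate_lognormal_params(ct, abundance_floor = 0)
  expect_equal(unname(est3$log_mu[2] - est3$log_mu[1]), 3, tolerance = 0.1)
  expect_equal(unname(est3$log_sigma[1]), 0.5, tolerance = 0.05)
})

test_that("simulated abundances honour the correlation structure and seed", {
  cfg0 <- simulation_config(n_samples = 5000, n_contributors = 2,
                            n_noncontributors = 3, seed = 5)
  x <- simulate_abundances(cfg0)
  lr <- cor(log(x))
  off <- abs(lr[upper.tri(lr)])
  expect_lt(max(off), 0.05)

  cfgc <- simulation_config(n_samples = 5000, n_contributors = 2,
                            n_noncontributors = 3, n_correlated = 1,
                            rho = 0.7, seed = 5)
  xc <- simulate_abundances(cfgc)
  lrc <- cor(log(xc))
  expect_equal(lrc["contrib_01", "null_001"], 0.7, tolerance = 0.03)

  expect_identical(simulate_abundances(cfg0), simulate_abundances(cfg0))
})

test_that("simulated responses follow the contributor model", {
  cfg <- simulation_config(n_samples = 5000, n_contributors = 0,
                           n_noncontributors = 5, seed = 9,
                           noise_floor = 1)
  x <- simulate_abundances(cfg)
  r0 <- simulate_response(x, cfg)
  expect_true(all(r0$true_beta == 0))
  expect_lt(max(abs(cor(log(x), r0$response))), 0.05)

  cfg2 <- simulation_config(n_samples = 200, n_contributors = 3,
                            n_noncontributors = 2, seed = 9,
                            noise_frac = 0, noise_floor = 1e-30)
  x2 <- simulate_abundances(cfg2)
  r2 <- simulate_response(x2, cfg2)
  expect_lt(max(abs(r2$response - drop(log(x2) %*% r2$true_beta))), 1e-8)
  expect_identical(r2$contributor_mask, as.integer(r2$true_beta != 0))

  # mean |Uniform(-5, 5)| = 2.5
  set.seed(1)
  draws <- replicate(500, {
    cfg3 <- simulation_config(n_samples = 3, n_contributors = 20,
                              n_noncontributors = 2,
                              seed = sample.int(1e6, 1))
    x3 <- simulate_abundances(cfg3)
    mean(abs(simulate_response(x3, cfg3)$true_beta[1:20]))
  })
  expect_equal(mean(draws), 2.5, tolerance = 0.1)
})

test_that("multinomial counts close exactly and converge to the composition", {
  set.seed(2)
  x <- exp(matrix(rnorm(40), 10, 4))
  set.seed(3)
  cnt <- simulate_counts(x, n_reads = 1e6)
  expect_true(all(rowSums(cnt$counts) == 1e6))
  expect_equal(unname(rowSums(cnt$rel_abundance)), rep(1, 10),
               tolerance = 1e-12)
  expect_lt(max(abs(cnt$counts / 1e6 - cnt$rel_abundance)), 2e-3)

  one <- matrix(2, 3, 1, dimnames = list(NULL, "only"))
  expect_equal(unname(simulate_counts(one, 500)$counts[, 1]), rep(500, 3))
  set.seed(4); a <- simulate_counts(x, 1000)
  set.seed(4); b <- simulate_counts(x, 1000)
  expect_identical(a, b)
})

test_that("make_dataset composes the generators with consistent bookkeeping", {
  sim <- make_dataset(simulation_config(seed = 1))
  expect_equal(dim(sim$counts), c(119, 120))
  expect_equal(sum(sim$contributor_mask), 20)
  expect_equal(sum(sim$correlated_mask), 0)
  expect_identical(sim$contributor_mask, as.integer(sim$true_beta != 0))
  expect_true(all(rowSums(sim$counts) == sim$config$n_reads))
  expect_equal(unname(rowSums(sim$rel_abundance)), rep(1, 119),
               tolerance = 1e-9)

  simc <- make_dataset(simulation_config(n_correlated = 20, seed = 2))
  expect_equal(sum(simc$correlated_mask), 20)
  expect_true(all(simc$contributor_mask[simc$correlated_mask == 1] == 0))

  sim2 <- make_dataset(simulation_config(seed = 3))
  expect_false(identical(sim$counts, sim2$counts))
  expect_equal(sum(sim2$contributor_mask), sum(sim$contributor_mask))
})

test_that("simulated communities mirror the empirical source table", {
  # estimate parameters from one simulated table, re-simulate, and compare
  # per-taxon mean abundance and coefficient of variation
  src <- make_dataset(simulation_config(seed = 6))
  est <- estimate_lognormal_params(community_table(src$counts),
                                   abundance_floor = 0)
  cfg <- simulation_config(n_samples = 119,
                           n_contributors = 20, n_noncontributors = 100,
                           log_mu = unname(est$log_mu),
                           log_sigma = unname(est$log_sigma), seed = 7)
  rep_ <- make_dataset(cfg)
  mean_src <- colMeans(src$rel_abundance)
  mean_rep <- colMeans(rep_$rel_abundance)
  cv <- function(m) apply(m, 2, sd) / colMeans(m)
  expect_gt(cor(mean_src, mean_rep, method = "spearman"), 0.9)
  expect_gt(cor(cv(src$rel_abundance), cv(rep_$rel_abundance),
                method = "spearman"), 0.5)
})
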