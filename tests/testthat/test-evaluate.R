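test_that("confusion metrics evaluate the four rates exactly", {
  truth <- setNames(rep(c(1, 0), c(20, 100)), paste0("t", 1:120))
  perfect <- confusion_metrics(names(truth)[truth == 1], truth)
  expect_equal(perfect[, c("TPR", "FPR", "precision", "accuracy")],
               tibble::tibble(TPR = 1, FPR = 0, precision = 1, accuracy = 1))
  # P = 20, N = 100, TP = 14, FP = 5
  sel <- c(names(truth)[1:14], names(truth)[21:25])
  m <- confusion_metrics(sel, truth)
  expect_equal(m$TPR, 0.70)
  expect_equal(m$FPR, 0.05)
  expect_equal(m$precision, 14 / 19)
  expect_equal(m$accuracy, 109 / 120)
  empty <- confusion_metrics(character(0), truth)
  expect_equal(empty$TPR, 0)
  expect_equal(empty$FPR, 0)
  expect_equal(empty$precision, 0)
  expect_equal(empty$accuracy, 100 / 120)
  expect_error(confusion_metrics("nope", truth), "outside")
})

test_that("ROC curves and AUC behave at the extremes and under permutation", {
  truth <- rep(c(1, 0), c(10, 30))
  ordered <- c(seq(0.9, 0.8, length.out = 10), seq(0.4, 0.1, length.out = 30))
  expect_equal(roc_auc(roc_from_scores(ordered, truth)), 1)
  expect_equal(roc_auc(roc_from_scores(-ordered, truth)), 0)
  set.seed(8)
  null_auc <- replicate(400, roc_auc(roc_from_scores(sample(ordered), truth)))
  expect_equal(mean(null_auc), 0.5, tolerance = 0.02)
  expect_warning(roc_from_scores(rep(0.5, 40), truth), "single point")
})

test_that("clr transform centres each sample's log composition", {
  expect_equal(unname(clr_transform(matrix(0.25, 2, 4))),
               matrix(0, 2, 4))
  two <- clr_transform(matrix(c(0.2, 0.8), 1))
  expect_equal(unname(drop(two)), c(log(0.5), log(2)), tolerance = 1e-12)
  set.seed(5)
  m <- matrix(rgamma(60, 1), 6)
  expect_lt(max(abs(rowSums(clr_transform(m)))), 1e-9)
})

test_that("clr-LASSO shrinks to empty and relaxes to OLS", {
  set.seed(10)
  n <- 200; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("t", 1:p)))
  y <- drop(X %*% c(2, -1, 0, 0)) + rnorm(n, 0, 0.5)
  f <- fit_clr_lasso(X, y, cv_folds = 5, seed = 1)
  expect_true(all(c("t1", "t2") %in% f$selected))
  # lambda -> large: nothing selected
  cf_big <- coef(f$cv_fit$glmnet.fit, s = max(f$cv_fit$lambda) * 100)[-1, 1]
  expect_true(all(cf_big == 0))
  # lambda -> 0: matches ordinary least squares
  cf0 <- coef(f$cv_fit$glmnet.fit, s = 0, exact = TRUE, x = X, y = y)[-1, 1]
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(cf0), unname(ols), tolerance = 1e-4)
  expect_error(fit_clr_lasso(X, rep(1, n)), "zero variance")
})

test_that("clr-SS selects strong contributors on clr predictors", {
  set.seed(12)
  sim <- make_dataset(simulation_config(n_samples = 150, n_contributors = 2,
                                        n_noncontributors = 18, seed = 12))
  clr <- clr_transform(community_table(sim$counts))
  f <- fit_clr_ss(clr, sim$response,
                  config = sampler_config(n_burn = 1000, n_draws = 1000,
                                          seed = 3))
  expect_s3_class(f$summary, "inclusion_summary")
  expect_true(all(f$summary$p_hat >= 0 & f$summary$p_hat <= 1))
  # the strongest true contributor should outrank the bulk of the nulls
  strongest <- names(which.max(abs(sim$true_beta)))
  expect_gt(f$summary$p_hat[f$summary$taxon_id == strongest],
            median(f$summary$p_hat))
})

test_that("performance sweep returns tidy mean/sd metrics", {
  sw <- performance_sweep("n_samples", grid = c(60, 90), n_sims = 2,
                          methods = "clr_lasso",
                          base_config = simulation_config(
                            n_contributors = 5, n_noncontributors = 15),
                          seed = 4)
  expect_setequal(unique(sw$metric), c("TPR", "FPR", "precision", "accuracy"))
  expect_equal(nrow(sw), 2 * 4)
  expect_true(all(is.finite(sw$mean)))
  sw1 <- performance_sweep("n_contributors", grid = 5, n_sims = 1,
                           methods = "clr_lasso",
                           base_config = simulation_config(
                             n_samples = 60, n_noncontributors = 15),
                           seed = 4)
  expect_true(all(is.na(sw1$sd)))
})

test_that("correlated non-contributors are tracked across correlation strengths", {
  cd <- correlated_discrimination_experiment(
    rhos = c(0.1, 0.7), n_sims = 3, methods = "bracod",
    base_config = simulation_config(n_contributors = 5,
                                    n_noncontributors = 25,
                                    n_correlated = 5, n_samples = 60),
    sampler = sampler_config(n_burn = 1000, n_draws = 1000), seed = 6)
  expect_named(cd, c("method", "rho", "n_sims", "flag_rate",
                     "corr_taxon_rate", "plain_taxon_rate"))
  expect_true(all(cd$flag_rate >= 0 & cd$flag_rate <= 1))
  expect_equal(cd$n_sims, c(3L, 3L))
  # confusion with correlated partners should not shrink as rho grows
  expect_gte(cd$corr_taxon_rate[cd$rho == 0.7] + 0.1,
             cd$corr_taxon_rate[cd$rho == 0.1])
  expect_error(correlated_discrimination_experiment(
    base_config = simulation_config()), "correlated")
})
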