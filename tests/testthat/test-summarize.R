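make_fake_trace <- function(ind, bi, taxa = colnames(ind)) {
  nd <- nrow(ind)
  structure(list(draws = list(alpha = rnorm(nd), sigma2 = rep(1, nd),
                              tau2 = rep(0.01, nd),
                              beta_included = bi,
                              beta_excluded = matrix(0, nd, ncol(ind)),
                              indicators = ind),
                 taxon_ids = taxa,
                 mean_rel_abundance = rep(1 / ncol(ind), ncol(ind)),
                 y_center = 0, y_scale = 1, standardized = FALSE,
                 priors = prior_config(), config = sampler_config(),
                 method = "bracod",
                 diagnostics = list(accept_flip = 0.1)),
            class = "bracod_trace")
}

test_that("summarize_trace averages indicators and slab draws", {
  ind <- cbind(a = c(1, 1, 0, 1), b = c(0, 0, 0, 0))
  bi <- cbind(a = c(1, 2, 3, 2), b = c(0.1, -0.1, 0.2, -0.2))
  s <- summarize_trace(make_fake_trace(ind, bi), cutoff = 0.3)
  expect_equal(s$p_hat[s$taxon_id == "a"], 0.75)
  expect_equal(s$beta_hat_included[s$taxon_id == "a"], 2)
  expect_equal(s$p_hat[s$taxon_id == "b"], 0)
  expect_identical(selected_taxa(s), "a")
  # conditional estimator averages only included draws
  sc <- summarize_trace(make_fake_trace(ind, bi), conditional = TRUE)
  expect_equal(sc$beta_hat_included[sc$taxon_id == "a"], mean(c(1, 2, 2)))
  # cutoff 0 returns everything ranked by p_hat
  s0 <- summarize_trace(make_fake_trace(ind, bi), cutoff = 0)
  expect_true(all(s0$selected))
  expect_equal(s0$taxon_id, c("a", "b"))
  # degenerate all-zero trace selects nothing at any positive cutoff
  sz <- summarize_trace(make_fake_trace(ind * 0, bi), cutoff = 1e-9)
  expect_length(selected_taxa(sz), 0)
})

test_that("selection is monotone in the cutoff and invariant to draw order", {
  set.seed(14)
  ind <- matrix(rbinom(400, 1, runif(8, 0, 1)[col(matrix(0, 50, 8))]), 50, 8)
  colnames(ind) <- paste0("t", 1:8)
  bi <- matrix(rnorm(400), 50, 8, dimnames = list(NULL, colnames(ind)))
  tr <- make_fake_trace(ind, bi)
  sizes <- vapply(seq(0, 1, by = 0.1), function(ct) {
    sum(summarize_trace(tr, cutoff = ct)$selected)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  perm <- sample(50)
  tr2 <- make_fake_trace(ind[perm, ], bi[perm, ])
  expect_equal(summarize_trace(tr2)$p_hat, summarize_trace(tr)$p_hat)
})

test_that("scatter_summary carries the contributor flag at the active cutoff", {
  ind <- cbind(hi = rep(1, 10), lo = rep(0, 10))
  bi <- cbind(hi = rep(0.02, 10), lo = rep(0.3, 10))
  sc <- scatter_summary(summarize_trace(make_fake_trace(ind, bi),
                                        cutoff = 0.3))
  expect_equal(sc$contributor[sc$taxon_id == "hi"], TRUE)
  expect_equal(sc$contributor[sc$taxon_id == "lo"], FALSE)
  sc2 <- scatter_summary(summarize_trace(make_fake_trace(ind, bi),
                                         cutoff = 1.01))
  expect_false(any(sc2$contributor))
})

test_that("replicate concordance recovers identity and independence", {
  ind <- matrix(rbinom(300, 1, 0.4), 30, 10,
                dimnames = list(NULL, paste0("t", 1:10)))
  bi <- matrix(0, 30, 10, dimnames = dimnames(ind))
  s <- summarize_trace(make_fake_trace(ind, bi))
  cc <- replicate_concordance(s, s)
  expect_equal(cc$slope, 1)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$adj_r2, 1)
  set.seed(15)
  mk <- function() {
    i2 <- matrix(rbinom(6000, 1, runif(200)[col(matrix(0, 30, 200))]),
                 30, 200, dimnames = list(NULL, paste0("t", 1:200)))
    summarize_trace(make_fake_trace(i2, matrix(0, 30, 200,
                                               dimnames = dimnames(i2))))
  }
  cc2 <- replicate_concordance(mk(), mk())
  expect_lt(abs(cc2$adj_r2), 0.1)
  bad <- s; bad$taxon_id <- paste0("x", seq_len(nrow(bad)))
  expect_error(replicate_concordance(s, bad), "different taxa")
})

test_that("tidy and glance methods expose the headline summaries", {
  ind <- cbind(a = rep(1, 5), b = rep(0, 5))
  bi <- cbind(a = rep(0.5, 5), b = rep(0, 5))
  tr <- make_fake_trace(ind, bi)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("taxon_id", "p_hat", "beta_hat_included", "beta_sd",
                     "mean_rel_abundance", "selected"))
  gl <- glance(tr)
  expect_equal(gl$n_taxa, 2)
  expect_equal(gl$n_selected, 1)
})

test_that("plot methods return ggplot objects", {
  ind <- cbind(a = rep(1, 5), b = rep(0, 5))
  bi <- cbind(a = rep(0.5, 5), b = rep(0, 5))
  tr <- make_fake_trace(ind, bi)
  expect_s3_class(autoplot(summarize_trace(tr)), "ggplot")
  expect_s3_class(plot_trace_scalars(tr), "ggplot")
  roc <- roc_from_scores(c(0.9, 0.1), c(1, 0))
  expect_s3_class(autoplot(roc), "ggplot")
  sw <- tibble::tibble(vary = "n_samples", value = c(10, 20), method = "m",
                       metric = "TPR", mean = c(0.5, 0.6), sd = c(0.1, 0.1))
  expect_s3_class(plot_performance_sweep(sw), "ggplot")
})
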