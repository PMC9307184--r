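#' Confusion metrics for a selection against ground truth
#'
#' Exact integer counting of true/false positives followed by the four
#' standard rates: `TPR = TP / P`, `FPR = FP / N`,
#' `precision = TP / (TP + FP)` (defined as 0 when nothing is selected) and
#' `accuracy = (TP + N - FP) / (P + N)`.
#'
#' @param selected selected taxa: a character vector of ids or a
#'   logical/0-1 mask over the candidate universe.
#' @param truth named binary contributor mask covering all candidate taxa
#'   (names are taxon ids), or an unnamed 0/1 vector when `selected` is a
#'   mask of the same length.
#' @return one-row tibble: `TP`, `FP`, `P`, `N`, `TPR`, `FPR`,
#'   `precision`, `accuracy`.
#' @examples
#' truth <- c(a = 1, b = 1, c = 0, d = 0)
#' confusion_metrics(c("a", "c"), truth)
#' @export
confusion_metrics <- function(selected, truth) {
  truth <- unlist(truth)
  if (!all(truth %in% c(0, 1))) abort("`truth` must be a binary mask.")
  if (is.character(selected)) {
    if (is.null(names(truth))) abort("`truth` must be named when `selected` is a character vector.")
    outside <- setdiff(selected, names(truth))
    if (length(outside)) {
      abort(paste0("selected taxa outside the candidate universe: ",
                   paste(outside, collapse = ", ")))
    }
    sel <- names(truth) %in% selected
  } else {
    if (length(selected) != length(truth)) {
      abort("`selected` mask length must match `truth`.")
    }
    sel <- as.logical(selected)
  }
  P <- sum(truth == 1); N <- sum(truth == 0)
  TP <- sum(sel & truth == 1); FP <- sum(sel & truth == 0)
  tibble(TP = TP, FP = FP, P = P, N = N,
         TPR = if (P > 0) TP / P else NA_real_,
         FPR = if (N > 0) FP / N else NA_real_,
         precision = if (TP + FP > 0) TP / (TP + FP) else 0,
         accuracy = if (P + N > 0) (TP + N - FP) / (P + N) else NA_real_)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' ROC curve from per-taxon scores or a LASSO selection path
#'
#' For inclusion-probability methods, sweeps a threshold over the scores;
#' for the LASSO comparator, sweeps the regularization strength with
#' selection = nonzero coefficients at each lambda (pass the logical
#' path matrix from [fit_clr_lasso()]).
#'
#' @param scores numeric per-taxon score vector (higher = more
#'   contributor-like), or a lambda x taxa logical matrix of per-lambda
#'   selections.
#' @param truth binary contributor mask aligned with the taxa.
#' @param method label stored on the result (`"bracod"`, `"clr_lasso"`,
#'   `"clr_ss"` or anything descriptive).
#' @return a tibble of class `roc_result` with columns `threshold`, `tpr`,
#'   `fpr` and attributes `auc` and `method`.
#' @export
roc_from_scores <- function(scores, truth, method = "scores") {
  truth <- unlist(truth)
  if (is.matrix(scores)) {
    if (ncol(scores) != length(truth)) {
      abort("path matrix column count must match `truth`.")
    }
    pts <- purrr::map_dfr(seq_len(nrow(scores)), function(k) {
      m <- confusion_metrics(as.logical(scores[k, ]), truth)
      tibble(threshold = k, tpr = m$TPR, fpr = m$FPR)
    })
  } else {
    if (length(scores) != length(truth)) {
      abort("`scores` length must match `truth`.")
    }
    if (any(!is.finite(scores))) abort("`scores` must be finite.")
    if (length(unique(scores)) == 1L) {
      warn("all scores identical; ROC degenerates to a single point.")
    }
    thr <- sort(unique(scores), decreasing = TRUE)
    pts <- purrr::map_dfr(thr, function(t) {
      m <- confusion_metrics(scores >= t, truth)
      tibble(threshold = t, tpr = m$TPR, fpr = m$FPR)
    })
  }
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  attr(pts, "auc") <- auc
  attr(pts, "method") <- method
  class(pts) <- c("roc_result", class(pts))
  pts
}

#' Area under a `roc_result`
#' @param roc a `roc_result`.
#' @return scalar AUC.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Centered log-ratio transform
#'
#' Per sample: `log(c_ij) - mean_j log(c_ij)` on zero-replaced closed
#' relative abundances; every row of the result sums to zero.
#'
#' @inheritParams relative_abundance
#' @return samples x taxa numeric matrix with zero row sums.
#' @export
clr_transform <- function(table, zero_policy = "multiplicative",
                          zero_frac = 0.5) {
  lc <- log_relative_abundance(table, zero_policy, zero_frac)
  sweep(lc, 1, rowMeans(lc), "-")
}

#' clr-LASSO comparator
#'
#' L1-penalized linear regression of the response on clr-transformed
#' abundances (predictors standardized inside glmnet), with the
#' regularization strength chosen by cross-validation. Selection = taxa
#' with nonzero coefficient at the CV-best lambda.
#'
#' @param clr_matrix samples x taxa matrix from [clr_transform()] (a
#'   `community_table` is accepted and transformed on the fly).
#' @param response numeric response vector.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed seed for the CV fold assignment.
#' @return list with `selected` (taxon ids), `coefficients` (tibble of
#'   nonzero coefficients at the best lambda), `lambda` (best lambda),
#'   `path_nonzero` (lambda x taxa logical matrix for ROC sweeps) and the
#'   underlying `cv_fit`.
#' @export
fit_clr_lasso <- function(clr_matrix, response, cv_folds = 5, seed = 1) {
  if (inherits(clr_matrix, "community_table")) {
    clr_matrix <- clr_transform(clr_matrix)
  }
  y <- as.numeric(response)
  if (sd(y) == 0) abort("response has zero variance.")
  if (nrow(clr_matrix) != length(y)) abort("sizes of predictors and response differ.")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(clr_matrix, y, alpha = 1, nfolds = cv_folds,
                          standardize = TRUE)
  cf <- coef(cv, s = "lambda.min")[-1, 1] # drop intercept
  selected <- names(cf)[cf != 0]
  path <- cv$glmnet.fit
  nz <- t(as.matrix(path$beta) != 0) # lambda x taxa
  colnames(nz) <- rownames(path$beta)
  list(selected = selected,
       coefficients = tibble(taxon_id = names(cf)[cf != 0],
                             coefficient = unname(cf[cf != 0])),
       lambda = cv$lambda.min,
       path_nonzero = nz,
       cv_fit = cv)
}

#' clr-SS comparator: spike-and-slab regression on clr predictors
#'
#' A standard Gaussian spike-and-slab linear model (no total-abundance
#' marginalization) fitted with the same SSVS sampler as the main model,
#' on column-standardized clr-transformed abundances. Contributors are
#' selected at the same inclusion-probability cut point.
#'
#' @inheritParams fit_clr_lasso
#' @param cutoff inclusion-probability cut point (default 0.3).
#' @param priors a [prior_config()] (total-abundance entries are unused).
#' @param config a [sampler_config()].
#' @return list with `selected`, `summary` (an `inclusion_summary`) and the
#'   full `trace`.
#' @export
fit_clr_ss <- function(clr_matrix, response, cutoff = 0.3,
                       priors = prior_config(), config = sampler_config()) {
  if (inherits(clr_matrix, "community_table")) {
    clr_matrix <- clr_transform(clr_matrix)
  }
  y <- as.numeric(response)
  sds <- apply(clr_matrix, 2, sd)
  sds[sds == 0] <- 1
  Xs <- sweep(clr_matrix, 2, sds, "/")
  trace <- ssvs_fit(y, Xs, priors, config, standardize = TRUE,
                    marginalize_total = FALSE, method = "clr_ss")
  smry <- summarize_trace(trace, cutoff = cutoff)
  list(selected = selected_taxa(smry), summary = smry, trace = trace)
}

# Fit one method on one simulated dataset; returns selection, scores and
# (for lasso) the path matrix, all aligned to colnames(sim$counts).
fit_method_once <- function(method, sim, cutoff = 0.3,
                            priors = prior_config(),
                            config = sampler_config(), cv_folds = 5) {
  ct <- community_table(sim$counts)
  taxa <- colnames(sim$counts)
  if (method == "bracod") {
    fit <- run_chain(ct, sim$response, priors, config)
    s <- summarize_trace(fit, cutoff = cutoff)
    scores <- setNames(s$p_hat, s$taxon_id)[taxa]
    list(selected = selected_taxa(s), scores = scores, path = NULL)
  } else if (method == "clr_lasso") {
    f <- fit_clr_lasso(clr_transform(ct), sim$response, cv_folds = cv_folds,
                       seed = config$seed)
    list(selected = f$selected, scores = NULL,
         path = f$path_nonzero[, taxa, drop = FALSE])
  } else if (method == "clr_ss") {
    f <- fit_clr_ss(clr_transform(ct), sim$response, cutoff = cutoff,
                    priors = priors, config = config)
    scores <- setNames(f$summary$p_hat, f$summary$taxon_id)[taxa]
    list(selected = f$selected, scores = scores, path = NULL)
  } else {
    abort(sprintf("unknown method '%s'.", method))
  }
}

#' Flagging of correlated non-contributors across correlation strengths
#'
#' For each correlation strength rho, simulates communities in which a
#' subset of non-contributors is log-correlated with contributors and
#' records, per method, the fraction of simulations in which at least one
#' correlated non-contributor is (wrongly) selected.
#'
#' @param rhos correlation strengths to sweep (default 0.1 to 0.7).
#' @param n_sims simulations per strength.
#' @param methods subset of `c("bracod", "clr_lasso", "clr_ss")`.
#' @param base_config a [simulation_config()] with `n_correlated > 0`.
#' @param cutoff inclusion cut point for the Bayesian methods.
#' @param priors,sampler model prior and sampler settings.
#' @param seed master seed; per-simulation seeds are derived from it.
#' @return tibble: `method`, `rho`, `n_sims`, `flag_rate` (fraction of
#'   simulations flagging at least one correlated non-contributor),
#'   `corr_taxon_rate` and `plain_taxon_rate` (mean per-taxon selection
#'   rates among correlated and uncorrelated nulls, for baseline
#'   comparison).
#' @export
correlated_discrimination_experiment <- function(
    rhos = seq(0.1, 0.7, by = 0.2), n_sims = 20,
    methods = c("bracod", "clr_lasso", "clr_ss"),
    base_config = simulation_config(n_correlated = 20), cutoff = 0.3,
    priors = prior_config(), sampler = sampler_config(), seed = 1) {
  if (base_config$n_correlated <= 0) {
    abort("`base_config` must designate correlated non-contributors.")
  }
  grid <- tidyr::expand_grid(rho = rhos, sim = seq_len(n_sims))
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    rho <- grid$rho[k]; i <- grid$sim[k]
    cfg <- base_config
    cfg$rho <- rho
    cfg$seed <- as.integer((as.numeric(seed) * 10000 + k) %% 2147483629)
    sim <- make_dataset(cfg)
    corr_taxa <- colnames(sim$counts)[sim$correlated_mask == 1]
    plain_null <- colnames(sim$counts)[sim$correlated_mask == 0 &
                                         sim$contributor_mask == 0]
    purrr::map_dfr(methods, function(m) {
      f <- fit_method_once(m, sim, cutoff = cutoff, priors = priors,
                           config = sampler_config(
                             n_burn = sampler$n_burn,
                             n_draws = sampler$n_draws,
                             seed = cfg$seed, thin = sampler$thin))
      tibble(method = m, rho = rho, sim = i,
             flagged = any(corr_taxa %in% f$selected),
             corr_frac = mean(corr_taxa %in% f$selected),
             plain_frac = mean(plain_null %in% f$selected))
    })
  })
  dplyr::summarise(dplyr::group_by(res, .data$method, .data$rho),
                   n_sims = dplyr::n(),
                   flag_rate = mean(.data$flagged),
                   corr_taxon_rate = mean(.data$corr_frac),
                   plain_taxon_rate = mean(.data$plain_frac),
                   .groups = "drop")
}

#' Performance sweep over simulation settings
#'
#' Repeats the simulate-fit-score cycle over a grid of either the number of
#' contributing taxa or the number of community samples, and reports mean
#' and SD of the confusion metrics per grid point and method.
#'
#' @param vary which setting the grid applies to: `"n_contributors"` or
#'   `"n_samples"`.
#' @param grid integer vector of grid values.
#' @param n_sims simulations per grid point.
#' @param methods subset of `c("bracod", "clr_lasso", "clr_ss")`.
#' @param base_config a [simulation_config()] providing all other settings.
#' @param cutoff inclusion cut point.
#' @param priors,sampler model prior and sampler settings.
#' @param seed master seed.
#' @return tidy tibble: `vary`, `value`, `method`, `metric`, `mean`, `sd`
#'   (`sd` is `NA` when `n_sims = 1`).
#' @export
performance_sweep <- function(vary = c("n_contributors", "n_samples"),
                              grid, n_sims = 5,
                              methods = "bracod",
                              base_config = simulation_config(),
                              cutoff = 0.3, priors = prior_config(),
                              sampler = sampler_config(), seed = 1) {
  vary <- match.arg(vary)
  if (!length(grid)) abort("`grid` must be non-empty.")
  cells <- tidyr::expand_grid(value = as.integer(grid),
                              sim = seq_len(n_sims))
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(k) {
    cfg <- base_config
    cfg[[vary]] <- cells$value[k]
    cfg$seed <- as.integer((as.numeric(seed) * 20000 + k) %% 2147483629)
    sim <- make_dataset(cfg)
    truth <- setNames(sim$contributor_mask, colnames(sim$counts))
    purrr::map_dfr(methods, function(m) {
      f <- fit_method_once(m, sim, cutoff = cutoff, priors = priors,
                           config = sampler_config(
                             n_burn = sampler$n_burn,
                             n_draws = sampler$n_draws,
                             seed = cfg$seed, thin = sampler$thin))
      cm <- confusion_metrics(f$selected, truth)
      dplyr::mutate(cm, method = m, value = cells$value[k],
                    sim = cells$sim[k])
    })
  })
  long <- tidyr::pivot_longer(
    dplyr::select(res, "method", "value", "sim", "TPR", "FPR", "precision",
                  "accuracy"),
    cols = c("TPR", "FPR", "precision", "accuracy"),
    names_to = "metric", values_to = "x")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$method, .data$value, .data$metric),
    mean = mean(.data$x), sd = if (dplyr::n() > 1) sd(.data$x) else NA_real_,
    .groups = "drop")
  dplyr::mutate(out, vary = vary, .before = 1)
}

#' Averaged ROC curves and AUC per method over repeated simulations
#'
#' Runs `n_sims` simulations under `base_config` and builds one ROC curve
#' per method: inclusion-probability methods are vertically averaged on a
#' fixed threshold grid; the LASSO curve is vertically averaged on a fixed
#' FPR grid across the per-simulation lambda sweeps.
#'
#' @inheritParams performance_sweep
#' @param p_grid inclusion-probability threshold grid.
#' @param fpr_grid FPR grid used to average LASSO curves.
#' @return list with `curves` (tibble: `method`, `threshold`, `fpr`, `tpr`)
#'   and `auc` (tibble: `method`, `auc`).
#' @export
benchmark_roc <- function(n_sims = 20,
                          methods = c("bracod", "clr_lasso", "clr_ss"),
                          base_config = simulation_config(),
                          priors = prior_config(),
                          sampler = sampler_config(), seed = 1,
                          p_grid = seq(0, 1, by = 0.02),
                          fpr_grid = seq(0, 1, by = 0.02)) {
  per_sim <- purrr::map(seq_len(n_sims), function(i) {
    cfg <- base_config
    cfg$seed <- as.integer((as.numeric(seed) * 30000 + i) %% 2147483629)
    sim <- make_dataset(cfg)
    truth <- setNames(sim$contributor_mask, colnames(sim$counts))
    purrr::map(setNames(methods, methods), function(m) {
      f <- fit_method_once(m, sim, priors = priors,
                           config = sampler_config(
                             n_burn = sampler$n_burn,
                             n_draws = sampler$n_draws,
                             seed = cfg$seed, thin = sampler$thin))
      list(truth = truth, scores = f$scores, path = f$path)
    })
  })
  curves <- purrr::map_dfr(methods, function(m) {
    fits <- purrr::map(per_sim, m)
    if (m == "clr_lasso") {
      # per-sim ROC, then vertical averaging on the FPR grid
      tprs <- purrr::map(fits, function(f) {
        roc <- roc_from_scores(f$path, f$truth, method = m)
        vapply(fpr_grid, function(x) max(c(0, roc$tpr[roc$fpr <= x])),
               numeric(1))
      })
      tibble(method = m, threshold = NA_real_, fpr = fpr_grid,
             tpr = rowMeans(do.call(cbind, tprs)))
    } else {
      pts <- purrr::map_dfr(fits, function(f) {
        purrr::map_dfr(p_grid, function(t) {
          cm <- confusion_metrics(f$scores >= t, f$truth)
          tibble(threshold = t, fpr = cm$FPR, tpr = cm$TPR)
        })
      })
      avg <- dplyr::summarise(dplyr::group_by(pts, .data$threshold),
                              fpr = mean(.data$fpr), tpr = mean(.data$tpr),
                              .groups = "drop")
      dplyr::mutate(avg, method = m, .before = 1)
    }
  })
  auc <- dplyr::summarise(dplyr::group_by(curves, .data$method),
                          auc = trapezoid_auc(.data$fpr, .data$tpr),
                          .groups = "drop")
  list(curves = curves, auc = auc)
}
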