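#' Summarize a posterior trace into per-taxon inclusion statistics
#'
#' Collapses a trace into the model's two headline outputs per taxon: the
#' inclusion probability `p_hat` (posterior mean of the binary indicator)
#' and the slab-coefficient mean `beta_hat_included`. Taxa with
#' `p_hat >= cutoff` are flagged as contributors; `cutoff = 0` returns the
#' full ranked list with every taxon selected.
#'
#' @param trace a `bracod_trace` from [run_chain()] or [fit_clr_ss()].
#' @param table optional [community_table()] used to (re)compute the mean
#'   relative abundance column; by default the abundances recorded at fit
#'   time are used.
#' @param cutoff inclusion-probability cut point (default 0.3, the broad
#'   performance optimum on simulated communities).
#' @param conditional if `TRUE`, average the slab coefficient only over
#'   draws in which the taxon was included (falling back to the
#'   unconditional mean when it never was); default `FALSE`, averaging all
#'   slab draws.
#' @return a tibble of class `inclusion_summary`, sorted by `p_hat`
#'   descending: `taxon_id`, `p_hat`, `beta_hat_included`, `beta_sd`,
#'   `mean_rel_abundance`, `selected`. Coefficients are reported on the
#'   original response scale.
#' @export
summarize_trace <- function(trace, table = NULL, cutoff = 0.3,
                            conditional = FALSE) {
  stopifnot(inherits(trace, "bracod_trace"))
  ind <- trace$draws$indicators
  bi <- trace$draws$beta_included
  if (!nrow(ind)) abort("empty trace: no retained draws to summarize.")
  if (cutoff < 0 || cutoff > 1.01) {
    warn("`cutoff` outside [0, 1]; selection may be empty or full.")
  }
  p_hat <- colMeans(ind)
  if (conditional) {
    beta_hat <- vapply(seq_len(ncol(bi)), function(j) {
      sel <- ind[, j] == 1
      if (any(sel)) mean(bi[sel, j]) else mean(bi[, j])
    }, numeric(1))
  } else {
    beta_hat <- colMeans(bi)
  }
  beta_sd <- apply(bi, 2, sd)
  mra <- if (!is.null(table)) {
    colMeans(relative_abundance(as_community_table(table)))
  } else {
    trace$mean_rel_abundance %||% rep(NA_real_, length(p_hat))
  }
  out <- tibble(taxon_id = trace$taxon_ids,
                p_hat = unname(p_hat),
                beta_hat_included = unname(beta_hat) * trace$y_scale,
                beta_sd = unname(beta_sd) * trace$y_scale,
                mean_rel_abundance = unname(mra),
                selected = unname(p_hat) >= cutoff)
  out <- dplyr::arrange(out, dplyr::desc(.data$p_hat))
  attr(out, "cutoff") <- cutoff
  attr(out, "method") <- trace$method
  class(out) <- c("inclusion_summary", class(out))
  out
}

#' Selected taxa of an inclusion summary
#'
#' @param summary an `inclusion_summary` from [summarize_trace()].
#' @return character vector of selected taxon ids.
#' @export
selected_taxa <- function(summary) {
  summary$taxon_id[summary$selected]
}

#' Coefficient-vs-inclusion scatter table
#'
#' The `(beta_hat_included, p_hat)` pairs used for the cut-point diagnostic
#' scatter plot: non-contributing taxa cluster tightly around a near-zero
#' coefficient while genuine contributors separate along both axes.
#'
#' @param summary an `inclusion_summary`.
#' @return tibble with `taxon_id`, `beta_hat_included`, `p_hat`,
#'   `contributor` (flag at the summary's active cutoff).
#' @export
scatter_summary <- function(summary) {
  stopifnot(inherits(summary, "inclusion_summary"))
  tibble(taxon_id = summary$taxon_id,
         beta_hat_included = summary$beta_hat_included,
         p_hat = summary$p_hat,
         contributor = summary$selected)
}

#' Concordance between two replicate runs
#'
#' Ordinary least-squares regression of the inclusion probabilities of run b
#' on those of run a, the replicate-stability diagnostic: well-converged
#' chains give slope near 1, intercept near 0 and adjusted r-squared near 1.
#'
#' @param summary_a,summary_b `inclusion_summary` objects over the same
#'   taxa.
#' @return one-row tibble with `slope`, `intercept`, `adj_r2`.
#' @export
replicate_concordance <- function(summary_a, summary_b) {
  if (!identical(sort(summary_a$taxon_id), sort(summary_b$taxon_id))) {
    abort("the two summaries cover different taxa.")
  }
  m <- match(summary_a$taxon_id, summary_b$taxon_id)
  pa <- summary_a$p_hat
  pb <- summary_b$p_hat[m]
  if (sd(pa) == 0) {
    return(tibble(slope = NA_real_, intercept = mean(pb), adj_r2 = NA_real_))
  }
  fit <- lm(pb ~ pa)
  adj_r2 <- suppressWarnings(summary(fit)$adj.r.squared) # exact fits warn
  tibble(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         adj_r2 = adj_r2)
}

#' @rdname summarize_trace
#' @param x a `bracod_trace`.
#' @param ... passed to [summarize_trace()].
#' @export
tidy.bracod_trace <- function(x, ...) {
  out <- summarize_trace(x, ...)
  class(out) <- setdiff(class(out), "inclusion_summary")
  out
}

#' One-row overview of a fitted trace
#'
#' @param x a `bracod_trace`.
#' @param cutoff cut point used for the `n_selected` count.
#' @param ... unused.
#' @return one-row tibble: draw count, taxa, selected count, mean inclusion
#'   probability, posterior mean residual variance and spike scale, flip
#'   acceptance rate.
#' @export
glance.bracod_trace <- function(x, cutoff = 0.3, ...) {
  p_hat <- colMeans(x$draws$indicators)
  tibble(n_draws = length(x$draws$alpha),
         n_taxa = length(x$taxon_ids),
         n_selected = sum(p_hat >= cutoff),
         mean_p_hat = mean(p_hat),
         sigma2 = mean(x$draws$sigma2) * x$y_scale^2,
         tau2 = mean(x$draws$tau2),
         accept_flip = x$diagnostics$accept_flip)
}

#' Write an inclusion summary as TSV
#'
#' Columns: `taxon_id`, `p_hat`, `beta_hat_included`,
#' `mean_rel_abundance`, `selected` (0/1).
#'
#' @param summary an `inclusion_summary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  out <- dplyr::transmute(tibble::as_tibble(summary),
                          taxon_id = .data$taxon_id,
                          p_hat = .data$p_hat,
                          beta_hat_included = .data$beta_hat_included,
                          mean_rel_abundance = .data$mean_rel_abundance,
                          selected = as.integer(.data$selected))
  readr::write_tsv(out, path)
  invisible(path)
}
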