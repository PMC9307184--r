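#' Read a taxon count table from CSV
#'
#' Expects samples in rows and taxa in columns, with sample identifiers in
#' the first column. Orientation is auto-detected by a header heuristic
#' (more columns than rows usually means samples-as-rows in OTU tables can
#' be ambiguous, so detection is based on which margin repeats typical
#' sample-id patterns less often than numeric content allows) and can be
#' forced with `orientation`.
#'
#' @param path CSV file path.
#' @param orientation `"auto"`, `"samples_rows"` or `"taxa_rows"`.
#' @param delim field delimiter; `NULL` auto-detects comma/tab/semicolon.
#' @return a [community_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("auto", "samples_rows",
                                             "taxa_rows"),
                             delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t"
             else if (grepl(";", first)) ";" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2L) abort("count table needs an id column plus data columns.")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- names(df)[-1L][!vapply(df[-1L], is.numeric, logical(1))][1L]
    abort(sprintf("non-numeric data column '%s' in %s.", bad, path))
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("negative value at row %d ('%s'), column '%s' of %s.",
                  neg[1, 1], ids[neg[1, 1]], colnames(mat)[neg[1, 2]], path))
  }
  rownames(mat) <- ids
  if (orientation == "auto") {
    # heuristic: taxa usually far outnumber samples in OTU tables
    orientation <- if (ncol(mat) >= nrow(mat)) "samples_rows" else "taxa_rows"
  }
  if (orientation == "taxa_rows") mat <- t(mat)
  community_table(mat)
}

#' Read a per-sample response from a two-column CSV
#'
#' @param path CSV with columns `(sample_id, value)`.
#' @return tibble with `sample_id` (character) and `value` (numeric).
#' @export
read_response <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort("response file needs (sample_id, value) columns.")
  out <- tibble(sample_id = as.character(df[[1L]]),
                value = as.numeric(df[[2L]]))
  if (any(!is.finite(out$value))) {
    abort(sprintf("non-finite response values for: %s",
                  paste(out$sample_id[!is.finite(out$value)], collapse = ", ")))
  }
  out
}

#' Aggregate a community table to a higher taxonomic level
#'
#' Counts are summed within groups of the taxonomy map. Taxa missing from
#' the map are pooled per parent clade as `unclassified_<parent>` when a
#' parent column is available, otherwise into a single `unclassified`
#' group.
#'
#' @param table a [community_table()].
#' @param taxonomy_map data frame with columns `taxon_id` and the target
#'   `level` (e.g. `genus`, `family`); an optional `parent` column labels
#'   pools of unmapped taxa.
#' @param level name of the column in `taxonomy_map` to aggregate to.
#' @return an aggregated [community_table()].
#' @export
aggregate_taxonomy <- function(table, taxonomy_map, level = "genus") {
  table <- as_community_table(table)
  if (!is.data.frame(taxonomy_map) || !nrow(taxonomy_map)) {
    abort("`taxonomy_map` must be a non-empty data frame.")
  }
  if (!all(c("taxon_id", level) %in% names(taxonomy_map))) {
    abort(sprintf("`taxonomy_map` needs columns 'taxon_id' and '%s'.", level))
  }
  ids <- colnames(table)
  m <- match(ids, as.character(taxonomy_map$taxon_id))
  group <- as.character(taxonomy_map[[level]])[m]
  if (anyNA(group)) {
    parent <- if ("parent" %in% names(taxonomy_map)) {
      as.character(taxonomy_map$parent)[m]
    } else NULL
    miss <- is.na(group)
    group[miss] <- if (!is.null(parent) && any(!is.na(parent[miss]))) {
      ifelse(is.na(parent[miss]), "unclassified",
             paste0("unclassified_", parent[miss]))
    } else "unclassified"
  }
  groups <- unique(group)
  agg <- vapply(groups, function(gp) {
    rowSums(unclass(table)[, group == gp, drop = FALSE])
  }, numeric(nrow(table)))
  community_table(agg, sample_ids = rownames(table), taxon_ids = groups,
                  is_counts = attr(table, "is_counts"))
}

#' Write a simulated dataset to disk
#'
#' Emits a counts CSV (samples in rows, id column first), a response CSV
#' `(sample_id, value)` and a ground-truth JSON (true coefficients, masks,
#' config echo).
#'
#' @param sim a `simulated_dataset` from [make_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(sim, dir, prefix = "simulated") {
  stopifnot(inherits(sim, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, paste0(prefix, "_counts.csv"))
  resp_path <- file.path(dir, paste0(prefix, "_response.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  cnt <- tibble::as_tibble(sim$counts)
  cnt <- dplyr::bind_cols(tibble(sample_id = rownames(sim$counts)), cnt)
  readr::write_csv(cnt, counts_path)
  readr::write_csv(tibble(sample_id = rownames(sim$counts),
                          value = sim$response), resp_path)
  cfg <- sim$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(
    list(true_beta = setNames(as.list(sim$true_beta), names(sim$true_beta)),
         contributor_mask = sim$contributor_mask,
         correlated_mask = sim$correlated_mask,
         config = unclass(cfg), seed = sim$config$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(counts = counts_path, response = resp_path, truth = truth_path))
}

#' Persist a posterior trace to a directory
#'
#' Writes the scalar draws and the three per-taxon draw matrices as CSV
#' plus a JSON manifest (taxa, configuration, seed, scaling), so a saved
#' run can be re-summarized at a new cut point without re-sampling.
#'
#' @param trace a `bracod_trace`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "bracod_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble(alpha = trace$draws$alpha,
                          sigma2 = trace$draws$sigma2,
                          tau2 = trace$draws$tau2),
                   file.path(dir, "scalars.csv"))
  for (nm in c("beta_included", "beta_excluded", "indicators")) {
    readr::write_csv(tibble::as_tibble(trace$draws[[nm]]),
                     file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(
    list(taxon_ids = trace$taxon_ids,
         mean_rel_abundance = trace$mean_rel_abundance,
         y_center = trace$y_center, y_scale = trace$y_scale,
         standardized = trace$standardized, method = trace$method,
         priors = unclass(trace$priors), config = unclass(trace$config),
         diagnostics = trace$diagnostics),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a persisted posterior trace
#'
#' @param dir directory written by [write_trace()].
#' @return a `bracod_trace`.
#' @export
read_trace <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) abort(sprintf("no trace manifest under %s", dir))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  scalars <- readr::read_csv(file.path(dir, "scalars.csv"),
                             show_col_types = FALSE, progress = FALSE)
  get_mat <- function(nm) {
    m <- as.matrix(readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                                   show_col_types = FALSE, progress = FALSE))
    colnames(m) <- man$taxon_ids
    m
  }
  structure(list(draws = list(alpha = scalars$alpha, sigma2 = scalars$sigma2,
                              tau2 = scalars$tau2,
                              beta_included = get_mat("beta_included"),
                              beta_excluded = get_mat("beta_excluded"),
                              indicators = get_mat("indicators")),
                 taxon_ids = man$taxon_ids,
                 mean_rel_abundance = man$mean_rel_abundance,
                 y_center = man$y_center, y_scale = man$y_scale,
                 standardized = man$standardized,
                 priors = do.call(prior_config, man$priors),
                 config = do.call(sampler_config, man$config),
                 method = man$method,
                 diagnostics = as.list(man$diagnostics)),
            class = "bracod_trace")
}
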