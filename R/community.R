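#' Construct a community abundance table
#'
#' A `community_table` holds a samples x taxa matrix of non-negative
#' abundances, either raw sequencing counts or relative abundances, together
#' with sample and taxon identifiers. It is the common input container for
#' model fitting ([run_chain()]), simulation parameter estimation
#' ([estimate_lognormal_params()]) and the clr transform ([clr_transform()]).
#'
#' @param values numeric matrix or data frame, samples in rows and taxa in
#'   columns. A data frame may carry sample identifiers in a first
#'   non-numeric column.
#' @param sample_ids,taxon_ids optional character vectors of identifiers;
#'   defaults are taken from dimnames or generated.
#' @param is_counts logical; `TRUE` for raw counts. Guessed from the values
#'   (all integral) when `NULL`.
#' @return an object of class `community_table`: the numeric matrix with
#'   dimnames set and an `is_counts` attribute.
#' @examples
#' ct <- community_table(matrix(c(10, 0, 5, 85, 90, 10), nrow = 2),
#'                       taxon_ids = c("otu1", "otu2", "otu3"))
#' relative_abundance(ct)
#' @export
community_table <- function(values, sample_ids = NULL, taxon_ids = NULL,
                            is_counts = NULL) {
  if (is.data.frame(values)) {
    first <- values[[1L]]
    if (!is.numeric(first)) {
      if (is.null(sample_ids)) sample_ids <- as.character(first)
      values <- values[, -1L, drop = FALSE]
    }
    if (is.null(taxon_ids)) taxon_ids <- names(values)
    values <- as.matrix(values)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix or a data frame of abundances.")
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("sample_", seq_len(nrow(values)))
  taxon_ids <- taxon_ids %||% colnames(values) %||%
    paste0("taxon_", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values)) {
    abort("`sample_ids` length does not match the number of rows.")
  }
  if (length(taxon_ids) != ncol(values)) {
    abort("`taxon_ids` length does not match the number of columns.")
  }
  if (anyDuplicated(taxon_ids)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (any(!is.finite(values))) abort("abundance values must be finite.")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("negative abundance at sample '%s', taxon '%s'.",
                  sample_ids[bad[1L]], taxon_ids[bad[2L]]))
  }
  rs <- rowSums(values)
  if (any(rs == 0)) {
    abort(paste0("all-zero sample row(s): ",
                 paste(sample_ids[rs == 0], collapse = ", ")))
  }
  if (is.null(is_counts)) {
    is_counts <- all(abs(values - round(values)) < 1e-8) && any(values > 1)
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(taxon_ids))
  structure(values, is_counts = is_counts, class = c("community_table", "matrix", "array"))
}

#' @exportS3Method base::print
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d taxa (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_counts"))) "counts" else "relative abundances"))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE], 4L))
  invisible(x)
}

as_community_table <- function(x, ...) {
  if (inherits(x, "community_table")) x else community_table(x, ...)
}

#' Closure: renormalize each sample to relative abundances
#'
#' Divides every row by its sum so rows sum to one. Optionally replaces zero
#' entries first (multiplicative replacement) so that downstream log
#' transforms are defined.
#'
#' @param table a [community_table()] (or coercible matrix/data frame).
#' @param zero_policy `"multiplicative"` replaces every zero with
#'   `zero_frac` times the smallest nonzero relative abundance in the whole
#'   table and re-closes the rows; `"none"` leaves zeros in place.
#' @param zero_frac fraction of the smallest nonzero relative abundance used
#'   as the replacement value (default 0.5).
#' @return numeric matrix of relative abundances, rows summing to 1.
#' @export
relative_abundance <- function(table,
                               zero_policy = c("multiplicative", "none"),
                               zero_frac = 0.5) {
  zero_policy <- match.arg(zero_policy)
  x <- unclass(as_community_table(table))
  attr(x, "is_counts") <- NULL
  x <- x / rowSums(x)
  if (zero_policy == "multiplicative" && any(x == 0)) {
    repl <- zero_frac * min(x[x > 0])
    x[x == 0] <- repl
    x <- x / rowSums(x)
  }
  x
}

#' Log relative abundances
#'
#' Convenience wrapper: zero-replaced closed relative abundances on the
#' natural-log scale, the predictor matrix of the regression model.
#'
#' @inheritParams relative_abundance
#' @return numeric matrix `log(c_ij)`, all entries finite under the default
#'   zero policy.
#' @export
log_relative_abundance <- function(table, zero_policy = "multiplicative",
                                   zero_frac = 0.5) {
  lc <- log(relative_abundance(table, zero_policy, zero_frac))
  if (any(!is.finite(lc))) {
    abort(paste("log relative abundances contain non-finite entries;",
                "zeros must be replaced first (see `zero_policy`)."))
  }
  lc
}

# Align a response to a community table by sample id; returns a numeric
# vector in table row order. `response` may be a bare numeric vector (used
# positionally) or a two-column data frame (sample_id, value).
align_response <- function(table, response) {
  ids <- rownames(table)
  if (is.data.frame(response)) {
    if (ncol(response) < 2L) abort("response data frame needs (sample_id, value) columns.")
    rid <- as.character(response[[1L]])
    val <- response[[2L]]
    if (!is.numeric(val)) abort("second response column must be numeric.")
    missing <- setdiff(ids, rid)
    extra <- setdiff(rid, ids)
    if (length(missing) || length(extra)) {
      abort(paste0("response/table sample mismatch.",
                   if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
                   if (length(extra)) paste0(" Unmatched: ", paste(extra, collapse = ", "), ".")))
    }
    y <- val[match(ids, rid)]
  } else {
    y <- as.numeric(response)
    if (length(y) != nrow(table)) {
      abort(sprintf("response length (%d) does not match samples (%d).",
                    length(y), nrow(table)))
    }
  }
  if (any(!is.finite(y))) abort("response values must be finite.")
  names(y) <- ids
  y
}
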