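#' Expression matrix container
#'
#' A light container for a feature x sample matrix of log2 abundances with
#' per-sample time/replicate metadata. Feature identifiers must be unique and
#' all values finite; every sample carries a time (hours) and a replicate
#' index encoded in its column name as `t{h}h_rep{r}`.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   rownames are feature identifiers, colnames sample identifiers.
#' @param sample_meta optional data.frame with columns `sample_id`, `time_h`,
#'   `replicate`; derived from `colnames(values)` when omitted.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `sample_meta`.
#' @export
expression_matrix <- function(values, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    mirnet_stop("mirnet_bad_input", "values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mirnet_stop("mirnet_bad_input", "values must have row and column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    mirnet_stop("mirnet_duplicate_ids", "duplicate feature id(s): %s",
                paste(dup, collapse = ", "))
  if (any(!is.finite(values)))
    mirnet_stop("mirnet_bad_input", "values must be finite")
  if (is.null(sample_meta)) sample_meta <- parse_sample_ids(colnames(values))
  stopifnot(identical(sample_meta$sample_id, colnames(values)))
  structure(list(values = values, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (time points %s h; %d replicates)\n",
              nrow(x$values), ncol(x$values),
              paste(sort(unique(x$sample_meta$time_h)), collapse = ","),
              max(x$sample_meta$replicate)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

time_points <- function(em) sort(unique(em$sample_meta$time_h))

# subset an expr_matrix by feature ids
subset_features <- function(em, ids) {
  expression_matrix(em$values[ids, , drop = FALSE], em$sample_meta)
}
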