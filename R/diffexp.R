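#' One-way ANOVA across the time course
#'
#' Fits, for every feature, a one-way fixed-effects ANOVA with the time
#' points as groups and returns the F-test p-value. Computation is the
#' standard between/within sum-of-squares decomposition evaluated for all
#' rows at once; [stats::pf()] supplies the F distribution. Features with
#' zero variance everywhere have an undefined F statistic and are assigned
#' p = 1 (not significant), with a warning giving their count.
#'
#' @param em an [expression_matrix()]; every time point must have at least
#'   two replicates and there must be at least two time points.
#' @return named numeric vector of p-values (one per feature).
#' @export
anova_time_course <- function(em) {
  g <- factor(em$sample_meta$time_h)
  sizes <- table(g)
  if (nlevels(g) < 2L)
    mirnet_stop("mirnet_bad_design", "need at least two time points")
  if (any(sizes < 2L))
    mirnet_stop("mirnet_bad_design",
                "time point group(s) with a single replicate: %s h",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
  x <- em$values
  n <- ncol(x)
  k <- nlevels(g)
  gm <- t(rowsum(t(x), g)) / rep(as.vector(sizes), each = nrow(x))
  fitted <- gm[, as.integer(g), drop = FALSE]
  ssw <- rowSums((x - fitted)^2)
  ssb <- rowSums((fitted - rowMeans(x))^2)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(fstat, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw == 0 & ssb == 0
  if (any(degenerate)) {
    warning(sprintf("%d feature(s) with zero variance; ANOVA p set to 1",
                    sum(degenerate)))
    p[degenerate] <- 1
  }
  # ssw == 0 with ssb > 0: perfect separation, F = Inf, p = 0
  p[ssw == 0 & ssb > 0] <- 0
  stats::setNames(p, rownames(x))
}

#' Call per-time-point fold changes against baseline
#'
#' For each feature and post-treatment time point, the log2 fold change is
#' the replicate-mean log2 abundance minus the replicate-mean at t = 0. A
#' time point is called `up` when the linear ratio meets `fc_threshold`
#' (inclusive), `down` when it meets `1/fc_threshold`, otherwise `none`.
#'
#' @param em an [expression_matrix()] containing a t = 0 group.
#' @param fc_threshold linear fold-change cutoff (> 1); conventional values
#'   are 1.25 for array mRNA data and 2.0 for qPCR miRNA data.
#' @return A `diff_calls` object: list with `log2fc` and `direction`
#'   matrices (features x post-treatment time points), `anova_p` (NA until
#'   filled by the caller), `n_modulated`, `passes_filter` (NA until
#'   [apply_modulation_rule()]), and the threshold used.
#' @export
call_fold_changes <- function(em, fc_threshold = 1.25) {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      fc_threshold <= 1)
    mirnet_stop("mirnet_bad_threshold",
                "fc_threshold must be a single value > 1 (got %s)",
                paste(fc_threshold, collapse = ","))
  tp <- time_points(em)
  if (!0 %in% tp)
    mirnet_stop("mirnet_bad_design", "matrix has no t = 0 baseline samples")
  g <- factor(em$sample_meta$time_h)
  sizes <- as.vector(table(g))
  means <- t(rowsum(t(em$values), g)) / rep(sizes, each = nrow(em$values))
  post <- setdiff(tp, 0)
  l2fc <- means[, as.character(post), drop = FALSE] - means[, "0"]
  thr <- log2(fc_threshold)
  tol <- 1e-8  # inclusive boundaries, robust to float representation
  dir <- matrix("none", nrow(l2fc), ncol(l2fc), dimnames = dimnames(l2fc))
  dir[l2fc >= thr - tol] <- "up"
  dir[l2fc <= -thr + tol] <- "down"
  structure(list(feature_id = rownames(em$values),
                 time_points = post,
                 log2fc = l2fc,
                 direction = dir,
                 anova_p = stats::setNames(rep(NA_real_, nrow(l2fc)),
                                           rownames(l2fc)),
                 n_modulated = stats::setNames(as.integer(rowSums(dir != "none")),
                                               rownames(l2fc)),
                 passes_filter = stats::setNames(rep(NA, nrow(l2fc)),
                                                 rownames(l2fc)),
                 fc_threshold = fc_threshold),
            class = "diff_calls")
}

#' @export
print.diff_calls <- function(x, ...) {
  cat(sprintf("diff_calls: %d features, time points %s h, FC threshold %g\n",
              length(x$feature_id), paste(x$time_points, collapse = ","),
              x$fc_threshold))
  if (!all(is.na(x$passes_filter)))
    cat(sprintf("  passing filter: %d\n", sum(x$passes_filter)))
  invisible(x)
}

#' @export
as.data.frame.diff_calls <- function(x, ...) {
  out <- data.frame(feature_id = x$feature_id,
                    anova_p = unname(x$anova_p),
                    n_modulated_timepoints = unname(x$n_modulated),
                    passes_filter = unname(x$passes_filter))
  for (tp in colnames(x$log2fc)) {
    out[[paste0("log2fc_", tp, "h")]] <- x$log2fc[, tp]
    out[[paste0("dir_", tp, "h")]] <- x$direction[, tp]
  }
  out
}

#' Apply the multi-time-point modulation rule
#'
#' A feature passes when (i) its ANOVA p-value is below `alpha` (if ANOVA
#' filtering is enabled) and (ii) it is called up or down at at least
#' `min_timepoints` post-treatment time points. No multiple-testing
#' correction is applied by default, matching the conventional per-feature
#' p < 0.05 filter; set `fdr = TRUE` for Benjamini-Hochberg adjustment.
#'
#' @param calls a `diff_calls` object.
#' @param anova_p named vector from [anova_time_course()] (optional when
#'   already stored in `calls`).
#' @param min_timepoints minimum modulated time points (>= 1).
#' @param alpha significance cutoff.
#' @param use_anova apply the ANOVA component of the filter.
#' @param fdr use BH-adjusted p-values instead of raw p-values.
#' @return `calls` with `anova_p` and `passes_filter` filled; attribute
#'   `"n_pass"` gives the summary count.
#' @export
apply_modulation_rule <- function(calls, anova_p = NULL, min_timepoints = 2L,
                                  alpha = 0.05, use_anova = TRUE,
                                  fdr = FALSE) {
  if (!is_count(min_timepoints))
    mirnet_stop("mirnet_bad_threshold", "min_timepoints must be a count >= 1")
  if (!is.null(anova_p)) {
    if (!all(calls$feature_id %in% names(anova_p)))
      mirnet_stop("mirnet_bad_input", "anova_p missing some features")
    calls$anova_p <- anova_p[calls$feature_id]
  }
  p <- calls$anova_p
  if (fdr) p <- stats::p.adjust(p, "BH")
  ok_p <- if (use_anova) {
    if (all(is.na(p)))
      mirnet_stop("mirnet_bad_input",
                  "ANOVA requested but no p-values supplied")
    !is.na(p) & p < alpha
  } else rep(TRUE, length(calls$feature_id))
  calls$passes_filter <- stats::setNames(
    ok_p & calls$n_modulated >= min_timepoints, calls$feature_id)
  attr(calls, "n_pass") <- sum(calls$passes_filter)
  calls
}

#' Band passing miRNAs by peak fold change
#'
#' Each feature is summarised by the time point with the largest absolute
#' log2 fold change; the peak linear ratios are banded into three mutually
#' exclusive groups: induced at least 3-fold, induced 2- to 3-fold, and
#' reduced at least 2-fold. A boundary ratio of exactly 3 falls in the
#' >= 3-fold band. Percentages are of the total number of features supplied
#' and are truncated to whole percent (so the three bands can never total
#' more than 100%).
#'
#' @param calls a `diff_calls` object (typically miRNAs passing the
#'   modulation rule).
#' @param features optional subset of feature ids; defaults to the features
#'   passing the filter, or all features when the rule has not been applied.
#' @return data.frame with columns `band`, `count`, `percent`; total feature
#'   count in attribute `"total"`.
#' @export
band_fold_changes <- function(calls, features = NULL) {
  if (is.null(features)) {
    features <- if (all(is.na(calls$passes_filter))) calls$feature_id
                else calls$feature_id[calls$passes_filter]
  }
  total <- length(features)
  bands <- c(up_3fold = 0L, up_2to3fold = 0L, down_2fold = 0L)
  if (total) {
    l2 <- calls$log2fc[features, , drop = FALSE]
    peak <- l2[cbind(seq_len(nrow(l2)), max.col(abs(l2), "first"))]
    ratio <- 2^peak
    tol <- 1e-8
    bands["up_3fold"] <- sum(ratio >= 3 - tol)
    bands["up_2to3fold"] <- sum(ratio >= 2 - tol & ratio < 3 - tol)
    bands["down_2fold"] <- sum(ratio <= 0.5 + tol)
  }
  out <- data.frame(band = names(bands), count = as.integer(bands),
                    percent = if (total) as.integer(floor(100 * bands / total))
                              else rep(0L, 3L))
  attr(out, "total") <- total
  out
}
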