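#' Default temporal templates
#'
#' Idealised response shapes over the post-treatment time points: early
#' classes deviate at the first two time points and return to baseline,
#' late classes deviate at the last two. Over the default grid
#' (2, 4, 12, 24 h): `early_up = (1,1,0,0)`, `early_down = (-1,-1,0,0)`,
#' `late_up = (0,0,1,1)`, `late_down = (0,0,-1,-1)`.
#'
#' @param time_points_h post-treatment time points (baseline excluded).
#' @return numeric matrix, one template per row, columns named by time.
#' @export
default_templates <- function(time_points_h = c(2, 4, 12, 24)) {
  k <- length(time_points_h)
  if (k < 3L)
    mirnet_stop("mirnet_bad_design",
                "need at least 3 post-treatment time points for templates")
  early <- seq_len(floor(k / 2))
  late <- setdiff(seq_len(k), early)
  tm <- rbind(early_up = replace(numeric(k), early, 1),
              early_down = replace(numeric(k), early, -1),
              late_up = replace(numeric(k), late, 1),
              late_down = replace(numeric(k), late, -1))
  colnames(tm) <- as.character(time_points_h)
  tm
}

# phase (early/late) and direction implied by a template/class name
class_phase <- function(cls) sub("_(up|down)$", "", cls)
class_direction <- function(cls) sub("^(early|late)_", "", cls)

# time points belonging to each phase, given the post-treatment grid
phase_times <- function(time_points_h) {
  k <- length(time_points_h)
  list(early = time_points_h[seq_len(floor(k / 2))],
       late = time_points_h[setdiff(seq_len(k), seq_len(floor(k / 2)))])
}

#' Replicate-level log2 fold-change profiles
#'
#' Subtracts the replicate-mean baseline (t = 0) from every post-treatment
#' sample, keeping replicates separate. These replicate-resolved profiles
#' are what [match_templates()] correlates against the templates, so that a
#' profile only matches reproducibly when both replicates follow the shape.
#'
#' @param em an [expression_matrix()] containing t = 0 samples.
#' @return matrix features x post-treatment samples with a `"time_h"`
#'   attribute giving each column's time point.
#' @export
replicate_log2fc <- function(em) {
  meta <- em$sample_meta
  if (!0 %in% meta$time_h)
    mirnet_stop("mirnet_bad_design", "matrix has no t = 0 baseline samples")
  base <- rowMeans(em$values[, meta$time_h == 0, drop = FALSE])
  keep <- meta$time_h != 0
  out <- em$values[, keep, drop = FALSE] - base
  attr(out, "time_h") <- meta$time_h[keep]
  out
}

#' Assign features to temporal classes by template matching
#'
#' Pearson-correlates each feature's replicate-level log2 fold-change
#' profile with each template (template values are expanded across
#' replicates by time point). The best template is the argmax correlation;
#' exact ties are broken by the larger mean absolute log2 fold change over
#' the template's active phase, then by template name. Significance is a
#' permutation test: the profile's entries are permuted and the fraction of
#' permutations reaching the observed correlation, plus-one corrected,
#' gives `permutation_p`.
#'
#' A class is assigned only when `template_r >= r_min`, `permutation_p <
#' alpha`, and — when differential-expression calls are supplied — the
#' feature passes the modulation filter with the class's direction called at
#' at least one time point of the class's phase. Everything else is
#' `unclassified`.
#'
#' @param profiles matrix from [replicate_log2fc()] (or any feature x sample
#'   matrix with a `"time_h"` attribute).
#' @param templates template matrix from [default_templates()].
#' @param r_min minimum template correlation.
#' @param n_permutations permutations for the significance test.
#' @param alpha significance cutoff on the permutation p-value.
#' @param rng_seed seed for the permutation draw.
#' @param calls optional `diff_calls` for the same features, used to gate
#'   class assignment on the modulation rule.
#' @return data.frame: `feature_id`, `class` (`"unclassified"` when no
#'   template qualifies), `template_r`, `permutation_p`, `best_template`.
#' @export
match_templates <- function(profiles, templates = NULL, r_min = 0.8,
                            n_permutations = 10000L, alpha = 0.05,
                            rng_seed = 1L, calls = NULL) {
  th <- attr(profiles, "time_h")
  if (is.null(th))
    mirnet_stop("mirnet_bad_input", "profiles need a time_h attribute")
  if (length(unique(th)) < 3L)
    mirnet_stop("mirnet_bad_design",
                "template matching needs at least 3 post-treatment time points")
  if (is.null(templates)) templates <- default_templates(sort(unique(th)))
  if (!all(as.character(th) %in% colnames(templates)))
    mirnet_stop("mirnet_bad_input", "templates do not cover the profile time grid")
  texp <- templates[, as.character(th), drop = FALSE]  # replicate-expanded
  if (any(apply(texp, 1L, stats::sd) == 0))
    mirnet_stop("mirnet_bad_input", "constant template after expansion")

  m <- ncol(profiles)
  set.seed(rng_seed)
  perm <- matrix(0L, n_permutations, m)
  for (i in seq_len(n_permutations)) perm[i, ] <- sample.int(m)

  # standardised templates: correlation reduces to a dot product
  tz <- t(scale(t(texp)))
  r_all <- stats::cor(t(profiles), t(texp))  # features x templates
  ph <- phase_times(sort(unique(th)))

  res <- data.frame(feature_id = rownames(profiles),
                    class = "unclassified",
                    template_r = NA_real_,
                    permutation_p = NA_real_,
                    best_template = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profiles))) {
    x <- profiles[i, ]
    sx <- stats::sd(x)
    if (!is.finite(sx) || sx == 0) next
    ri <- r_all[i, ]
    best <- which(ri >= max(ri) - 1e-12)
    if (length(best) > 1L) {
      act <- vapply(rownames(texp)[best], function(cl) {
        mean(abs(x[th %in% ph[[class_phase(cl)]]]))
      }, numeric(1))
      best <- best[order(-act, rownames(texp)[best])][1L]
    }
    tmpl <- rownames(texp)[best]
    r_obs <- ri[best]
    z <- tz[best, ]
    rp <- as.vector(matrix(x[perm], n_permutations) %*% z) / ((m - 1) * sx)
    p <- (1 + sum(rp >= r_obs - 1e-12)) / (n_permutations + 1)
    res$template_r[i] <- r_obs
    res$permutation_p[i] <- p
    res$best_template[i] <- tmpl
    ok <- is.finite(r_obs) && r_obs >= r_min && p < alpha
    if (ok && !is.null(calls)) {
      j <- match(res$feature_id[i], calls$feature_id)
      ok <- !is.na(j) && isTRUE(calls$passes_filter[j]) &&
        any(calls$direction[j, as.character(ph[[class_phase(tmpl)]])] ==
              class_direction(tmpl))
    }
    if (ok) res$class[i] <- tmpl
  }
  res
}

#' Median temporal profile of a feature group
#'
#' Per-time-point median of the mean log2 fold-change profiles of the group
#' members, the summary used to display one curve per temporal class and to
#' correlate a miRNA class against its predicted targets.
#'
#' @param calls a `diff_calls` object holding the log2fc matrix.
#' @param members feature ids of the group (must be non-empty).
#' @return named numeric vector over post-treatment time points.
#' @export
median_class_profile <- function(calls, members) {
  if (!length(members))
    mirnet_stop("mirnet_empty_class", "empty class: no members supplied")
  missing <- setdiff(members, calls$feature_id)
  if (length(missing))
    mirnet_stop("mirnet_bad_input", "unknown feature(s): %s",
                paste(missing, collapse = ", "))
  apply(calls$log2fc[members, , drop = FALSE], 2L, stats::median)
}

#' Sample PCA and feature clustering overview
#'
#' Exploratory summaries of the whole matrix: PCA of the samples (centred
#' log2 values, [stats::prcomp()]) and average-linkage hierarchical
#' clustering of the features under a 1 - Pearson correlation distance.
#'
#' @param em an [expression_matrix()] with at least 3 samples.
#' @param k number of flat feature clusters to cut from the dendrogram.
#' @return list with `pca` (data.frame of sample coordinates),
#'   `variance_explained`, `hclust` (the feature dendrogram) and `clusters`
#'   (flat assignments from [stats::cutree()]).
#' @export
profile_overview <- function(em, k = 4L) {
  if (ncol(em$values) < 3L)
    mirnet_stop("mirnet_bad_design", "PCA overview needs at least 3 samples")
  if (stats::sd(as.vector(em$values)) == 0)
    mirnet_stop("mirnet_constant_matrix",
                "constant matrix: PCA is undefined")
  pc <- stats::prcomp(t(em$values), center = TRUE, scale. = FALSE)
  coords <- as.data.frame(pc$x)
  coords <- cbind(em$sample_meta, coords)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- apply(em$values, 1L, stats::sd) > 0
  d <- stats::as.dist(1 - stats::cor(t(em$values[keep, , drop = FALSE])))
  hc <- stats::hclust(d, method = "average")
  list(pca = coords, variance_explained = ve, hclust = hc,
       clusters = stats::cutree(hc, k = min(k, sum(keep))))
}

#' Self-organizing map preview of expression profiles
#'
#' Exploratory batch SOM (via [class::batchSOM()]) over mean log2
#' fold-change profiles, used to eyeball the major profile groups before
#' template matching; its output feeds nothing downstream. Deterministic
#' given `rng_seed`.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param grid `c(rows, cols)` of the map; at least 1 x 2.
#' @param epochs number of batch update rounds.
#' @param rng_seed seed for code-book initialisation.
#' @return integer vector assigning each profile to a map node (1-based,
#'   row-major), named by profile.
#' @export
som_preview <- function(profiles, grid = c(2L, 2L), epochs = 20L,
                        rng_seed = 1L) {
  if (!nrow(profiles))
    mirnet_stop("mirnet_bad_input", "no profiles supplied")
  if (prod(grid) < 2L)
    mirnet_stop("mirnet_bad_design", "SOM grid must have at least 2 nodes")
  set.seed(rng_seed)
  sg <- class::somgrid(grid[1L], grid[2L], "rectangular")
  sm <- class::batchSOM(profiles, sg, radii = seq(2, 0, length.out = epochs))
  d <- as.matrix(stats::dist(rbind(sm$codes, profiles)))
  nc <- nrow(sm$codes)
  assign <- apply(d[-(seq_len(nc)), seq_len(nc), drop = FALSE], 1L, which.min)
  stats::setNames(as.integer(assign), rownames(profiles))
}
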