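#' Phase-wise inverse miRNA:mRNA pairing
#'
#' Builds one of the four inversely regulated sets: the miRNAs of a given
#' temporal class (phase x direction) are linked to the genes that (i) pass
#' the differential-expression filter, (ii) are called in the opposite
#' direction at at least one time point of the same phase, and (iii) are
#' predicted targets of at least one class miRNA. The pairing carries its
#' edge list, the fraction of the phase/opposite-direction DE genes covered
#' by predictions, and the Pearson correlation between the miRNA-set median
#' profile and the target-set median profile.
#'
#' @param assignments data.frame from [match_templates()] (miRNA classes).
#' @param mirna_calls `diff_calls` for miRNAs (profiles for the medians).
#' @param mrna_calls `diff_calls` for genes with the modulation rule applied.
#' @param predictions a `prediction_table`.
#' @param phase `"early"` or `"late"`.
#' @param mirna_direction `"up"` or `"down"`.
#' @return A `phase_pairing`: list with `phase`, `mirna_direction`,
#'   `mirnas`, `target_genes`, `edges` (data.frame `mirna_id`, `gene_id`,
#'   `phase`, `n_sites`), `de_opposite_genes`, `coverage_fraction`,
#'   `mirna_median`, `target_median`, `median_profile_r`.
#' @export
pair_phase <- function(assignments, mirna_calls, mrna_calls, predictions,
                       phase = c("early", "late"),
                       mirna_direction = c("up", "down")) {
  phase <- match.arg(phase)
  mirna_direction <- match.arg(mirna_direction)
  if (all(is.na(mrna_calls$passes_filter)))
    mirnet_stop("mirnet_bad_input",
                "apply_modulation_rule() must be run on mrna_calls first")
  cls <- paste(phase, mirna_direction, sep = "_")
  mirnas <- assignments$feature_id[assignments$class == cls]
  if (!length(mirnas))
    warning(sprintf("empty miRNA class %s: pairing is empty", cls))

  opp <- if (mirna_direction == "up") "down" else "up"
  ptimes <- phase_times(mrna_calls$time_points)[[phase]]
  dirm <- mrna_calls$direction[, as.character(ptimes), drop = FALSE]
  de_opp <- mrna_calls$feature_id[mrna_calls$passes_filter &
                                    rowSums(dirm == opp) > 0]

  edges <- predictions[predictions$mirna_id %in% mirnas &
                         predictions$gene_id %in% de_opp,
                       c("mirna_id", "gene_id", "n_sites"), drop = FALSE]
  targets <- sort(unique(edges$gene_id))
  edges <- data.frame(mirna_id = edges$mirna_id, gene_id = edges$gene_id,
                      phase = rep(phase, nrow(edges)),
                      n_sites = edges$n_sites, row.names = NULL)
  coverage <- if (length(de_opp)) length(targets) / length(de_opp) else NA_real_

  mirna_median <- if (length(mirnas)) median_class_profile(mirna_calls, mirnas)
                  else NULL
  target_median <- if (length(targets)) median_class_profile(mrna_calls, targets)
                   else NULL
  r <- if (!is.null(mirna_median) && !is.null(target_median) &&
           stats::sd(mirna_median) > 0 && stats::sd(target_median) > 0)
    stats::cor(mirna_median, target_median) else NA_real_

  structure(list(phase = phase, mirna_direction = mirna_direction,
                 mirnas = mirnas, target_genes = targets, edges = edges,
                 de_opposite_genes = de_opp,
                 coverage_fraction = coverage,
                 mirna_median = mirna_median, target_median = target_median,
                 median_profile_r = r),
            class = "phase_pairing")
}

#' @export
print.phase_pairing <- function(x, ...) {
  cat(sprintf("phase_pairing %s/%s-miRNAs: %d miRNAs -> %d target genes (%d edges), coverage %.1f%%, median-profile r = %s\n",
              x$phase, x$mirna_direction, length(x$mirnas),
              length(x$target_genes), nrow(x$edges),
              100 * x$coverage_fraction,
              ifelse(is.na(x$median_profile_r), "NA",
                     sprintf("%.3f", x$median_profile_r))))
  invisible(x)
}

#' Summarise the four phase pairings
#'
#' Per-phase target totals are unions over that phase's up- and
#' down-direction pairings; the cross-phase overlap is the intersection of
#' the early and late target sets, expressed as a percentage (one decimal)
#' of the sum of the two phase totals.
#'
#' @param pairings list of `phase_pairing` objects (typically all four).
#' @return list with `per_pairing` (data.frame: class, n_mirnas, n_targets,
#'   n_edges, coverage_percent, median_profile_r), `phase_totals`,
#'   `overlap_count`, `overlap_percent`.
#' @export
pairing_summary <- function(pairings) {
  per <- do.call(rbind, lapply(pairings, function(p) {
    data.frame(class = paste(p$phase, p$mirna_direction, sep = "_"),
               n_mirnas = length(p$mirnas),
               n_targets = length(p$target_genes),
               n_edges = nrow(p$edges),
               n_de_opposite = length(p$de_opposite_genes),
               coverage_percent = round(100 * p$coverage_fraction),
               median_profile_r = p$median_profile_r)
  }))
  rownames(per) <- NULL
  phase_of <- vapply(pairings, `[[`, "", "phase")
  tg <- function(ph) sort(unique(unlist(
    lapply(pairings[phase_of == ph], `[[`, "target_genes"))))
  early <- tg("early"); late <- tg("late")
  ov <- length(intersect(early, late))
  denom <- length(early) + length(late)
  list(per_pairing = per,
       phase_totals = c(early = length(early), late = length(late)),
       overlap_count = ov,
       overlap_percent = if (denom) round(100 * ov / denom, 1) else NA_real_,
       early_targets = early, late_targets = late)
}
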