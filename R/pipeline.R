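#' Pipeline run configuration
#'
#' Collects the inputs and every stage threshold. Inputs may be file paths
#' (read with the package readers) or already-loaded objects; a simulated
#' dataset from [simulate_dataset()] can be passed directly as `sim`.
#'
#' @param mrna probe-level expression (path or [expression_matrix()]).
#' @param mirna_ct miRNA Ct table (path or matrix incl. reference row).
#' @param annotation probe-to-gene map (path or data.frame).
#' @param utrs,mirna_seqs sequences (paths or named character vectors).
#' @param coords miRNA coordinates (path or data.frame); optional.
#' @param gene_sets GMT gene sets (path or `gene_set_collection`); optional.
#' @param sim optional simulated dataset supplying all of the above.
#' @param fc_mrna,fc_mirna linear fold-change thresholds.
#' @param alpha ANOVA significance cutoff.
#' @param min_timepoints_mirna modulated-time-point rule for miRNAs.
#' @param r_min,n_permutations template-matching thresholds.
#' @param site_types seed-site types retained by the scanner.
#' @param window_bp genomic cluster chaining window.
#' @param top_k_mirna,top_k_gene ranking depths.
#' @param rng_seed seed for the permutation test.
#' @param out_dir optional directory for stage output files.
#' @return a `run_config` list.
#' @export
run_config <- function(mrna = NULL, mirna_ct = NULL, annotation = NULL,
                       utrs = NULL, mirna_seqs = NULL, coords = NULL,
                       gene_sets = NULL, sim = NULL,
                       fc_mrna = 1.25, fc_mirna = 2.0, alpha = 0.05,
                       min_timepoints_mirna = 2L,
                       r_min = 0.8, n_permutations = 10000L,
                       site_types = c("7mer-A1", "7mer-m8", "8mer"),
                       window_bp = 20000, top_k_mirna = 10L,
                       top_k_gene = 12L, rng_seed = 1L, out_dir = NULL) {
  if (!is.null(sim)) {
    mrna <- mrna %||% sim$mrna
    mirna_ct <- mirna_ct %||% sim$mirna_ct
    annotation <- annotation %||% sim$annotation
    utrs <- utrs %||% sim$utrs
    mirna_seqs <- mirna_seqs %||% sim$mirna_seqs
    coords <- coords %||% sim$coords
  }
  for (nm in c("mrna", "mirna_ct", "annotation", "utrs", "mirna_seqs")) {
    v <- get(nm)
    if (is.null(v))
      mirnet_stop("mirnet_bad_config", "run_config: missing input '%s'", nm)
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      mirnet_stop("mirnet_missing_file", "input '%s': file not found: %s",
                  nm, v)
  }
  structure(list(mrna = mrna, mirna_ct = mirna_ct, annotation = annotation,
                 utrs = utrs, mirna_seqs = mirna_seqs, coords = coords,
                 gene_sets = gene_sets, fc_mrna = fc_mrna,
                 fc_mirna = fc_mirna, alpha = alpha,
                 min_timepoints_mirna = as.integer(min_timepoints_mirna),
                 r_min = r_min, n_permutations = as.integer(n_permutations),
                 site_types = site_types, window_bp = window_bp,
                 top_k_mirna = as.integer(top_k_mirna),
                 top_k_gene = as.integer(top_k_gene),
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "run_config")
}

load_stage_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Run the full inference pipeline
#'
#' Executes differential expression (mRNA and miRNA), miRNA temporal
#' classification, seed-site target prediction, the four phase-wise inverse
#' pairings, network construction with rankings, hub detection over the
#' supplied gene sets, genomic miRNA clustering, and (when gene sets are
#' given) over-representation analysis of the phase target lists. The
#' report is identical for identical config and seed. A stage failure
#' aborts with the stage name; outputs of completed stages are retained in
#' `out_dir` when one is configured.
#'
#' @param config a [run_config()].
#' @return a `mirnet_report` list; see the elements it prints.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "mirnet_stage_error")) stop(e)
      mirnet_stop(c("mirnet_stage_error"), "stage '%s' failed: %s",
                  name, conditionMessage(e))
    })
  }
  out_dir <- config$out_dir
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      writer(obj, file.path(out_dir, file))
    }
  }

  ## inputs
  mrna_probes <- stage("read_mrna",
    load_stage_input(config$mrna, read_expression_tsv))
  mirna_em <- stage("read_mirna", {
    x <- config$mirna_ct
    if (is.character(x) && length(x) == 1L)
      read_expression_tsv(x, layout = "ct_with_reference")
    else if (is.matrix(x)) {
      ref <- x["U6", ]
      expression_matrix(sweep(-x[setdiff(rownames(x), "U6"), , drop = FALSE],
                              2L, ref, `+`))
    } else x
  })
  annotation <- stage("read_annotation",
    load_stage_input(config$annotation, read_annotation_tsv))
  utrs <- stage("read_utrs", load_stage_input(config$utrs, read_fasta))
  mirna_seqs <- stage("read_mirnas",
    load_stage_input(config$mirna_seqs, read_fasta))
  coords <- stage("read_bed", if (is.null(config$coords)) NULL
                  else load_stage_input(config$coords, read_bed))
  gene_sets <- stage("read_gmt", if (is.null(config$gene_sets)) NULL
                     else load_stage_input(config$gene_sets, read_gmt))

  ## differential expression
  mrna <- stage("collapse_probes", collapse_probes(mrna_probes, annotation))
  mrna_calls <- stage("diffexp_mrna", {
    calls <- call_fold_changes(mrna, config$fc_mrna)
    apply_modulation_rule(calls, anova_time_course(mrna),
                          min_timepoints = 1L, alpha = config$alpha)
  })
  mirna_calls <- stage("diffexp_mirna", {
    calls <- call_fold_changes(mirna_em, config$fc_mirna)
    apply_modulation_rule(calls, suppressWarnings(anova_time_course(mirna_em)),
                          min_timepoints = config$min_timepoints_mirna,
                          alpha = config$alpha)
  })
  emit(mrna_calls, "mrna_calls.tsv",
       function(o, f) utils::write.table(as.data.frame(o), f, sep = "\t",
                                         quote = FALSE, row.names = FALSE))
  emit(mirna_calls, "mirna_calls.tsv",
       function(o, f) utils::write.table(as.data.frame(o), f, sep = "\t",
                                         quote = FALSE, row.names = FALSE))

  ## temporal classification of miRNAs
  assignments <- stage("classify", {
    prof <- replicate_log2fc(mirna_em)
    match_templates(prof, r_min = config$r_min,
                    n_permutations = config$n_permutations,
                    alpha = config$alpha, rng_seed = config$rng_seed,
                    calls = mirna_calls)
  })
  emit(assignments, "classes.tsv",
       function(o, f) utils::write.table(o, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE))
  class_sizes <- table(factor(assignments$class,
                              levels = c("early_up", "early_down",
                                         "late_up", "late_down")))

  ## target prediction
  predictions <- stage("predict", {
    sites <- scan_seed_sites(mirna_seqs, utrs, site_types = config$site_types)
    as_prediction_table(sites)
  })
  emit(predictions, "predictions.tsv",
       function(o, f) utils::write.table(as.data.frame(o), f, sep = "\t",
                                         quote = FALSE, row.names = FALSE))

  ## phase-wise inverse pairing
  pairings <- stage("pair", {
    combos <- expand.grid(phase = c("early", "late"),
                          dir = c("up", "down"), stringsAsFactors = FALSE)
    ps <- lapply(seq_len(nrow(combos)), function(i)
      suppressWarnings(pair_phase(assignments, mirna_calls, mrna_calls,
                                  predictions, combos$phase[i],
                                  combos$dir[i])))
    names(ps) <- paste(combos$phase, combos$dir, sep = "_")
    ps
  })
  psum <- pairing_summary(pairings)
  for (nm in names(pairings))
    emit(pairings[[nm]], paste0("edges_", nm, ".tsv"),
         function(o, f) utils::write.table(o$edges, f, sep = "\t",
                                           quote = FALSE, row.names = FALSE))

  ## network layer
  network <- stage("network", build_network(pairings))
  top_mirnas <- rank_top(network, "miRNA", config$top_k_mirna)
  top_genes <- rank_top(network, "gene", config$top_k_gene)
  emit(network, "network.sif", function(o, f) write_network(o, f, "sif"))
  emit(network, "network_edges.tsv",
       function(o, f) write_network(o, f, "edge_tsv"))
  hubs <- stage("hubs", if (is.null(gene_sets)) NULL else
    lapply(gene_sets, function(gg)
      extract_hub_subnetwork(network, gg)))
  clusters <- stage("clusters", if (is.null(coords)) NULL else
    cluster_mirnas(coords, config$window_bp))

  ## enrichment of the phase target lists
  enrichment <- stage("enrich", {
    if (is.null(gene_sets)) NULL else {
      universe <- rownames(mrna$values)
      list(early = enrich(psum$early_targets, gene_sets, universe),
           late = enrich(psum$late_targets, gene_sets, universe))
    }
  })

  bands <- band_fold_changes(mirna_calls)
  summary <- summarize_counts(
    class_sizes = stats::setNames(as.integer(class_sizes), names(class_sizes)),
    de_counts = mrna_phase_direction_counts(mrna_calls),
    target_counts = stats::setNames(psum$per_pairing$n_targets,
                                    psum$per_pairing$class),
    overlap = psum$overlap_count,
    band_counts = stats::setNames(bands$count, bands$band),
    band_total = attr(bands, "total"))

  structure(list(summary = summary, class_sizes = class_sizes,
                 pairing_summary = psum, bands = bands,
                 top_mirnas = top_mirnas, top_genes = top_genes,
                 hubs = hubs, clusters = clusters, enrichment = enrichment,
                 assignments = assignments, network = network,
                 pairings = pairings, mrna_calls = mrna_calls,
                 mirna_calls = mirna_calls, config = config),
            class = "mirnet_report")
}

# mRNA counts per phase x direction: DE (passing) genes called in that
# direction at >= 1 time point of the phase; a gene may belong to both an
# early and a late group.
mrna_phase_direction_counts <- function(mrna_calls) {
  ph <- phase_times(mrna_calls$time_points)
  pass <- mrna_calls$passes_filter
  out <- c(early_down = 0L, early_up = 0L, late_down = 0L, late_up = 0L)
  for (p in names(ph)) for (d in c("down", "up")) {
    dirm <- mrna_calls$direction[, as.character(ph[[p]]), drop = FALSE]
    out[paste(p, d, sep = "_")] <- sum(pass & rowSums(dirm == d) > 0)
  }
  out
}

#' Summary-count arithmetic of the reporting layer
#'
#' Derives every printed summary number from raw counts: the total
#' classified miRNAs, per-phase target totals, target coverage of each
#' phase/direction DE gene group (nearest integer percent), the cross-phase
#' overlap as a percentage (one decimal) of the sum of the two phase
#' totals, and fold-change band percentages of the class total (truncated
#' to whole percent, so bands never over-count the total). Zero
#' denominators yield `NA` percentages.
#'
#' @param class_sizes named counts for `early_up, early_down, late_up,
#'   late_down` miRNA classes.
#' @param de_counts named DE mRNA counts per `phase_direction` group.
#' @param target_counts named target counts per miRNA class (targets of
#'   `early_up` miRNAs are `early_down` genes, etc.).
#' @param overlap number of genes in both the early and late target sets.
#' @param band_counts named counts `up_3fold, up_2to3fold, down_2fold`.
#' @param band_total denominator for band percentages (defaults to the sum
#'   of `class_sizes`).
#' @return list: `mirna_total`, `phase_totals`, `coverage_percent`,
#'   `overlap_percent`, `band_percent`.
#' @export
summarize_counts <- function(class_sizes, de_counts = NULL,
                             target_counts = NULL, overlap = NULL,
                             band_counts = NULL, band_total = NULL) {
  if (any(class_sizes < 0))
    mirnet_stop("mirnet_bad_input", "counts must be non-negative")
  out <- list(mirna_total = sum(class_sizes))
  pct <- function(num, den, digits = 0) {
    ifelse(den > 0, round(100 * num / den, digits), NA_real_)
  }
  if (!is.null(target_counts)) {
    out$phase_totals <- c(
      early = sum(target_counts[c("early_up", "early_down")]),
      late = sum(target_counts[c("late_up", "late_down")]))
    if (!is.null(de_counts)) {
      # targets of up-miRNAs are the down genes of the phase and vice versa
      opposite <- c(early_up = "early_down", early_down = "early_up",
                    late_up = "late_down", late_down = "late_up")
      cls <- names(target_counts)
      out$coverage_percent <- stats::setNames(
        pct(target_counts, de_counts[opposite[cls]]), cls)
    }
    if (!is.null(overlap)) {
      denom <- sum(out$phase_totals)
      out$overlap_count <- overlap
      out$overlap_percent <- if (denom > 0) round(100 * overlap / denom, 1)
                             else NA_real_
    }
  }
  if (!is.null(band_counts)) {
    tot <- band_total %||% out$mirna_total
    out$band_percent <- if (tot > 0)
      stats::setNames(floor(100 * band_counts / tot), names(band_counts))
    else stats::setNames(rep(NA_real_, length(band_counts)),
                         names(band_counts))
  }
  out
}

#' @export
print.mirnet_report <- function(x, ...) {
  s <- x$summary
  cat("miRNA:mRNA time-course inference report\n")
  cat(sprintf("  classified miRNAs: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes),
                    collapse = ", "), s$mirna_total))
  cat(sprintf("  phase target totals: early=%d late=%d (overlap %d, %.1f%%)\n",
              s$phase_totals["early"], s$phase_totals["late"],
              s$overlap_count, s$overlap_percent))
  cat(sprintf("  fold-change bands: %s\n",
              paste(sprintf("%s=%d (%d%%)", x$bands$band, x$bands$count,
                            x$bands$percent), collapse = ", ")))
  if (nrow(x$top_mirnas) && nrow(x$top_genes))
    cat(sprintf("  network: %d edges; top miRNA %s (%d targets); top gene %s (%d regulators)\n",
                nrow(x$network$edges), x$top_mirnas$id[1],
                x$top_mirnas$total[1], x$top_genes$id[1],
                x$top_genes$total[1]))
  if (!is.null(x$clusters) && nrow(x$clusters))
    cat(sprintf("  genomic clusters: %s\n",
                paste(sprintf("%s[%s]", x$clusters$chrom, x$clusters$members),
                      collapse = "; ")))
  invisible(x)
}
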