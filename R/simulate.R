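#' Simulation configuration
#'
#' Parameters of the coupled miRNA/mRNA time-course generator. Defaults
#' emulate a growth-factor induction experiment profiled at 0, 2, 4, 12 and
#' 24 h in biological duplicate: 204 miRNAs of which 50/16/36/29 follow the
#' early-up/early-down/late-up/late-down response shapes and 73 stay flat,
#' a ~2.8-fold (1.5 log2 units) miRNA modulation at the active time points,
#' and per-seed-site target repression of 0.6 log2 units transferred
#' proportionally to the regulator's deviation.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_mirnas number of miRNAs.
#' @param time_points_h strictly increasing time grid starting at 0 (hours).
#' @param n_replicates replicates per time point.
#' @param class_proportions named fractions over
#'   `early_up, early_down, late_up, late_down, flat`; must sum to 1.
#' @param mirna_effect_log2 miRNA deviation at active time points (log2).
#' @param direct_mrna_effect_log2 magnitude of miRNA-independent direct mRNA
#'   effects (log2).
#' @param repression_log2_per_site repression transferred to a target per
#'   seed site per log2 unit of miRNA deviation.
#' @param targets_per_mirna range (length 1 or 2) of planted targets per
#'   miRNA.
#' @param sites_per_edge range of seed sites planted per edge.
#' @param utr_length_nt simulated 3'-UTR length.
#' @param direct_effect_fraction fraction of genes given a direct
#'   (miRNA-independent) effect; drawn from genes without planted sites so
#'   a direct effect can never mask a planted inversion.
#' @param dup_probe_fraction fraction of genes interrogated by two probes.
#' @param noise_sd_log2 Gaussian measurement noise SD on the mRNA log2 scale.
#' @param ct_noise_sd Gaussian noise SD on the miRNA Ct scale.
#' @param rng_seed integer seed making the whole dataset reproducible.
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_mirnas = 204L,
                              time_points_h = c(0, 2, 4, 12, 24),
                              n_replicates = 2L,
                              class_proportions = c(early_up = 50, early_down = 16,
                                                    late_up = 36, late_down = 29,
                                                    flat = 73) / 204,
                              mirna_effect_log2 = 1.5,
                              direct_mrna_effect_log2 = 1.0,
                              repression_log2_per_site = 0.6,
                              targets_per_mirna = c(5L, 15L),
                              sites_per_edge = c(1L, 3L),
                              utr_length_nt = 1000L,
                              direct_effect_fraction = 0.1,
                              dup_probe_fraction = 0.1,
                              noise_sd_log2 = 0.2,
                              ct_noise_sd = 0.2,
                              rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              time_points_h = time_points_h,
              n_replicates = as.integer(n_replicates),
              class_proportions = class_proportions,
              mirna_effect_log2 = mirna_effect_log2,
              direct_mrna_effect_log2 = direct_mrna_effect_log2,
              repression_log2_per_site = repression_log2_per_site,
              targets_per_mirna = as.integer(range(targets_per_mirna)),
              sites_per_edge = as.integer(range(sites_per_edge)),
              utr_length_nt = as.integer(utr_length_nt),
              direct_effect_fraction = direct_effect_fraction,
              dup_probe_fraction = dup_probe_fraction,
              noise_sd_log2 = noise_sd_log2, ct_noise_sd = ct_noise_sd,
              rng_seed = as.integer(rng_seed))
  for (f in c("n_genes", "n_mirnas", "n_replicates", "utr_length_nt"))
    if (!is_count(cfg[[f]]))
      mirnet_stop("mirnet_bad_config", "%s must be a count >= 1", f)
  want <- c("early_up", "early_down", "late_up", "late_down", "flat")
  if (!setequal(names(cfg$class_proportions), want))
    mirnet_stop("mirnet_bad_config",
                "class_proportions must be named over: %s",
                paste(want, collapse = ", "))
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    mirnet_stop("mirnet_bad_config", "class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0))
    mirnet_stop("mirnet_bad_config", "class_proportions must be non-negative")
  tp <- cfg$time_points_h
  if (length(tp) < 3L || tp[1L] != 0 || any(diff(tp) <= 0))
    mirnet_stop("mirnet_bad_config",
                "time_points_h must be strictly increasing and start at 0")
  for (f in c("mirna_effect_log2", "direct_mrna_effect_log2",
              "repression_log2_per_site", "noise_sd_log2", "ct_noise_sd"))
    if (cfg[[f]] < 0)
      mirnet_stop("mirnet_bad_config", "%s must be >= 0", f)
  if (cfg$targets_per_mirna[2L] > cfg$n_genes)
    mirnet_stop("mirnet_infeasible_config",
                "targets_per_mirna (up to %d) exceeds n_genes (%d)",
                cfg$targets_per_mirna[2L], cfg$n_genes)
  structure(cfg, class = "simulation_config")
}

# deviation of each class over the post-treatment grid, in log2 units
class_deviation <- function(classes, post_times, effect) {
  tm <- default_templates(post_times)
  tm <- rbind(tm, flat = numeric(length(post_times)))
  tm[classes, , drop = FALSE] * effect
}

# site sequence implied by a miRNA's seed and a site type, UTR sense strand
planted_site_seq <- function(mirna_seq, type) {
  core6 <- revcomp(substr(mirna_seq, 2L, 7L))
  m8c <- complement_base(substr(mirna_seq, 8L, 8L))
  switch(type,
         "6mer" = core6,
         "7mer-A1" = paste0(core6, "A"),
         "7mer-m8" = paste0(m8c, core6),
         "8mer" = paste0(m8c, core6, "A"))
}

#' Simulate a coupled miRNA/mRNA time-course dataset
#'
#' Generates, reproducibly from `rng_seed`, every input the pipeline
#' consumes plus a ground-truth table:
#' \itemize{
#'   \item miRNA log2 profiles following their planted class template
#'     (early classes deviate at the first two post-treatment time points
#'     and return to baseline; late classes deviate at the last two),
#'     exported as a qPCR Ct matrix (`Ct = Ct_ref - log2(abundance)` plus Ct
#'     noise) with a constant reference row named `"U6"`.
#'   \item mRNA log2 abundances: baseline, minus
#'     `repression_log2_per_site * n_sites` times the regulator's deviation
#'     (sign-preserving, additive across regulators), plus any direct
#'     effect, plus Gaussian noise; probe-level, with a fraction of genes
#'     carried by two probes.
#'   \item random-background 3'-UTRs with the planted seed sites inserted
#'     at recorded positions; mature miRNA sequences with unique seed
#'     hexamers; a 6-column BED of miRNA loci including one planted genomic
#'     cluster of three miRNAs on chr6 (neighbouring loci ~12.7 kb apart).
#'   \item `truth`: per-miRNA classes, planted edges with site counts and
#'     types, direct-effect genes, and background ("incidental") seed sites
#'     detected in the finished UTRs but not planted.
#' }
#' Direct effects are only assigned to genes without planted sites, so a
#' direct effect can never mask a planted inverse correlation. Flat-class
#' miRNAs keep their planted sites but exert no repression, providing
#' negatives for recovery metrics.
#'
#' @param config a [simulation_config()].
#' @return list with elements `mrna` ([expression_matrix()], probe level),
#'   `mirna_ct` (matrix incl. the `U6` row), `utrs`, `mirna_seqs`,
#'   `coords`, `annotation`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  set.seed(config$rng_seed)
  tp <- config$time_points_h
  post <- tp[-1L]
  nrep <- config$n_replicates
  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  mirnas <- sprintf("miR-sim-%03d", seq_len(config$n_mirnas))

  ## temporal classes
  want <- c("early_up", "early_down", "late_up", "late_down", "flat")
  counts <- floor(config$class_proportions[want] * config$n_mirnas)
  rem <- config$n_mirnas - sum(counts)
  if (rem > 0) {  # largest-remainder rounding
    fr <- config$class_proportions[want] * config$n_mirnas - counts
    counts[order(-fr)[seq_len(rem)]] <- counts[order(-fr)[seq_len(rem)]] + 1L
  }
  classes <- sample(rep(want, counts))
  names(classes) <- mirnas
  dev <- class_deviation(classes, post, config$mirna_effect_log2)
  rownames(dev) <- mirnas

  ## mature miRNA sequences with unique seed hexamers
  seqs <- character(config$n_mirnas)
  seen <- character(0)
  for (i in seq_len(config$n_mirnas)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), 22L, replace = TRUE),
                 collapse = "")
      core <- substr(s, 2L, 7L)
      if (!core %in% seen) { seen <- c(seen, core); seqs[i] <- s; break }
    }
  }
  names(seqs) <- mirnas

  ## planted edges
  k <- if (config$targets_per_mirna[1L] == config$targets_per_mirna[2L])
    rep(config$targets_per_mirna[1L], config$n_mirnas)
  else sample(config$targets_per_mirna[1L]:config$targets_per_mirna[2L],
              config$n_mirnas, replace = TRUE)
  # No-masking constraint, applied at generation: a gene may be shared by
  # several regulators, but never by an up- and a down-miRNA acting in the
  # same phase (their repression/derepression would cancel and mask the
  # planted inversion). Each gene is pre-assigned the regulator direction it
  # accepts per phase; flat miRNAs exert no effect and may target any gene.
  early_label <- sample(c("up", "down"), config$n_genes, replace = TRUE)
  late_label <- sample(c("up", "down"), config$n_genes, replace = TRUE)
  pool_for <- function(cls) {
    switch(cls,
           early_up = genes[early_label == "up"],
           early_down = genes[early_label == "down"],
           late_up = genes[late_label == "up"],
           late_down = genes[late_label == "down"],
           flat = genes)
  }
  if (config$targets_per_mirna[2L] > min(sum(early_label == "up"),
                                         sum(early_label == "down"),
                                         sum(late_label == "up"),
                                         sum(late_label == "down")))
    mirnet_stop("mirnet_infeasible_config",
                "targets_per_mirna too large for the phase-compatible gene pools")
  edges <- do.call(rbind, lapply(seq_len(config$n_mirnas), function(i) {
    data.frame(mirna_id = mirnas[i],
               gene_id = sample(pool_for(classes[i]), k[i]),
               n_sites = sample(seq(config$sites_per_edge[1L],
                                    config$sites_per_edge[2L]),
                                k[i], replace = TRUE))
  }))
  plant_types <- c("7mer-A1", "7mer-m8", "8mer")
  site_rows <- edges[rep(seq_len(nrow(edges)), edges$n_sites),
                     c("mirna_id", "gene_id")]
  site_rows$site_type <- sample(plant_types, nrow(site_rows), replace = TRUE)

  ## UTRs: random background, sites inserted into disjoint 10-nt slots
  slot <- 10L
  n_slots <- config$utr_length_nt %/% slot
  per_gene <- table(factor(site_rows$gene_id, levels = genes))
  if (any(per_gene > n_slots))
    mirnet_stop("mirnet_infeasible_config",
                "utr_length_nt %d too short for up to %d planted sites per gene",
                config$utr_length_nt, max(per_gene))
  utrs <- vapply(seq_len(config$n_genes), function(i)
    paste(sample(c("A", "C", "G", "T"), config$utr_length_nt, replace = TRUE),
          collapse = ""), character(1))
  names(utrs) <- genes
  site_rows <- site_rows[order(site_rows$gene_id), , drop = FALSE]
  site_rows$utr_start <- NA_integer_
  site_rows$utr_end <- NA_integer_
  site_rows$sequence <- NA_character_
  for (g in unique(site_rows$gene_id)) {
    ix <- which(site_rows$gene_id == g)
    slots <- sample(n_slots, length(ix))
    u <- utrs[[g]]
    for (j in seq_along(ix)) {
      sseq <- planted_site_seq(seqs[[site_rows$mirna_id[ix[j]]]],
                               site_rows$site_type[ix[j]])
      off <- sample.int(slot - nchar(sseq) - 1L, 1L)  # keep a guard base
      start0 <- (slots[j] - 1L) * slot + off
      substr(u, start0 + 1L, start0 + nchar(sseq)) <- sseq
      site_rows$utr_start[ix[j]] <- start0
      site_rows$utr_end[ix[j]] <- start0 + nchar(sseq)
      site_rows$sequence[ix[j]] <- sseq
    }
    utrs[[g]] <- u
  }
  rownames(site_rows) <- NULL

  ## direct (miRNA-independent) effects on genes without planted sites
  free_genes <- setdiff(genes, unique(edges$gene_id))
  n_direct <- min(length(free_genes),
                  round(config$direct_effect_fraction * config$n_genes))
  direct <- data.frame(gene_id = character(0), phase = character(0),
                       direction = character(0))
  if (n_direct > 0) {
    direct <- data.frame(gene_id = sample(free_genes, n_direct),
                         phase = sample(c("early", "late"), n_direct,
                                        replace = TRUE),
                         direction = sample(c("up", "down"), n_direct,
                                            replace = TRUE))
  }

  ## gene-level log2 signal over the post grid
  sig <- matrix(0, config$n_genes, length(post),
                dimnames = list(genes, as.character(post)))
  for (i in seq_len(nrow(edges))) {
    g <- edges$gene_id[i]
    sig[g, ] <- sig[g, ] - config$repression_log2_per_site *
      edges$n_sites[i] * dev[edges$mirna_id[i], ]
  }
  ph <- phase_times(post)
  if (nrow(direct)) for (i in seq_len(nrow(direct))) {
    cols <- as.character(ph[[direct$phase[i]]])
    sgn <- if (direct$direction[i] == "up") 1 else -1
    sig[direct$gene_id[i], cols] <- sig[direct$gene_id[i], cols] +
      sgn * config$direct_mrna_effect_log2
  }

  ## probe-level matrix (a fraction of genes carried by two probes)
  gene_base <- stats::runif(config$n_genes, 6, 12)
  n_dup <- round(config$dup_probe_fraction * config$n_genes)
  dup_genes <- if (n_dup) sample(genes, n_dup) else character(0)
  probes <- c(paste0(genes, "_at"), paste0(dup_genes, "_b_at"))
  probe_gene <- c(genes, dup_genes)
  annotation <- data.frame(probe_id = probes, gene_symbol = probe_gene)
  sample_time <- rep(tp, each = nrep)
  sample_rep <- rep(seq_len(nrep), length(tp))
  sample_ids <- format_sample_ids(sample_time, sample_rep)
  full_sig <- cbind(0, sig)[, match(as.character(sample_time),
                                    c("0", colnames(sig)))]
  vals <- gene_base[match(probe_gene, genes)] + full_sig[match(probe_gene, genes), ] +
    matrix(stats::rnorm(length(probes) * length(sample_ids),
                        sd = config$noise_sd_log2),
           length(probes), length(sample_ids))
  dimnames(vals) <- list(probes, sample_ids)
  mrna <- expression_matrix(vals)

  ## miRNA Ct matrix with fixed U6 reference row
  mirna_base <- stats::runif(config$n_mirnas, 3, 7)
  mirna_log2 <- mirna_base + cbind(0, dev)[, match(as.character(sample_time),
                                                   c("0", colnames(dev)))]
  ct_ref <- 20
  ct <- ct_ref - mirna_log2 +
    matrix(stats::rnorm(length(mirna_log2), sd = config$ct_noise_sd),
           nrow(mirna_log2), ncol(mirna_log2))
  ct <- rbind(ct, U6 = rep(ct_ref, ncol(ct)))
  dimnames(ct) <- list(c(mirnas, "U6"), sample_ids)

  ## genomic coordinates: one planted chr6 cluster, the rest well separated
  cluster_members <- mirnas[seq_len(min(3L, config$n_mirnas))]
  coords <- data.frame(chrom = character(config$n_mirnas),
                       start = integer(config$n_mirnas),
                       end = integer(config$n_mirnas),
                       name = mirnas, score = 0L,
                       strand = sample(c("+", "-"), config$n_mirnas,
                                       replace = TRUE))
  offs <- c(0L, 5000L, 12700L)[seq_along(cluster_members)]
  coords$chrom[seq_along(cluster_members)] <- "chr6"
  coords$start[seq_along(cluster_members)] <- 1000000L + offs
  rest <- setdiff(seq_len(config$n_mirnas), seq_along(cluster_members))
  if (length(rest)) {
    coords$chrom[rest] <- paste0("chr", sample(1:20, length(rest),
                                               replace = TRUE))
    # one 100-kb bin per locus so no accidental cluster can form
    coords$start[rest] <- 2000000L + seq_along(rest) * 100000L +
      sample.int(50000L, length(rest))
  }
  coords$end <- coords$start + 22L

  ## incidental (background) pairs: sites detected in the final UTRs for
  ## miRNA:gene pairs that were never planted
  found <- scan_seed_sites(seqs, utrs)
  planted_pairs <- paste(edges$mirna_id, edges$gene_id)
  incidental <- found[!paste(found$mirna_id, found$gene_id) %in%
                        planted_pairs, , drop = FALSE]
  rownames(incidental) <- NULL

  edge_truth <- edges
  edge_truth$site_types <- vapply(
    split(site_rows$site_type,
          paste(site_rows$mirna_id, site_rows$gene_id, sep = "\r"))[
            paste(edges$mirna_id, edges$gene_id, sep = "\r")],
    paste, character(1), collapse = ",")
  edge_truth$mirna_class <- unname(classes[edge_truth$mirna_id])
  rownames(edge_truth) <- NULL

  list(mrna = mrna, mirna_ct = ct, utrs = utrs, mirna_seqs = seqs,
       coords = coords, annotation = annotation,
       truth = list(mirna_classes = classes, edges = edge_truth,
                    sites = site_rows, gene_direct_effects = direct,
                    incidental_sites = incidental,
                    cluster_members = cluster_members),
       config = config)
}

#' Write a simulated dataset as a fixture bundle
#'
#' Emits every file in the formats the readers expect (expression TSVs at
#' full precision, FASTA with the miRNA records in the RNA alphabet, 6-column
#' BED, truth TSVs) and returns a manifest of paths and MD5 checksums.
#' Reading the bundle back reproduces the matrices bit-exactly, and two runs
#' from the same `rng_seed` produce identical manifests.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return data.frame manifest: `file`, `md5`.
#' @export
write_fixture_bundle <- function(sim, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    mirnet_stop("mirnet_unwritable", "cannot write to directory: %s", dir)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(sim$mrna, p("mrna_log2.tsv"), id_col = "probe_id")
  ct <- apply(sim$mirna_ct, 2L, format_full)
  utils::write.table(cbind(mirna_id = rownames(sim$mirna_ct), ct),
                     p("mirna_ct.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(sim$utrs, p("utrs.fa"))
  write_fasta(chartr("T", "U", sim$mirna_seqs), p("mirnas.fa"))
  write_bed(sim$coords, p("mirna_coords.bed"))
  utils::write.table(sim$truth$edges, p("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mirna_id = names(sim$truth$mirna_classes),
               class = unname(sim$truth$mirna_classes)),
    p("truth_classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$gene_direct_effects, p("truth_direct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("mrna_log2.tsv", "mirna_ct.tsv", "annotation.tsv", "utrs.fa",
             "mirnas.fa", "mirna_coords.bed", "truth_edges.tsv",
             "truth_classes.tsv", "truth_direct.tsv")
  data.frame(file = files,
             md5 = unname(tools::md5sum(file.path(dir, files))))
}
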