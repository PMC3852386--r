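test_that("zero-effect, zero-noise configs produce constant mRNA profiles", {
  cfg <- simulation_config(n_genes = 50, n_mirnas = 10,
                           targets_per_mirna = c(2, 3),
                           mirna_effect_log2 = 0,
                           direct_mrna_effect_log2 = 0,
                           noise_sd_log2 = 0, rng_seed = 3)
  sim <- simulate_dataset(cfg)
  spread <- apply(sim$mrna$values, 1, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("edge count follows the configured targets per miRNA exactly", {
  sim <- simulate_dataset(simulation_config(n_genes = 100, n_mirnas = 10,
                                            targets_per_mirna = 5,
                                            rng_seed = 11))
  expect_identical(nrow(sim$truth$edges), 50L)
  expect_true(all(table(sim$truth$edges$mirna_id) == 5))
})

test_that("every planted seed site is re-detected by a substring scan of the emitted UTRs", {
  sim <- default_sim(1)
  sites <- sim$truth$sites
  # brute-force: compare the UTR substring at every recorded position
  found <- vapply(seq_len(nrow(sites)), function(i) {
    u <- sim$utrs[[sites$gene_id[i]]]
    substr(u, sites$utr_start[i] + 1L, sites$utr_end[i]) ==
      sites$sequence[i]
  }, logical(1))
  expect_identical(mean(found), 1)
})

test_that("planted miRNA:target pairs are perfectly anti-correlated without noise", {
  cfg <- simulation_config(n_genes = 200, n_mirnas = 12,
                           class_proportions = c(early_up = 0.5, early_down = 0,
                                                 late_up = 0, late_down = 0,
                                                 flat = 0.5),
                           targets_per_mirna = c(3, 5),
                           noise_sd_log2 = 0, ct_noise_sd = 0, rng_seed = 5)
  sim <- simulate_dataset(cfg)
  post <- sim$mrna$sample_meta$time_h != 0
  active <- sim$truth$edges[sim$truth$edges$mirna_class != "flat", ]
  for (i in seq_len(nrow(active))) {
    mp <- 20 - sim$mirna_ct[active$mirna_id[i], post]
    gp <- sim$mrna$values[paste0(active$gene_id[i], "_at"), post]
    expect_equal(stats::cor(mp, gp), -1, tolerance = 1e-12)
  }
  # flat regulators exert no effect: their targets stay constant unless
  # another (active) regulator also hits them
  flat_only <- setdiff(sim$truth$edges$gene_id[sim$truth$edges$mirna_class == "flat"],
                       active$gene_id)
  flat_only <- setdiff(flat_only, sim$truth$gene_direct_effects$gene_id)
  spread <- apply(sim$mrna$values[paste0(flat_only, "_at"), , drop = FALSE],
                  1, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("replicate residual spread matches the configured noise SD", {
  sim <- default_sim(1)
  v <- sim$mrna$values
  meta <- sim$mrna$sample_meta
  resid <- unlist(lapply(unique(meta$time_h), function(tp) {
    cols <- which(meta$time_h == tp)
    (v[, cols[1]] - v[, cols[2]]) / sqrt(2)
  }))
  expect_equal(stats::sd(resid), sim$config$noise_sd_log2, tolerance = 0.1)
})

test_that("identical seeds reproduce the dataset and its manifest bit-exactly", {
  cfg <- simulation_config(n_genes = 80, n_mirnas = 12,
                           targets_per_mirna = c(2, 4), rng_seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$mrna$values, s2$mrna$values)
  expect_identical(s1$mirna_ct, s2$mirna_ct)
  expect_identical(s1$utrs, s2$utrs)
  expect_identical(s1$truth$edges, s2$truth$edges)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(s1, d1)
  m2 <- write_fixture_bundle(s2, d2)
  expect_identical(m1$md5, m2$md5)
})

test_that("fixture bundles round-trip bit-exactly and checksums track content", {
  sim <- simulate_dataset(simulation_config(n_genes = 60, n_mirnas = 8,
                                            targets_per_mirna = c(2, 3),
                                            rng_seed = 9))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(sim, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))

  back <- read_expression_tsv(file.path(dir, "mrna_log2.tsv"))
  expect_identical(back$values, sim$mrna$values)
  mirna_back <- read_expression_tsv(file.path(dir, "mirna_ct.tsv"),
                                    layout = "ct_with_reference")
  expect_equal(mirna_back$values,
               sweep(-sim$mirna_ct[rownames(mirna_back$values), ], 2,
                     sim$mirna_ct["U6", ], `+`),
               tolerance = 1e-12)
  utr_back <- read_fasta(file.path(dir, "utrs.fa"))
  expect_identical(utr_back, sim$utrs)
  mir_back <- read_fasta(file.path(dir, "mirnas.fa"))  # written as RNA
  expect_identical(mir_back, sim$mirna_seqs)

  # checksum changes iff content changes
  f <- file.path(dir, "annotation.tsv")
  before <- unname(tools::md5sum(f))
  cat("probeX\tgeneX\n", file = f, append = TRUE)
  expect_false(identical(unname(tools::md5sum(f)), before))
  m_same <- tools::md5sum(file.path(dir, "utrs.fa"))
  expect_identical(unname(m_same),
                   manifest$md5[manifest$file == "utrs.fa"])
})

test_that("infeasible or invalid configurations fail with named errors", {
  expect_error(simulation_config(n_genes = 5, targets_per_mirna = 10),
               class = "mirnet_infeasible_config")
  expect_error(simulation_config(class_proportions = c(early_up = 0.5,
                                                       early_down = 0.5,
                                                       late_up = 0.5,
                                                       late_down = -0.25,
                                                       flat = -0.25)),
               class = "mirnet_bad_config")
  expect_error(simulation_config(time_points_h = c(2, 4, 12)),
               class = "mirnet_bad_config")
  expect_error(simulation_config(mirna_effect_log2 = -1),
               class = "mirnet_bad_config")
  # UTR too short to host the planted sites
  expect_error(
    simulate_dataset(simulation_config(n_genes = 4, n_mirnas = 20,
                                       targets_per_mirna = 4,
                                       utr_length_nt = 40, rng_seed = 1)),
    class = "mirnet_infeasible_config")
})

test_that("direct effects never land on genes that carry planted sites", {
  sim <- default_sim(1)
  expect_length(intersect(sim$truth$gene_direct_effects$gene_id,
                          sim$truth$edges$gene_id), 0)
  # and no gene accepts opposing same-phase regulators
  ed <- sim$truth$edges[sim$truth$edges$mirna_class != "flat", ]
  ph <- sub("_(up|down)$", "", ed$mirna_class)
  dir <- sub("^(early|late)_", "", ed$mirna_class)
  per_gene <- split(paste(ph, dir), ed$gene_id)
  has_conflict <- vapply(per_gene, function(x) {
    ("early up" %in% x && "early down" %in% x) ||
      ("late up" %in% x && "late down" %in% x)
  }, logical(1))
  expect_false(any(has_conflict))
})
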