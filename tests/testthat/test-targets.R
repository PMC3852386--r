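test_that("the canonical let-7 site is typed as an 8mer at the right coordinates", {
  mir <- c("let7" = "UGAGGUAGUAGGUUGUAUAGUU")
  utr <- c(tgt = "AAACTACCTCAAAA")
  sites <- scan_seed_sites(mir, utr, site_types = c("6mer", "7mer-A1",
                                                    "7mer-m8", "8mer"))
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$site_type, "8mer")
  expect_identical(sites$utr_start, 3L)
  expect_identical(sites$utr_end, 11L)
  expect_identical(sites$matched_sequence, "CTACCTCA")

  # a UTR that cannot pair with the seed yields nothing
  expect_identical(nrow(scan_seed_sites(mir, c(x = "AAAAGGGG"))), 0L)
})

test_that("site widths match their types and typing is maximal", {
  set.seed(101)
  mir <- c(m1 = random_dna(22))
  utr <- c(u1 = random_dna(10000))
  sites <- scan_seed_sites(mir, utr, site_types = c("6mer", "7mer-A1",
                                                    "7mer-m8", "8mer"))
  widths <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
  expect_identical(sites$utr_end - sites$utr_start,
                   unname(widths[sites$site_type]))
  # no site is nested inside another site of the same miRNA
  if (nrow(sites) > 1) {
    for (i in seq_len(nrow(sites))) {
      nested <- sites$utr_start <= sites$utr_start[i] &
        sites$utr_end >= sites$utr_end[i] &
        seq_len(nrow(sites)) != i
      expect_false(any(nested))
    }
  }
})

test_that("the scanner agrees with an exhaustive substring oracle on random 10 kb UTRs", {
  set.seed(17)
  for (rep in 1:3) {
    mir <- c(m = random_dna(22))
    utr <- c(u = random_dna(10000))
    got <- scan_seed_sites(mir, utr, site_types = c("6mer", "7mer-A1",
                                                    "7mer-m8", "8mer"))
    want <- oracle_scan(mir, utr)
    got <- got[order(got$utr_start), c("site_type", "utr_start", "utr_end")]
    want <- want[order(want$utr_start), c("site_type", "utr_start", "utr_end")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("scanning is shift-equivariant and never scans the reverse strand", {
  set.seed(55)
  mir <- c(m = random_dna(22))
  u <- random_dna(3000)
  s0 <- scan_seed_sites(mir, c(u = u))
  shifted <- scan_seed_sites(mir, c(u = paste0(strrep("N", 10), u)))
  expect_identical(shifted$utr_start, s0$utr_start + 10L)
  expect_identical(shifted$site_type, s0$site_type)
  # sites found on the sense strand are not reported for the reverse strand
  rc <- oracle_revcomp(u)
  s_rc <- scan_seed_sites(mir, c(u = rc))
  # the two strands are scanned independently; equality would be coincidence
  expect_false(identical(s_rc$utr_start, s0$utr_start) && nrow(s0) > 0)
})

test_that("miRNAs shorter than 8 nt are rejected by name", {
  err <- expect_error(scan_seed_sites(c(tiny = "ACGTACG"), c(u = "ACGTACGT")),
                      class = "mirnet_short_mirna")
  expect_match(conditionMessage(err), "tiny")
})

test_that("prediction tables aggregate sites and rank the best type", {
  sites <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2"),
    gene_id = c("g1", "g1", "g2", "g1"),
    site_type = c("7mer-A1", "8mer", "6mer", "7mer-m8"),
    utr_start = c(0L, 20L, 5L, 9L), utr_end = c(7L, 28L, 11L, 16L),
    matched_sequence = "N")
  tab <- as_prediction_table(sites)
  expect_identical(nrow(tab), 3L)
  g1m1 <- tab[tab$mirna_id == "m1" & tab$gene_id == "g1", ]
  expect_identical(g1m1$n_sites, 2L)
  expect_identical(g1m1$best_site_type, "8mer")
})

test_that("merging prediction tables follows set semantics", {
  a <- make_predictions(c("m1", "m1", "m2"), c("g1", "g2", "g1"))
  empty <- data.frame(mirna_id = character(), gene_id = character())
  expect_identical(nrow(merge_predictions(a, empty, "union")), 3L)

  b <- data.frame(mirna_id = c("m1", "m3"), gene_id = c("g1", "g9"))
  u <- merge_predictions(a, b, "union")
  expect_identical(nrow(u), 4L)
  expect_identical(u$source[u$mirna_id == "m1" & u$gene_id == "g1"], "both")
  expect_identical(u$source[u$mirna_id == "m3"], "external")
  i <- merge_predictions(a, b, "intersection")
  expect_identical(nrow(i), 1L)

  # |union| = |A| + |B| - |A intersect B| on random tables
  set.seed(20)
  for (rep in 1:5) {
    ka <- paste0("m", sample(4, 8, TRUE), "\rg", sample(5, 8, TRUE))
    ka <- unique(ka)
    kb <- paste0("m", sample(4, 8, TRUE), "\rg", sample(5, 8, TRUE))
    kb <- unique(kb)
    A <- make_predictions(sub("\r.*", "", ka), sub(".*\r", "", ka))
    B <- data.frame(mirna_id = sub("\r.*", "", kb),
                    gene_id = sub(".*\r", "", kb))
    expect_identical(nrow(merge_predictions(A, B, "union")),
                     length(ka) + length(kb) - length(intersect(ka, kb)))
  }
})

test_that("UTR fragmentation assigns sites by start and conserves counts", {
  sites <- data.frame(mirna_id = "m", gene_id = "g",
                      site_type = c("8mer", "7mer-A1"),
                      utr_start = c(3L, 98L), utr_end = c(11L, 105L),
                      matched_sequence = "N")
  fr <- fragment_sites(sites, utr_length = 1500, breakpoints = c(100, 300))
  expect_identical(fr$fragment, c(1L, 1L))
  expect_identical(fr$spans_breakpoint, c(FALSE, TRUE))  # crosses 100

  expect_error(fragment_sites(sites, 1500, c(100, 1600)),
               class = "mirnet_bad_input")
  expect_error(fragment_sites(sites, 1500, c(300, 100)),
               class = "mirnet_bad_input")

  set.seed(33)
  mir <- c(m = random_dna(22))
  utr <- c(u = random_dna(5000))
  all_sites <- scan_seed_sites(mir, utr, site_types = c("6mer", "7mer-A1",
                                                        "7mer-m8", "8mer"))
  fr2 <- fragment_sites(all_sites, 5000, c(800, 1000))
  expect_identical(as.integer(sum(table(fr2$fragment))), nrow(all_sites))
})

test_that("planted edges are always recovered by the scanner", {
  sim <- default_sim(1)
  sites <- scan_seed_sites(sim$mirna_seqs, sim$utrs)
  tab <- as_prediction_table(sites)
  planted <- paste(sim$truth$edges$mirna_id, sim$truth$edges$gene_id)
  expect_true(all(planted %in% paste(tab$mirna_id, tab$gene_id)))
})
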