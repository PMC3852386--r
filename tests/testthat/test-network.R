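pairing_stub <- function(edges) list(edges = edges)

edge_df <- function(mirna, gene, phase = "early", n_sites = 1L) {
  data.frame(mirna_id = mirna, gene_id = gene, phase = phase,
             n_sites = n_sites, stringsAsFactors = FALSE)
}

random_edges <- function(n_mir, n_gene, p = 0.3) {
  grid <- expand.grid(mirna_id = paste0("m", seq_len(n_mir)),
                      gene_id = paste0("g", seq_len(n_gene)),
                      stringsAsFactors = FALSE)
  grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  grid$phase <- sample(c("early", "late"), nrow(grid), TRUE)
  grid$n_sites <- sample(1:3, nrow(grid), TRUE)
  grid
}

test_that("connectivity equals bipartite degrees", {
  net <- build_network(list(pairing_stub(edge_df(c("miR-A", "miR-A", "miR-B"),
                                                 c("g1", "g2", "g2")))))
  gc <- net$gene_connectivity
  mc <- net$mirna_connectivity
  expect_identical(gc$total[gc$id == "g2"], 2L)
  expect_identical(mc$total[mc$id == "miR-A"], 2L)
  empty <- build_network(list(pairing_stub(edge_df(character(0), character(0),
                                                   character(0), integer(0)))))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("degrees match a brute-force recount and satisfy the handshake identity", {
  set.seed(12)
  for (rep in 1:5) {
    e <- random_edges(8, 15)
    net <- build_network(list(pairing_stub(e)))
    pairs <- unique(e[, c("mirna_id", "gene_id")])
    for (m in unique(pairs$mirna_id))
      expect_identical(net$mirna_connectivity$total[net$mirna_connectivity$id == m],
                       as.integer(sum(pairs$mirna_id == m)))
    for (g in unique(pairs$gene_id))
      expect_identical(net$gene_connectivity$total[net$gene_connectivity$id == g],
                       as.integer(sum(pairs$gene_id == g)))
    expect_identical(sum(net$mirna_connectivity$total), nrow(pairs))
    expect_identical(sum(net$gene_connectivity$total), nrow(pairs))
    # phase-split degrees recombine into the distinct-partner total
    both <- merge(net$gene_connectivity,
                  aggregate(mirna_id ~ gene_id, unique(e[, c("mirna_id", "gene_id", "phase")]),
                            function(x) length(unique(x))),
                  by.x = "id", by.y = "gene_id")
    expect_identical(both$total, both$mirna_id)
  }
})

test_that("ranking is stable, tie-broken lexicographically and input-order invariant", {
  e <- edge_df(c("A", "A", "A", "B", "C", "C", "C"),
               c("g1", "g2", "g3", "g1", "g4", "g5", "g6"))
  net <- build_network(list(pairing_stub(e)))
  top <- rank_top(net, "miRNA", 2)
  expect_identical(top$id, c("A", "C"))
  all_nodes <- rank_top(net, "miRNA", 99)
  expect_identical(nrow(all_nodes), 3L)

  set.seed(4)
  e2 <- random_edges(10, 12)
  n1 <- build_network(list(pairing_stub(e2)))
  n2 <- build_network(list(pairing_stub(e2[sample(nrow(e2)), ])))
  expect_identical(rank_top(n1, "gene", 5), rank_top(n2, "gene", 5))
  # full sort oracle
  full <- rank_top(n1, "miRNA", nrow(n1$mirna_connectivity))
  ord <- order(-n1$mirna_connectivity$total, n1$mirna_connectivity$id)
  expect_identical(full$id, n1$mirna_connectivity$id[ord])
})

test_that("hub detection finds co-regulating miRNA sets and matches the exponential oracle", {
  e <- edge_df(c("m1", "m1", "m2", "m2", "m3", "m3"),
               rep(c("g1", "g2"), 3))
  net <- build_network(list(pairing_stub(e)))
  hubs <- extract_hub_subnetwork(net, c("g1", "g2"))
  expect_length(hubs$hubs, 1L)
  expect_identical(hubs$hubs[[1]]$mirnas, c("m1", "m2", "m3"))
  expect_identical(sort(hubs$hubs[[1]]$genes), c("g1", "g2"))

  e2 <- edge_df(c("m1", "m1", "m2", "m2"), rep(c("g1", "g2"), 2))
  net2 <- build_network(list(pairing_stub(e2)))
  expect_length(extract_hub_subnetwork(net2, c("g1", "g2"))$hubs, 0L)

  set.seed(77)
  for (rep in 1:5) {
    e3 <- random_edges(8, 6, p = 0.45)
    if (!nrow(e3)) next
    net3 <- build_network(list(pairing_stub(e3)))
    group <- paste0("g", 1:6)
    got <- lapply(extract_hub_subnetwork(net3, group)$hubs, `[[`, "mirnas")
    want <- oracle_hubs(e3, group)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("hub detection is monotone in the gene group and capped searches fail loudly", {
  set.seed(78)
  e <- random_edges(9, 8, p = 0.4)
  net <- build_network(list(pairing_stub(e)))
  small <- paste0("g", 1:5)
  big <- paste0("g", 1:8)
  h_small <- lapply(extract_hub_subnetwork(net, small)$hubs, `[[`, "mirnas")
  h_big <- lapply(extract_hub_subnetwork(net, big)$hubs, `[[`, "mirnas")
  for (h in h_small) {
    contained <- any(vapply(h_big, function(H) all(h %in% H), logical(1)))
    expect_true(contained)
  }
  expect_error(extract_hub_subnetwork(net, big, max_pairs = 1),
               class = "mirnet_search_overflow")
  expect_error(extract_hub_subnetwork(net, character(0)),
               class = "mirnet_bad_input")
})

test_that("genomic clustering chains neighbours within the window", {
  coords <- data.frame(chrom = "chr6",
                       start = c(0, 5000, 12700),
                       end = c(22, 5022, 12722),
                       name = c("miR-495", "miR-543", "miR-381"),
                       score = 0, strand = "+")
  cl <- cluster_mirnas(coords, 20000)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 3L)
  expect_identical(cl$members, "miR-495,miR-543,miR-381")
  expect_identical(cl$span_bp, 12722 - 0)

  far <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(22, 50022),
                    name = c("a", "b"), score = 0, strand = "+")
  expect_identical(nrow(cluster_mirnas(far, 20000)), 0L)
})

test_that("chaining equals a union-find transitive closure on random layouts", {
  set.seed(90)
  for (rep in 1:5) {
    coords <- data.frame(chrom = paste0("chr", sample(1:3, 20, TRUE)),
                         start = sample(0:200000, 20),
                         name = paste0("mir", 1:20), score = 0, strand = "+")
    coords$end <- coords$start + 22
    got <- cluster_mirnas(coords, 15000)
    got_sets <- lapply(strsplit(got$members, ","), sort)
    want_sets <- oracle_clusters(coords, 15000)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})
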