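# Independent brute-force oracles used to cross-check the implementations.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

# Exhaustive seed-site scan: slide every full site pattern over every offset
# of the UTR by literal substring comparison (pattern-first, in contrast to
# the implementation's core-hit-then-extend strategy).
oracle_scan <- function(mirna_seq, utr, mirna_id = "m", gene_id = "g") {
  m <- chartr("U", "T", toupper(mirna_seq))
  u <- chartr("U", "T", toupper(utr))
  core6 <- oracle_revcomp(substr(m, 2, 7))
  m8c <- chartr("ACGT", "TGCA", substr(m, 8, 8))
  patterns <- list("8mer" = paste0(m8c, core6, "A"),
                   "7mer-m8" = paste0(m8c, core6),
                   "7mer-A1" = paste0(core6, "A"),
                   "6mer" = core6)
  hits <- list()
  for (ty in names(patterns)) {
    p <- patterns[[ty]]
    L <- nchar(p)
    for (i in seq_len(nchar(u) - L + 1)) {
      if (substr(u, i, i + L - 1) == p)
        hits[[length(hits) + 1]] <- data.frame(
          site_type = ty, utr_start = i - 1L, utr_end = i - 1L + L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(mirna_id = character(),
                                       gene_id = character(),
                                       site_type = character(),
                                       utr_start = integer(),
                                       utr_end = integer()))
  h <- do.call(rbind, hits)
  # maximal typing: drop any hit nested inside a longer hit
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(h$utr_start <= h$utr_start[i] & h$utr_end >= h$utr_end[i] &
           (h$utr_end - h$utr_start) > (h$utr_end[i] - h$utr_start[i]))
  }, logical(1))
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$utr_start, h$site_type), , drop = FALSE]
  data.frame(mirna_id = mirna_id, gene_id = gene_id, h,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Exponential hub oracle: test every subset of every miRNA in the network.
oracle_hubs <- function(edges, gene_group, min_mirnas = 3, min_shared = 2) {
  edges <- unique(edges[edges$gene_id %in% gene_group,
                        c("mirna_id", "gene_id")])
  mirnas <- sort(unique(edges$mirna_id))
  targets <- split(edges$gene_id, edges$mirna_id)
  n <- length(mirnas)
  stopifnot(n <= 15)
  cand <- list()
  for (mask in seq_len(2^n - 1)) {
    sel <- mirnas[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) < min_mirnas) next
    shared <- Reduce(intersect, targets[sel])
    if (length(shared) >= min_shared)
      cand[[length(cand) + 1]] <- sort(sel)
  }
  # maximal sets only
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && length(cand[[j]]) > length(cand[[i]]) &&
        all(cand[[i]] %in% cand[[j]])
    }, logical(1)))
  }, logical(1))
  unique(cand[keep])
}

# Union-find chaining oracle for genomic clusters.
oracle_clusters <- function(coords, window_bp) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && coords$chrom[i] == coords$chrom[j]) {
      gap <- max(coords$start[i], coords$start[j]) -
        min(coords$end[i], coords$end[j])
      if (gap <= window_bp) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(coords$name, roots)
  lapply(unname(comps[lengths(comps) >= 2]), sort)
}

# Naive O(n^3) average-linkage agglomeration under 1 - Pearson distance,
# returning the flat partition with k clusters.
oracle_average_linkage <- function(x, k) {
  d <- 1 - stats::cor(t(x))
  groups <- as.list(seq_len(nrow(x)))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        dij <- mean(d[groups[[i]], groups[[j]]])
        if (dij < bestd) { bestd <- dij; best <- c(i, j) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  out <- integer(nrow(x))
  for (i in seq_along(groups)) out[groups[[i]]] <- i
  out
}

# two partitions identical up to label names
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))]))
}

# Exact hypergeometric upper tail by enumerating every possible draw.
oracle_hyper_enum <- function(universe, set, list_size, min_overlap) {
  draws <- utils::combn(universe, list_size, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set)) >= min_overlap,
              logical(1)))
}
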