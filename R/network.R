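#' Build the bipartite regulatory network from phase pairings
#'
#' Takes the union of the phase edge sets and computes bipartite
#' connectivity: each miRNA's number of distinct target genes, and each
#' gene's number of distinct upstream miRNAs, split by phase and in total.
#' A regulator targeting a gene in both phases counts once in the total
#' (distinct-partner counting).
#'
#' @param pairings list of `phase_pairing` objects.
#' @return A `regulatory_network`: list with `nodes` (id, type),
#'   `edges` (`mirna_id`, `gene_id`, `phase`, `n_sites`),
#'   `mirna_connectivity` and `gene_connectivity` data.frames with
#'   `early`, `late` and `total` degree columns.
#' @export
build_network <- function(pairings) {
  if (!length(pairings))
    mirnet_stop("mirnet_bad_input", "need at least one pairing")
  edges <- do.call(rbind, lapply(pairings, `[[`, "edges"))
  edges <- edges[!duplicated(edges[, c("mirna_id", "gene_id", "phase")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  mirnas <- sort(unique(edges$mirna_id))
  genes <- sort(unique(edges$gene_id))

  degree_split <- function(by, other) {
    tot <- tapply(edges[[other]], edges[[by]],
                  function(x) length(unique(x)))
    per_phase <- function(ph) {
      e <- edges[edges$phase == ph, , drop = FALSE]
      d <- tapply(e[[other]], e[[by]], function(x) length(unique(x)))
      out <- stats::setNames(integer(length(tot)), names(tot))
      out[names(d)] <- as.integer(d)
      out
    }
    data.frame(id = names(tot),
               early = unname(per_phase("early")),
               late = unname(per_phase("late")),
               total = as.integer(unname(tot)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  mc <- if (nrow(edges)) degree_split("mirna_id", "gene_id") else
    data.frame(id = character(), early = integer(), late = integer(),
               total = integer())
  gc <- if (nrow(edges)) degree_split("gene_id", "mirna_id") else
    data.frame(id = character(), early = integer(), late = integer(),
               total = integer())
  nodes <- rbind(data.frame(id = mirnas, type = rep("miRNA", length(mirnas))),
                 data.frame(id = genes, type = rep("gene", length(genes))))
  structure(list(nodes = nodes, edges = edges,
                 mirna_connectivity = mc, gene_connectivity = gc),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d miRNAs, %d genes, %d edges\n",
              sum(x$nodes$type == "miRNA"), sum(x$nodes$type == "gene"),
              nrow(x$edges)))
  invisible(x)
}

#' Rank nodes by connectivity
#'
#' Descending by total distinct-partner degree; ties are broken
#' lexicographically by id (stable and order-independent).
#'
#' @param network a `regulatory_network`.
#' @param node_type `"miRNA"` or `"gene"`.
#' @param k number of top nodes to return (all nodes if larger).
#' @return data.frame `id`, `early`, `late`, `total`, `rank`.
#' @export
rank_top <- function(network, node_type = c("miRNA", "gene"), k = 10L) {
  node_type <- match.arg(node_type)
  if (!is_count(k))
    mirnet_stop("mirnet_bad_threshold", "k must be a count >= 1")
  tab <- if (node_type == "miRNA") network$mirna_connectivity
         else network$gene_connectivity
  tab <- tab[order(-tab$total, tab$id), , drop = FALSE]
  tab <- utils::head(tab, k)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Enumerate hub miRNA sets over a functional gene group
#'
#' A hub is a maximal set of at least `min_mirnas` miRNAs that jointly
#' regulate at least `min_shared_genes` common genes of the supplied group
#' (the "three or more miRNAs regulating at least two functionally related
#' genes" rule). Enumeration is exact: every maximal co-regulating set is
#' found by closing over gene pairs of the group, and maximality is checked
#' set-wise. The search is guarded by a cap on the number of gene pairs.
#'
#' @param network a `regulatory_network`.
#' @param gene_group non-empty character vector of functionally related
#'   genes (e.g. one GMT set).
#' @param min_mirnas minimum miRNAs per hub.
#' @param min_shared_genes minimum genes jointly regulated by every hub
#'   member.
#' @param max_pairs cap on gene pairs examined; exceeding it is an error
#'   instructing the caller to tighten the group.
#' @return list with `hubs` (list of `list(mirnas, genes)`) and `subnetwork`
#'   (edges of the induced bipartite subnetwork).
#' @export
extract_hub_subnetwork <- function(network, gene_group, min_mirnas = 3L,
                                   min_shared_genes = 2L, max_pairs = 1e5) {
  if (!length(gene_group))
    mirnet_stop("mirnet_bad_input", "gene_group must be non-empty")
  edges <- unique(network$edges[network$edges$gene_id %in% gene_group,
                                c("mirna_id", "gene_id")])
  targets_of <- split(edges$gene_id, edges$mirna_id)
  genes <- sort(unique(edges$gene_id))
  if (choose(length(genes), 2) > max_pairs)
    mirnet_stop("mirnet_search_overflow",
                "hub search space too large (%d genes); tighten the gene group",
                length(genes))
  regulators_of <- split(edges$mirna_id, edges$gene_id)

  cand <- list()
  if (length(genes) >= min_shared_genes) {
    combos <- utils::combn(genes, 2L, simplify = FALSE)
    for (pr in combos) {
      m <- intersect(regulators_of[[pr[1L]]], regulators_of[[pr[2L]]])
      if (length(m) < min_mirnas) next
      shared <- Reduce(intersect, targets_of[m])
      if (length(shared) < min_shared_genes) next
      cand[[paste(sort(m), collapse = "\r")]] <-
        list(mirnas = sort(m), genes = sort(shared))
    }
  }
  # keep only maximal miRNA sets
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1L) {
    for (i in seq_along(cand)) for (j in seq_along(cand)) {
      if (i != j && keep[i] &&
          length(cand[[i]]$mirnas) < length(cand[[j]]$mirnas) &&
          all(cand[[i]]$mirnas %in% cand[[j]]$mirnas))
        keep[i] <- FALSE
    }
  }
  hubs <- unname(cand[keep])
  hub_mirnas <- unique(unlist(lapply(hubs, `[[`, "mirnas")))
  hub_genes <- unique(unlist(lapply(hubs, `[[`, "genes")))
  sub <- network$edges[network$edges$mirna_id %in% hub_mirnas &
                         network$edges$gene_id %in% hub_genes, , drop = FALSE]
  rownames(sub) <- NULL
  list(hubs = hubs, subnetwork = sub)
}

#' Detect genomic miRNA clusters
#'
#' Single-linkage chaining of miRNA loci: two loci on the same chromosome
#' join when the gap between them (start of the downstream locus minus end
#' of the upstream one) is at most `window_bp`; chains propagate
#' transitively. Only clusters of two or more miRNAs are reported.
#'
#' @param coords coordinate data.frame from [read_bed()].
#' @param window_bp chaining window in base pairs (default 20 kb, the scale
#'   of polycistronic miRNA clusters such as the rat chr6q32 / human 14q32.2
#'   locus).
#' @return data.frame: `cluster_id`, `chrom`, `members` (comma-joined,
#'   ordered by position), `n_members`, `span_bp` (max end - min start).
#' @export
cluster_mirnas <- function(coords, window_bp = 20000) {
  out <- list()
  cid <- 0L
  for (ch in unique(coords$chrom)) {
    cc <- coords[coords$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    if (nrow(cc) < 2L) next
    gap <- cc$start[-1L] - cummax(cc$end[-nrow(cc)])
    grp <- cumsum(c(TRUE, gap > window_bp))
    for (g in unique(grp)) {
      mem <- cc[grp == g, , drop = FALSE]
      if (nrow(mem) < 2L) next
      cid <- cid + 1L
      out[[cid]] <- data.frame(cluster_id = sprintf("cluster_%d", cid),
                               chrom = ch,
                               members = paste(mem$name, collapse = ","),
                               n_members = nrow(mem),
                               span_bp = max(mem$end) - min(mem$start))
    }
  }
  if (!length(out))
    return(data.frame(cluster_id = character(), chrom = character(),
                      members = character(), n_members = integer(),
                      span_bp = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
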