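#' Over-representation analysis against gene sets
#'
#' Hypergeometric upper-tail test of a gene list's overlap with each
#' annotated set, the generic form of GO/KEGG term enrichment. Sets are
#' intersected with the universe before testing; p-values come from
#' [stats::phyper()] and are Benjamini-Hochberg adjusted across the tested
#' sets.
#'
#' @param gene_list character vector, must be a subset of `universe`.
#' @param gene_sets a `gene_set_collection` (or named list of character
#'   vectors).
#' @param universe background gene identifiers (typically all genes on the
#'   expression matrix).
#' @return data.frame sorted by p-value: `set_id`, `description`,
#'   `overlap_count`, `list_size`, `set_size`, `universe_size`, `p_value`,
#'   `fdr`.
#' @export
enrich <- function(gene_list, gene_sets, universe) {
  if (!length(universe))
    mirnet_stop("mirnet_bad_input", "empty universe")
  if (!length(gene_list))
    mirnet_stop("mirnet_bad_input", "empty gene list")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray))
    mirnet_stop("mirnet_bad_input",
                "gene list not contained in universe (e.g. %s)", stray[1L])
  N <- length(universe)
  n <- length(gene_list)
  res <- do.call(rbind, lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    K <- length(set)
    q <- length(intersect(gene_list, set))
    p <- if (K) stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE) else NA_real_
    data.frame(set_id = id, overlap_count = q, list_size = n, set_size = K,
               universe_size = N, p_value = p)
  }))
  desc <- attr(gene_sets, "descriptions")
  res$description <- if (is.null(desc)) res$set_id else unname(desc[res$set_id])
  res$fdr <- stats::p.adjust(res$p_value, "BH")
  res <- res[order(res$p_value, res$set_id),
             c("set_id", "description", "overlap_count", "list_size",
               "set_size", "universe_size", "p_value", "fdr")]
  rownames(res) <- NULL
  res
}

#' Signed up/down overlap report per gene set
#'
#' For two directional gene lists, reports per set the up-regulated overlap
#' as a positive count and the down-regulated overlap as a negative count
#' (the usual signed-bar presentation of directional term summaries). Sets
#' hit by neither list are omitted.
#'
#' @param up,down directional gene lists.
#' @param gene_sets a `gene_set_collection`.
#' @param universe background genes.
#' @return data.frame sorted by decreasing total hits: `set_id`, `up_count`,
#'   `down_count` (negative), `total`.
#' @export
direction_split_report <- function(up, down, gene_sets, universe) {
  universe <- unique(universe)
  rows <- do.call(rbind, lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    u <- length(intersect(up, set))
    d <- length(intersect(down, set))
    data.frame(set_id = id, up_count = u, down_count = -d, total = u + d)
  }))
  rows <- rows[rows$total > 0, , drop = FALSE]
  rows <- rows[order(-rows$total, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
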