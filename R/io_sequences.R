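#' Read a nucleotide multi-FASTA
#'
#' Sequences are uppercased and RNA `U` is normalised to `T` so miRNA records
#' may be written in either alphabet. Record identifiers are the first
#' whitespace-delimited token of the header. Characters outside the IUPAC
#' nucleotide alphabet cause a rejection naming the offending record.
#'
#' @param path file path (gzip transparent).
#' @return named character vector of DNA-alphabet sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    mirnet_stop("mirnet_missing_file", "file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) mirnet_stop("mirnet_bad_input",
                                                  "cannot parse FASTA %s: %s",
                                                  path, conditionMessage(e)))
  if (!length(set))
    mirnet_stop("mirnet_bad_input", "empty FASTA file: %s", path)
  seqs <- normalize_nt(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad))
    mirnet_stop("mirnet_bad_alphabet",
                "non-IUPAC nucleotide character(s) in record(s): %s",
                paste(names(seqs)[bad], collapse = ", "))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    mirnet_stop("mirnet_duplicate_ids", "duplicate FASTA id(s): %s",
                paste(dup, collapse = ", "))
  seqs
}

#' Write sequences as multi-FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(as.character(seqs), names(seqs))),
    path, width = width)
  invisible(path)
}

#' Read miRNA genomic coordinates from BED
#'
#' Standard 6-column BED (0-based, half-open). Parsing is delegated to
#' \pkg{rtracklayer}; coordinates are returned in the BED convention.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) mirnet_stop("mirnet_bad_input",
                                                 "cannot parse BED %s: %s",
                                                 path, conditionMessage(e)))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(end0 <= start0))
    mirnet_stop("mirnet_bad_input",
                "BED interval(s) with end <= start: %s",
                paste(gr$name[end0 <= start0], collapse = ", "))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0,
             name = as.character(gr$name),
             score = if (is.null(gr$score)) 0 else as.numeric(gr$score),
             strand = as.character(BiocGenerics::strand(gr)))
}

#' Write a 6-column BED file
#' @param coords data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(coords, path) {
  utils::write.table(
    coords[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a regulatory network
#'
#' Supported formats: `edge_tsv` (lossless: all edge attributes), `sif`
#' (Cytoscape simple interaction file, `source<TAB>relation<TAB>target`) and
#' `graphml` (via \pkg{igraph}).
#'
#' @param network a `regulatory_network` from [build_network()].
#' @param path output path.
#' @param format one of `"edge_tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- network$edges
  if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s\tregulates\t%s", edges$mirna_id, edges$gene_id),
               path)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# Build an igraph object with node/edge attributes from a regulatory_network.
network_to_igraph <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("mirna_id", "gene_id")], directed = TRUE,
    vertices = data.frame(name = nodes$id, type = nodes$type))
  igraph::E(g)$phase <- edges$phase
  igraph::E(g)$n_sites <- edges$n_sites
  g
}
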