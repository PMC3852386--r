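#' Read an expression table (log2 intensities or qPCR Ct values)
#'
#' Reads a TSV whose first column holds feature identifiers and whose
#' remaining columns are samples named `t{h}h_rep{r}`. Two layouts are
#' supported:
#' \describe{
#'   \item{`log2`}{values are log2 abundances and are returned as-is.}
#'   \item{`ct_with_reference`}{values are raw qPCR cycle thresholds. One row
#'     (default `"U6"`) is the endogenous reference probe; returned values are
#'     reference-normalised log2 abundances,
#'     `log2(abundance) = Ct_ref(sample) - Ct_feature(sample)` (each Ct unit
#'     is a two-fold abundance change), and the reference row is dropped from
#'     the feature set.}
#' }
#'
#' Undetermined Ct values (empty or `NA`) are imputed at a detection ceiling
#' and flagged; features flagged in more than `max_missing_frac` of samples
#' are excluded (a message reports how many).
#'
#' @param path file path (plain or gzip-compressed TSV).
#' @param layout `"log2"` or `"ct_with_reference"`.
#' @param reference_id feature id of the reference probe for the Ct layout.
#' @param ct_ceiling Ct assigned to undetermined wells before normalisation.
#' @param max_missing_frac maximum tolerated fraction of flagged samples per
#'   feature.
#' @return An [expression_matrix()]. For the Ct layout the number of excluded
#'   features is attached as attribute `"n_excluded"`.
#' @export
read_expression_tsv <- function(path,
                                layout = c("log2", "ct_with_reference"),
                                reference_id = "U6",
                                ct_ceiling = 40,
                                max_missing_frac = 0.25) {
  layout <- match.arg(layout)
  if (!file.exists(path))
    mirnet_stop("mirnet_missing_file", "file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    mirnet_stop("mirnet_duplicate_ids", "duplicate feature id(s) in %s: %s",
                path, paste(dup, collapse = ", "))
  meta <- parse_sample_ids(colnames(tab)[-1L])
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1L, drop = FALSE])),
           nrow = nrow(tab), dimnames = list(ids, meta$sample_id)))

  if (layout == "log2") {
    if (any(!is.finite(vals)))
      mirnet_stop("mirnet_bad_input", "non-numeric or missing values in %s", path)
    return(expression_matrix(vals, meta))
  }

  if (!reference_id %in% ids)
    mirnet_stop("mirnet_missing_reference",
                "reference row '%s' not found in %s", reference_id, path)
  ref <- vals[reference_id, ]
  if (any(!is.finite(ref)))
    mirnet_stop("mirnet_bad_input", "reference row '%s' has missing Ct values",
                reference_id)
  ct <- vals[setdiff(ids, reference_id), , drop = FALSE]
  flagged <- !is.finite(ct)
  ct[flagged] <- ct_ceiling
  keep <- rowMeans(flagged) <= max_missing_frac
  if (any(!keep))
    message(sprintf("read_expression_tsv: excluded %d feature(s) with >%d%% undetermined Ct",
                    sum(!keep), round(100 * max_missing_frac)))
  log2ab <- sweep(-ct[keep, , drop = FALSE], 2L, ref, `+`)
  em <- expression_matrix(log2ab, meta)
  attr(em, "n_excluded") <- sum(!keep)
  attr(em, "flagged") <- flagged[keep, , drop = FALSE]
  em
}

#' Write an expression matrix as TSV
#'
#' Values are serialised at full precision so that reading the file back
#' reproduces the matrix bit-exactly.
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @param id_col name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path, id_col = "probe_id") {
  m <- apply(em$values, 2L, format_full)
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(em$values))
  out <- cbind(rownames(em$values), m)
  colnames(out) <- c(id_col, colnames(em$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Expects a TSV with columns `probe_id` and `gene_symbol`. Many probes may
#' map to one gene; a probe must not map to two genes.
#'
#' @param path file path.
#' @return data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (!all(c("probe_id", "gene_symbol") %in% colnames(ann)))
    mirnet_stop("mirnet_bad_input",
                "annotation must have columns probe_id and gene_symbol")
  dup <- unique(ann$probe_id[duplicated(ann$probe_id)])
  if (length(dup))
    mirnet_stop("mirnet_duplicate_ids", "probe(s) mapped twice: %s",
                paste(dup, collapse = ", "))
  ann[, c("probe_id", "gene_symbol")]
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes are mapped to gene symbols through the annotation; where several
#' probes interrogate one gene the probe with the highest median intensity is
#' retained (a common one-probe-per-gene rule for downstream set arithmetic).
#' Unmapped probes are not dropped silently: their ids are attached as the
#' `"unmapped"` attribute and reported in a message.
#'
#' @param em probe-level [expression_matrix()].
#' @param annotation data.frame from [read_annotation_tsv()].
#' @return gene-level `expr_matrix` keyed by gene symbol.
#' @export
collapse_probes <- function(em, annotation) {
  idx <- match(rownames(em$values), annotation$probe_id)
  unmapped <- rownames(em$values)[is.na(idx)]
  if (length(unmapped))
    message(sprintf("collapse_probes: %d unmapped probe(s) set aside",
                    length(unmapped)))
  mapped <- !is.na(idx)
  gene <- annotation$gene_symbol[idx[mapped]]
  vals <- em$values[mapped, , drop = FALSE]
  med <- apply(vals, 1L, stats::median)
  ord <- order(gene, -med)  # best probe first within each gene
  first <- !duplicated(gene[ord])
  pick <- ord[first]
  out <- vals[pick, , drop = FALSE]
  rownames(out) <- gene[ord][first]
  gm <- expression_matrix(out, em$sample_meta)
  attr(gm, "unmapped") <- unmapped
  attr(gm, "probe_used") <- stats::setNames(rownames(vals)[pick], rownames(out))
  gm
}

#' Read gene sets in GMT format
#'
#' One tab-separated set per line: `set_id<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path file path.
#' @return A `gene_set_collection`: named list of member character vectors
#'   with a `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    mirnet_stop("mirnet_bad_input", "empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    mirnet_stop("mirnet_bad_input", "GMT line(s) with fewer than 3 fields: %s",
                paste(short, collapse = ", "))
  ids <- vapply(parts, `[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    mirnet_stop("mirnet_duplicate_ids", "duplicate gene set id(s): %s",
                paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(!lengths(sets)))
    mirnet_stop("mirnet_bad_input", "gene set(s) with no members: %s",
                paste(ids[!lengths(sets)], collapse = ", "))
  names(sets) <- ids
  structure(sets,
            descriptions = stats::setNames(vapply(parts, `[`, "", 2L), ids),
            class = c("gene_set_collection", "list"))
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (optionally a
#'   `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to the set ids.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||%
    attr(sets, "descriptions") %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
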