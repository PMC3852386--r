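SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")  # weakest to strongest

site_rank <- function(type) match(type, SITE_TYPES)

#' Scan 3'-UTRs for canonical miRNA seed sites
#'
#' Finds, on the mRNA sense strand only, the four canonical site types
#' defined by complementarity to the miRNA seed (miRNA positions 2-8,
#' 5' to 3'):
#' \describe{
#'   \item{6mer}{UTR match to the reverse complement of positions 2-7.}
#'   \item{7mer-m8}{reverse complement of positions 2-8.}
#'   \item{7mer-A1}{6mer followed by an `A` opposite miRNA position 1 (the
#'     `A` is required in the UTR regardless of the miRNA's first base).}
#'   \item{8mer}{7mer-m8 followed by that `A`.}
#' }
#' Every occurrence of the seed core is typed maximally (an 8mer locus is
#' reported once, not additionally as its nested 7mers), overlapping
#' occurrences are all reported, matching is case-insensitive and `U == T`.
#'
#' @param mirnas named character vector of mature miRNA sequences (>= 8 nt).
#' @param utrs named character vector of UTR sequences (sense strand).
#' @param site_types site types to retain (default excludes plain 6mers,
#'   which carry little specificity).
#' @return data.frame of sites: `mirna_id`, `gene_id`, `site_type`,
#'   `utr_start`, `utr_end` (0-based, half-open), `matched_sequence`.
#' @export
scan_seed_sites <- function(mirnas, utrs,
                            site_types = c("7mer-A1", "7mer-m8", "8mer")) {
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  mirnas <- stats::setNames(normalize_nt(mirnas), names(mirnas))
  utrs <- stats::setNames(normalize_nt(utrs), names(utrs))
  short <- names(mirnas)[nchar(mirnas) < 8L]
  if (length(short))
    mirnet_stop("mirnet_short_mirna",
                "miRNA(s) shorter than 8 nt: %s", paste(short, collapse = ", "))
  utr_set <- Biostrings::DNAStringSet(utrs)
  lens <- nchar(utrs)
  out <- vector("list", length(mirnas))
  for (mi in seq_along(mirnas)) {
    m <- mirnas[[mi]]
    core6 <- revcomp(substr(m, 2L, 7L))
    m8c <- complement_base(substr(m, 8L, 8L))
    hits <- Biostrings::vmatchPattern(core6, utr_set)
    nh <- S4Vectors::elementNROWS(hits)
    if (!sum(nh)) next
    ui <- rep(seq_along(utrs), nh)
    s <- BiocGenerics::start(unlist(hits))  # 1-based core start
    useq <- utrs[ui]
    has_m8 <- s > 1L & substr(useq, s - 1L, s - 1L) == m8c
    has_a1 <- s + 6L <= lens[ui] & substr(useq, s + 6L, s + 6L) == "A"
    type <- ifelse(has_m8 & has_a1, "8mer",
                   ifelse(has_m8, "7mer-m8",
                          ifelse(has_a1, "7mer-A1", "6mer")))
    start0 <- ifelse(has_m8, s - 2L, s - 1L)
    end0 <- ifelse(has_a1, s + 6L, s + 5L)
    out[[mi]] <- data.frame(mirna_id = names(mirnas)[mi],
                            gene_id = names(utrs)[ui],
                            site_type = type,
                            utr_start = as.integer(start0),
                            utr_end = as.integer(end0),
                            matched_sequence = substr(useq, start0 + 1L, end0),
                            stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, c(out, list(empty_sites())))
  sites <- sites[sites$site_type %in% site_types, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_sites <- function() {
  data.frame(mirna_id = character(), gene_id = character(),
             site_type = character(), utr_start = integer(),
             utr_end = integer(), matched_sequence = character(),
             stringsAsFactors = FALSE)
}

#' Aggregate seed sites into a miRNA-to-gene prediction table
#'
#' @param sites site data.frame from [scan_seed_sites()].
#' @param source provenance label for the aggregated pairs.
#' @return `prediction_table`: data.frame keyed by (`mirna_id`, `gene_id`)
#'   with `n_sites`, `best_site_type` and `source`; the per-pair site lists
#'   are kept in the `"sites"` attribute.
#' @export
as_prediction_table <- function(sites, source = "seed_scan") {
  key <- paste(sites$mirna_id, sites$gene_id, sep = "\r")
  ord <- order(key)
  sites <- sites[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  n <- as.integer(table(factor(key, levels = unique(key))))
  best <- vapply(split(sites$site_type, factor(key, levels = unique(key))),
                 function(tt) SITE_TYPES[max(site_rank(tt))], character(1))
  tab <- data.frame(mirna_id = sites$mirna_id[first],
                    gene_id = sites$gene_id[first],
                    n_sites = n,
                    best_site_type = unname(best),
                    source = source,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, sites = sites, class = c("prediction_table", "data.frame"))
}

#' Merge two prediction tables
#'
#' @param scanned sequence-based `prediction_table` (takes precedence for
#'   site details on conflict).
#' @param external externally supplied table (e.g. an imported prediction
#'   database export); needs at least `mirna_id` and `gene_id` columns.
#' @param mode `"union"` keeps pairs from either source, `"intersection"`
#'   keeps pairs present in both; pairs found in both are labelled
#'   `source = "both"`.
#' @return merged `prediction_table`.
#' @export
merge_predictions <- function(scanned, external,
                              mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  key_s <- paste(scanned$mirna_id, scanned$gene_id, sep = "\r")
  key_e <- paste(external$mirna_id, external$gene_id, sep = "\r")
  if (anyDuplicated(key_e))
    mirnet_stop("mirnet_duplicate_ids", "duplicate pairs in external table")
  in_both <- key_s %in% key_e
  scanned$source <- ifelse(in_both, "both", scanned$source)
  if (mode == "intersection") {
    out <- scanned[in_both, , drop = FALSE]
  } else {
    extra <- external[!key_e %in% key_s, , drop = FALSE]
    if (nrow(extra)) {
      add <- data.frame(mirna_id = extra$mirna_id, gene_id = extra$gene_id,
                        n_sites = extra$n_sites %||% NA_integer_,
                        best_site_type = extra$best_site_type %||% NA_character_,
                        source = "external", stringsAsFactors = FALSE)
      out <- rbind(as.data.frame(scanned)[names(add)], add)
    } else out <- scanned
  }
  rownames(out) <- NULL
  structure(as.data.frame(out), sites = attr(scanned, "sites"),
            class = c("prediction_table", "data.frame"))
}

#' Assign sites of a UTR to fragments
#'
#' Splits a UTR at the given breakpoints (the reporter-construct style
#' fragmentation of a long UTR into sub-regions) and assigns each site to
#' the fragment containing its start; sites spanning a breakpoint are
#' flagged.
#'
#' @param sites site data.frame for a single UTR.
#' @param utr_length length of that UTR (nt).
#' @param breakpoints strictly increasing 0-based cut positions inside the
#'   UTR.
#' @return `sites` with added `fragment` (1-based) and `spans_breakpoint`
#'   columns.
#' @export
fragment_sites <- function(sites, utr_length, breakpoints) {
  if (any(diff(breakpoints) <= 0))
    mirnet_stop("mirnet_bad_input", "breakpoints must be strictly increasing")
  if (any(breakpoints <= 0 | breakpoints >= utr_length))
    mirnet_stop("mirnet_bad_input",
                "breakpoint(s) outside the UTR (length %d): %s", utr_length,
                paste(breakpoints[breakpoints <= 0 | breakpoints >= utr_length],
                      collapse = ", "))
  sites$fragment <- findInterval(sites$utr_start, breakpoints) + 1L
  frag_end <- c(breakpoints, utr_length)[sites$fragment]
  sites$spans_breakpoint <- sites$utr_end > frag_end
  sites
}
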