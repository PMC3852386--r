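# Internal helpers shared across modules.

# Signal a classed error so callers/tests can match failures by name.
mirnet_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mirnet_error", "error")))
}

# Sample identifiers follow the layout t{hours}h_rep{replicate}.
parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^t([0-9]+(?:\\.[0-9]+)?)h_rep([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    mirnet_stop("mirnet_bad_header",
                "malformed sample header(s): %s (expected t{h}h_rep{r})",
                paste(ids[bad], collapse = ", "))
  }
  data.frame(sample_id = ids,
             time_h = as.numeric(vapply(m, `[`, "", 2L)),
             replicate = as.integer(vapply(m, `[`, "", 3L)))
}

format_sample_ids <- function(time_h, replicate) {
  # %g drops trailing zeros: 2 -> "t2h_rep1", 2.5 -> "t2.5h_rep1"
  sprintf("t%gh_rep%d", time_h, as.integer(replicate))
}

# DNA alphabet handling: sequences are stored uppercase with U normalised to T.
normalize_nt <- function(x) chartr("Uu", "Tt", toupper(x))

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

# Numbers are serialised with full precision so a write/read round trip is
# bit-exact.
format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
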