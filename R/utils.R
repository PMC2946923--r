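# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character DNA
#'
#' Vectorised over `x`. Accepts only A/C/G/T/N (case-insensitive).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("acgtn", "ACGTN", s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Disjoint-set forest used for single-linkage grouping (catalog clusters,
# ancestral groups). Path compression only; sizes here are small.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# Validate a DNA string; returns the uppercased sequence or stops.
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (nchar(x) > 0 && grepl(sprintf("[^%s]", alphabet), x)) {
    stop(what, " contains characters outside {", alphabet, "}", call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
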