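#' Direct-repeat definitions
#'
#' A CRISPR locus is a series of near-identical direct repeats separated by
#' spacers. Spacer extraction needs the repeat sequence of the locus family.
#' Two families occur in the *Sulfolobus islandicus* loci handled here: the
#' A family (loci A1 and A2, 24-nt repeat) and the C family (locus C, 25-nt
#' repeat).
#'
#' @param locus_family single character, e.g. `"A"` or `"C"`.
#' @param sequence repeat sequence, uppercase DNA over A/C/G/T.
#' @return an object of class `repeat_definition`.
#' @examples
#' repeat_definition("C", "GATTAATCCTAAAAGGAATTGAAAG")
#' @export
repeat_definition <- function(locus_family, sequence) {
  sequence <- check_dna(sequence, "repeat sequence", allow_n = FALSE)
  if (nchar(sequence) == 0) stop("repeat sequence must be non-empty")
  structure(
    list(locus_family = as.character(locus_family), sequence = sequence),
    class = "repeat_definition"
  )
}

#' Built-in repeat definitions for the A and C locus families
#'
#' @return named list of [repeat_definition()] objects (`A`, `C`).
#' @export
builtin_repeats <- function() {
  list(
    A = repeat_definition("A", "GATAATCTACTATAGAATTGAAAG"),
    C = repeat_definition("C", "GATTAATCCTAAAAGGAATTGAAAG")
  )
}

#' @export
print.repeat_definition <- function(x, ...) {
  cat(sprintf("<repeat_definition> family %s, %d nt: %s\n",
              x$locus_family, nchar(x$sequence), x$sequence))
  invisible(x)
}

#' Locate direct repeats in a locus sequence
#'
#' Scans both strands for occurrences of the repeat at Hamming distance
#' `max_mismatches` or less. Overlapping candidates are resolved greedily left
#' to right: among candidates overlapping the current leftmost one, the hit
#' with fewest mismatches (then leftmost) wins, and all candidates overlapping
#' it are dropped. Repeats never legitimately overlap in a CRISPR locus, so
#' this only adjudicates spurious fuzzy hits.
#'
#' @param sequence locus DNA (single string).
#' @param repeat_def a [repeat_definition()].
#' @param max_mismatches maximum Hamming distance per hit (default 2).
#' @return data.frame with columns `start` (0-based), `end` (exclusive),
#'   `mismatches`, `strand` (`"+"`/`"-"`), sorted by `start`.
#' @export
find_repeats <- function(sequence, repeat_def, max_mismatches = 2) {
  stopifnot(inherits(repeat_def, "repeat_definition"), max_mismatches >= 0)
  sequence <- check_dna(sequence, "locus sequence")
  if (nchar(sequence) == 0) stop("empty input sequence", call. = FALSE)
  if (nchar(sequence) < nchar(repeat_def$sequence)) {
    stop("sequence shorter than the repeat", call. = FALSE)
  }

  subject <- Biostrings::DNAString(sequence)
  hits_for <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatches)
    if (length(m) == 0) {
      return(data.frame(start = integer(0), end = integer(0),
                        mismatches = integer(0), strand = character(0)))
    }
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                                      starting.at = IRanges::start(m),
                                      with.indels = FALSE)
    data.frame(start = IRanges::start(m) - 1L, end = IRanges::end(m),
               mismatches = as.integer(mm), strand = strand,
               stringsAsFactors = FALSE)
  }

  pat <- repeat_def$sequence
  cand <- hits_for(pat, "+")
  rc <- revcomp(pat)
  if (rc != pat) cand <- rbind(cand, hits_for(rc, "-"))
  if (nrow(cand) == 0) return(cand[order(cand$start), , drop = FALSE])
  cand <- cand[order(cand$start, cand$mismatches), , drop = FALSE]

  # greedy left-to-right resolution of overlaps
  keep <- logical(nrow(cand))
  active <- rep(TRUE, nrow(cand))
  while (any(active)) {
    i <- which(active)[1]
    overl <- which(active & cand$start < cand$end[i] & cand$end > cand$start[i])
    best <- overl[order(cand$mismatches[overl], cand$start[overl])][1]
    keep[best] <- TRUE
    active[active & cand$start < cand$end[best] & cand$end > cand$start[best]] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
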