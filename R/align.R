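#' Align two spacer arrays at the spacer level
#'
#' Global dynamic-programming alignment over spacer symbols, where a symbol
#' is the spacer's exact (full-length, 100%) identity class. Array change is
#' modelled as acquisition plus loss, never in-place substitution, so
#' mismatch columns are disallowed: two different spacers can only face a
#' pair of gaps. Scoring: match +2, gap -1. Traceback is deterministic
#' (match preferred, then gap in `a`, then gap in `b`), so identical inputs
#' always give identical alignments.
#'
#' @param a,b [spacer_array()]s of the same locus. Ends must be compatible:
#'   equal, or one of the two arrays `"full"`.
#' @param match_score,gap_score DP scores (defaults +2 / -1).
#' @param check_ends enforce the end-compatibility contract (default TRUE).
#'   Internal context adjudication relaxes it: when arrays are short, a
#'   leader and a trailer fragment of the same locus overlap and their
#'   alignment is informative.
#' @return object of class `array_alignment`: `a`, `b`, `score`, `n_match`,
#'   and `columns`, a data.frame with `a_pos`/`b_pos` (1-based spacer
#'   positions, NA = gap), leader-most column first.
#' @export
align_arrays <- function(a, b, match_score = 2, gap_score = -1,
                         check_ends = TRUE) {
  stopifnot(inherits(a, "spacer_array"), inherits(b, "spacer_array"))
  if (a$locus != b$locus) {
    stop("cannot align arrays from different loci (", a$locus, " vs ",
         b$locus, ")", call. = FALSE)
  }
  if (check_ends && a$end != b$end && a$end != "full" && b$end != "full") {
    stop("cannot align a ", a$end, "-end fragment with a ", b$end,
         "-end fragment", call. = FALSE)
  }
  sa <- a$spacers$sequence
  sb <- b$spacers$sequence
  na <- length(sa); nb <- length(sb)

  D <- matrix(0, na + 1L, nb + 1L)
  D[, 1] <- gap_score * (seq_len(na + 1L) - 1L)
  D[1, ] <- gap_score * (seq_len(nb + 1L) - 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(D[i, j + 1L] + gap_score, D[i + 1L, j] + gap_score)
      if (sa[i] == sb[j]) best <- max(best, D[i, j] + match_score)
      D[i + 1L, j + 1L] <- best
    }
  }

  # traceback, deterministic: match > gap-in-a > gap-in-b
  i <- na; j <- nb
  a_pos <- integer(0); b_pos <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && sa[i] == sb[j] &&
        D[i + 1L, j + 1L] == D[i, j] + match_score) {
      a_pos <- c(i, a_pos); b_pos <- c(j, b_pos); i <- i - 1L; j <- j - 1L
    } else if (j > 0 && D[i + 1L, j + 1L] == D[i + 1L, j] + gap_score) {
      a_pos <- c(NA_integer_, a_pos); b_pos <- c(j, b_pos); j <- j - 1L
    } else {
      a_pos <- c(i, a_pos); b_pos <- c(NA_integer_, b_pos); i <- i - 1L
    }
  }
  columns <- data.frame(a_pos = a_pos, b_pos = b_pos)
  structure(
    list(a = a, b = b, columns = columns, score = D[na + 1L, nb + 1L],
         n_match = sum(!is.na(a_pos) & !is.na(b_pos)),
         match_score = match_score, gap_score = gap_score),
    class = "array_alignment"
  )
}

#' @export
print.array_alignment <- function(x, ...) {
  cat(sprintf(
    "<array_alignment> %s vs %s (locus %s): %d columns, %d matches, score %d\n",
    x$a$strain, x$b$strain, x$a$locus, nrow(x$columns), x$n_match, x$score))
  invisible(x)
}

#' Detect spacer-loss events in an array alignment
#'
#' A loss is evidenced by two isolates carrying the same spacers in the same
#' order on either side of a gap: a maximal run of gap columns in one row,
#' flanked immediately on both sides by match columns, is reported as one
#' loss event in the gapped strain with `run_length` lost spacers. Gap runs
#' touching either array terminus carry no flanking evidence and are never
#' reported.
#'
#' @param alignment an [align_arrays()] result.
#' @return data.frame: `strain` (the loser), `locus`, `end`, `run_length`,
#'   `after_position` (the loser's own spacer position immediately leaderward
#'   of the gap — the same physical loss seen against different partners
#'   shares it), `flank_left`, `flank_right` (surviving spacer positions in
#'   the intact strain's array).
#' @export
detect_losses <- function(alignment) {
  stopifnot(inherits(alignment, "array_alignment"))
  cols <- alignment$columns
  is_match <- !is.na(cols$a_pos) & !is.na(cols$b_pos)
  out <- list()
  for (row in c("a", "b")) {
    gapped <- is.na(cols[[paste0(row, "_pos")]])
    other <- if (row == "a") "b_pos" else "a_pos"
    arr <- alignment[[row]]
    r <- rle(gapped)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      lo <- starts[k]; hi <- ends[k]
      if (lo > 1 && hi < nrow(cols) && is_match[lo - 1L] && is_match[hi + 1L]) {
        out[[length(out) + 1L]] <- data.frame(
          strain = arr$strain, locus = arr$locus, end = arr$end,
          run_length = hi - lo + 1L,
          after_position = cols[[paste0(row, "_pos")]][lo - 1L],
          flank_left = cols[[other]][lo - 1L],
          flank_right = cols[[other]][hi + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(strain = character(0), locus = character(0), end = character(0),
               run_length = integer(0), after_position = integer(0),
               flank_left = integer(0), flank_right = integer(0),
               stringsAsFactors = FALSE)
  }
}

#' Scan a population of arrays for spacer-loss events
#'
#' Runs [detect_losses()] over every compatible pair of arrays (same locus;
#' same end or one full) and collapses repeated sightings of the same
#' physical loss — the same strain, fragment, run length and position seen
#' against different partner strains — into one event.
#'
#' @param arrays list of [spacer_array()]s (any mix of loci and ends).
#' @return deduplicated data.frame as [detect_losses()], without the flank
#'   columns.
#' @export
population_losses <- function(arrays) {
  out <- list()
  n <- length(arrays)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        x <- arrays[[i]]; y <- arrays[[j]]
        if (x$strain == y$strain || x$locus != y$locus) next
        if (x$end != y$end && x$end != "full" && y$end != "full") next
        ev <- detect_losses(align_arrays(x, y))
        if (nrow(ev)) out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strain = character(0), locus = character(0),
                      end = character(0), run_length = integer(0),
                      after_position = integer(0), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out)
  ev <- ev[, c("strain", "locus", "end", "run_length", "after_position")]
  ev <- unique(ev)
  ev <- ev[order(ev$strain, ev$locus, ev$end, ev$after_position), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}
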