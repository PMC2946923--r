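# Coded representation of spacer arrays: one row per strain, one column per
# aligned spacer position, cell = exact-identity-class code. This mirrors the
# coloured array figure used for CRISPR rarefaction: identical spacers in a
# column share a code, different spacers in the same column get different
# codes, "-" is a real gap (spacer absent), NA is missing data (fragment not
# sequenced past that point, or locus absent).

# Progressively stack one group of arrays (same locus + end) into aligned
# columns. Arrays are added longest-first (ties: strain order); each is
# aligned to the running profile by the same match/gap DP used for pairwise
# array alignment, where an array symbol matches a column if that column
# already contains it.
stack_group <- function(arrays, match_score = 2, gap_score = -1) {
  ord <- order(-vapply(arrays, length, integer(1)),
               vapply(arrays, function(a) a$strain, character(1)))
  arrays <- arrays[ord]
  cols <- list()   # each: list(symbols = character set, cells = named chr)
  for (arr in arrays) {
    sym <- arr$spacers$sequence
    n <- length(sym); m <- length(cols)
    D <- matrix(0, n + 1L, m + 1L)
    D[, 1] <- gap_score * (seq_len(n + 1L) - 1L)
    D[1, ] <- gap_score * (seq_len(m + 1L) - 1L)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        best <- max(D[i, j + 1L] + gap_score, D[i + 1L, j] + gap_score)
        if (sym[i] %in% cols[[j]]$symbols) best <- max(best, D[i, j] + match_score)
        D[i + 1L, j + 1L] <- best
      }
    }
    i <- n; j <- m
    ops <- list()  # reversed list of (type, i, j)
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 && sym[i] %in% cols[[j]]$symbols &&
          D[i + 1L, j + 1L] == D[i, j] + match_score) {
        ops[[length(ops) + 1L]] <- c("match", i, j); i <- i - 1L; j <- j - 1L
      } else if (j > 0 && D[i + 1L, j + 1L] == D[i + 1L, j] + gap_score) {
        ops[[length(ops) + 1L]] <- c("skip", NA, j); j <- j - 1L
      } else {
        ops[[length(ops) + 1L]] <- c("insert", i, NA); i <- i - 1L
      }
    }
    ops <- rev(ops)
    new_cols <- list()
    for (op in ops) {
      if (op[1] == "match") {
        cc <- cols[[as.integer(op[3])]]
        cc$cells[arr$strain] <- sym[as.integer(op[2])]
        new_cols[[length(new_cols) + 1L]] <- cc
      } else if (op[1] == "skip") {
        new_cols[[length(new_cols) + 1L]] <- cols[[as.integer(op[3])]]
      } else {
        s <- sym[as.integer(op[2])]
        new_cols[[length(new_cols) + 1L]] <-
          list(symbols = s, cells = stats::setNames(s, arr$strain))
      }
    }
    # record symbol membership for future matching
    cols <- lapply(new_cols, function(cc) {
      cc$symbols <- unique(c(cc$symbols, unname(cc$cells)))
      cc
    })
  }
  strains <- sort(unique(vapply(arrays, function(a) a$strain, character(1))))
  mat <- matrix(NA_character_, length(strains), length(cols),
                dimnames = list(strains, NULL))
  for (j in seq_along(cols)) {
    cells <- cols[[j]]$cells
    mat[names(cells), j] <- cells
  }
  # distinguish real gaps from missing data, by fragment end: a leader
  # fragment is anchored at the leader boundary (left), so columns left of
  # its first spacer are real gaps and columns right of its last are
  # unsequenced; a trailer fragment mirrors this; a full array has no
  # missing interior
  end_of <- vapply(arrays, function(a) a$end, character(1))
  names(end_of) <- vapply(arrays, function(a) a$strain, character(1))
  for (s in strains) {
    row <- mat[s, ]
    pres <- which(!is.na(row))
    if (length(pres) == 0) next
    lo <- min(pres); hi <- max(pres)
    row[setdiff(seq(lo, hi), pres)] <- "-"          # internal gaps
    e <- end_of[[s]]
    if (e %in% c("leader", "full")) row[seq_len(lo - 1L)[lo > 1]] <- "-"
    if (e %in% c("trailer", "full")) {
      if (hi < length(row)) row[(hi + 1L):length(row)] <- "-"
    }
    mat[s, ] <- row
  }
  mat
}

#' Build the coded array matrix
#'
#' Stacks spacer arrays, per locus and end, into aligned columns and codes
#' each cell by the spacer's exact identity class. By default the per-group
#' matrices are concatenated column-wise over all loci and ends into one
#' coded matrix per strain, the representation the CRISPR rarefaction curve
#' is computed from; `per = "group"` returns the per-(locus, end) matrices.
#'
#' @param arrays list of [spacer_array()]s (any mix of loci and ends).
#' @param per `"concatenated"` (default) or `"group"`.
#' @param leader_depth,trailer_depth fully sequenced arrays are split into
#'   a leader view (first `leader_depth` spacers) and a non-overlapping
#'   trailer view so they stack into the same columns as the end fragments
#'   of the other strains.
#' @return a character matrix (strains x columns; cells: class code, `"-"`
#'   gap, `NA` missing), or a named list of such matrices for
#'   `per = "group"`. Class codes are the spacer sequences themselves — any
#'   injective recoding gives the same distances.
#' @export
coded_matrix <- function(arrays, per = c("concatenated", "group"),
                         leader_depth = 10, trailer_depth = 10) {
  per <- match.arg(per)
  if (length(arrays) == 0) stop("no arrays given")
  split_full <- function(a) {
    if (a$end != "full") return(list(a))
    n <- nrow(a$spacers)
    k <- min(leader_depth, n)
    out <- list(spacer_array(a$strain, a$locus, "leader",
                             a$spacers$sequence[seq_len(k)],
                             source_record = a$source_record))
    lo <- max(k + 1L, n - trailer_depth + 1L)
    if (lo <= n) {
      out[[2]] <- spacer_array(a$strain, a$locus, "trailer",
                               a$spacers$sequence[lo:n],
                               source_record = a$source_record)
    }
    out
  }
  arrays <- unlist(lapply(arrays, split_full), recursive = FALSE)
  grp_key <- vapply(arrays, function(a) paste(a$locus, a$end, sep = "|"),
                    character(1))
  groups <- split(arrays, grp_key)
  mats <- lapply(groups, stack_group)
  if (per == "group") return(mats)
  strains <- sort(unique(unlist(lapply(mats, rownames))))
  full <- lapply(names(mats), function(g) {
    m <- mats[[g]]
    out <- matrix(NA_character_, length(strains), ncol(m),
                  dimnames = list(strains, NULL))
    out[rownames(m), ] <- m
    out
  })
  do.call(cbind, full)
}
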