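#' Compare two spacers under the ungapped overlap rule
#'
#' Slides one spacer along the other over every ungapped offset (and, if
#' `check_revcomp`, over the reverse complement of `b`) and reports the best
#' overlap, maximising identity first, then overlap length; ties are broken
#' by smaller absolute offset, then by the forward orientation. Two spacers
#' "match" when identity is at least `min_identity` over an overlap of at
#' least `min_overlap` nt — with the defaults (88%, 17 nt) a full-length
#' 39-nt pair may carry at most 4 SNPs. Offsets with overlap below
#' `min_overlap` are considered only when no offset reaches it.
#'
#' @param a,b spacer sequences (character) or single rows of a spacer table.
#' @param min_identity minimum identity fraction (default 0.88).
#' @param min_overlap minimum overlap in nt (default 17).
#' @param check_revcomp also try the reverse complement of `b` (default
#'   FALSE; arrays are already orientation-normalised).
#' @return object of class `match_result`: list with `offset` (shift of `b`
#'   relative to `a`; `b[1]` aligns with `a[1 + offset]`), `overlap`,
#'   `identity`, `snps`, `is_match`, `orientation` (`"same"` or
#'   `"revcomp"`).
#' @export
pair_match <- function(a, b, min_identity = 0.88, min_overlap = 17,
                       check_revcomp = FALSE) {
  a <- check_dna(if (is.list(a) || is.data.frame(a)) a$sequence else a, "spacer a")
  b <- check_dna(if (is.list(b) || is.data.frame(b)) b$sequence else b, "spacer b")
  if (nchar(a) == 0 || nchar(b) == 0) stop("spacer sequences must be non-empty")

  consider <- function(bseq, orientation) {
    r <- .best_overlap(a, bseq, as.integer(min_overlap))
    list(offset = r[1], overlap = r[2], identity = 1 - r[3] / r[2],
         snps = r[3], orientation = orientation)
  }
  best <- consider(b, "same")
  if (check_revcomp) {
    alt <- consider(revcomp(b), "revcomp")
    if (better_match(alt, best, min_overlap)) best <- alt
  }

  # tolerance guards the exact-boundary case (e.g. 22/25 vs 0.88)
  best$is_match <- best$overlap >= min_overlap &&
    (best$overlap - best$snps) >= min_identity * best$overlap - 1e-9
  best$min_identity <- min_identity
  best$min_overlap <- min_overlap
  class(best) <- "match_result"
  best
}

# candidate ordering: admissible overlap first, then identity, overlap,
# smaller |offset|, forward orientation
better_match <- function(cand, best, min_overlap) {
  ca <- cand$overlap >= min_overlap
  ba <- best$overlap >= min_overlap
  if (ca != ba) return(ca)
  if (cand$identity != best$identity) return(cand$identity > best$identity)
  if (cand$overlap != best$overlap) return(cand$overlap > best$overlap)
  if (abs(cand$offset) != abs(best$offset)) {
    return(abs(cand$offset) < abs(best$offset))
  }
  cand$orientation == "same" && best$orientation != "same"
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %s: offset %+d, overlap %d nt, identity %.3f (%d SNPs)%s\n",
    if (x$is_match) "MATCH" else "no match", x$offset, x$overlap, x$identity,
    x$snps, if (x$orientation == "revcomp") " [revcomp]" else ""))
  invisible(x)
}

#' Catalogue spacers: exact identity classes and fuzzy match clusters
#'
#' Exact classes partition spacers by full-length identical sequence (after
#' leader-to-trailer orientation normalisation in extraction). Fuzzy
#' clusters are the single-linkage closure over all pairwise matches under
#' the 88%/17-nt rule, mirroring contig-assembly semantics: the number of
#' fuzzy clusters is the unique-spacer count. Complete linkage is available
#' for sensitivity analysis.
#'
#' @param spacers a spacer table ([spacer_table()]) or character vector of
#'   sequences.
#' @inheritParams pair_match
#' @param linkage `"single"` (default) or `"complete"`.
#' @return object of class `spacer_catalog`: list with `spacers` (the table
#'   plus `exact_class` and `cluster` integer ids), `n_exact`, `n_clusters`,
#'   `matches` (data.frame of exact-class pairs with `is_match` TRUE:
#'   class_a, class_b, offset, overlap, identity, snps), and the thresholds.
#' @export
build_catalog <- function(spacers, min_identity = 0.88, min_overlap = 17,
                          check_revcomp = FALSE,
                          linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (is.character(spacers)) {
    spacers <- data.frame(strain = NA_character_, locus = NA_character_,
                          end = NA_character_, position = seq_along(spacers),
                          sequence = toupper(spacers),
                          length = nchar(spacers), stringsAsFactors = FALSE)
  }
  if (nrow(spacers) < 1) stop("need at least one spacer")

  seqs <- unique(spacers$sequence)          # first-appearance order
  spacers$exact_class <- match(spacers$sequence, seqs)
  n <- length(seqs)

  # pairwise fuzzy matches between exact-class representatives
  if (!check_revcomp) {
    e <- .match_edges(seqs, min_identity, as.integer(min_overlap))
    matches <- data.frame(
      class_a = e[, 1], class_b = e[, 2], offset = e[, 3], overlap = e[, 4],
      identity = 1 - e[, 5] / e[, 4], snps = e[, 5],
      orientation = rep("same", nrow(e)), stringsAsFactors = FALSE)
  } else {
    edges <- list()
    if (n > 1) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          m <- pair_match(seqs[i], seqs[j], min_identity, min_overlap,
                          check_revcomp = TRUE)
          if (m$is_match) {
            edges[[length(edges) + 1L]] <- data.frame(
              class_a = i, class_b = j, offset = m$offset,
              overlap = m$overlap, identity = m$identity, snps = m$snps,
              orientation = m$orientation, stringsAsFactors = FALSE)
          }
        }
      }
    }
    matches <- if (length(edges)) do.call(rbind, edges) else
      data.frame(class_a = integer(0), class_b = integer(0),
                 offset = integer(0), overlap = integer(0),
                 identity = numeric(0), snps = integer(0),
                 orientation = character(0), stringsAsFactors = FALSE)
  }

  cluster_of <- cluster_classes(n, matches, linkage)
  spacers$cluster <- cluster_of[spacers$exact_class]

  structure(
    list(spacers = spacers, exact_seqs = seqs, n_exact = n,
         n_clusters = length(unique(cluster_of)), class_cluster = cluster_of,
         matches = matches, min_identity = min_identity,
         min_overlap = min_overlap, check_revcomp = check_revcomp,
         linkage = linkage),
    class = "spacer_catalog"
  )
}

cluster_classes <- function(n, matches, linkage) {
  if (linkage == "single") {
    parent <- uf_new(n)
    if (nrow(matches)) {
      for (k in seq_len(nrow(matches))) {
        parent <- uf_union(parent, matches$class_a[k], matches$class_b[k])
      }
    }
    return(uf_components(parent))
  }
  # complete linkage over the 0/1 match "distance"
  if (n == 1) return(1L)
  d <- matrix(1, n, n)
  if (nrow(matches)) {
    for (k in seq_len(nrow(matches))) {
      d[matches$class_a[k], matches$class_b[k]] <- 0
      d[matches$class_b[k], matches$class_a[k]] <- 0
    }
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  unname(stats::cutree(hc, h = 0.5))
}

#' @export
print.spacer_catalog <- function(x, ...) {
  cat(sprintf(
    "<spacer_catalog> %d spacers: %d exact classes, %d unique (%s linkage, %.0f%%/%d nt)\n",
    nrow(x$spacers), x$n_exact, x$n_clusters, x$linkage,
    100 * x$min_identity, x$min_overlap))
  invisible(x)
}

#' Search spacers against a target (virus/plasmid/genome) database
#'
#' Exhaustive ungapped scan of every spacer against every target on both
#' strands: all full-length placements with at most
#' `floor(length * (1 - min_identity))` mismatches are reported, scored with
#' match +1 / mismatch -1. Hits at 100% identity over the full spacer length
#' are flagged (`exact`), since perfect protospacer matches identify the
#' shared viral pool.
#'
#' @param spacers character vector of spacer sequences (names used as ids;
#'   defaults to `spacer1..n`), a spacer table, or a `spacer_catalog` (its
#'   exact-class representatives are searched).
#' @param targets named character vector of target sequences, or a FASTA
#'   path.
#' @param min_identity minimum identity over the spacer length (default 0.9).
#' @param min_length spacers shorter than this are skipped (default 17).
#' @param both_strands search the minus strand too (default TRUE).
#' @return data.frame (BED-like): `target`, `start` (0-based), `end`
#'   (exclusive), `strand`, `spacer`, `length`, `mismatches`, `identity`,
#'   `score`, `exact`.
#' @export
search_protospacers <- function(spacers, targets, min_identity = 0.9,
                                min_length = 17, both_strands = TRUE) {
  if (inherits(spacers, "spacer_catalog")) {
    spacers <- stats::setNames(spacers$exact_seqs,
                               paste0("class", seq_along(spacers$exact_seqs)))
  } else if (is.data.frame(spacers)) {
    spacers <- stats::setNames(
      spacers$sequence,
      paste(spacers$strain, spacers$locus, spacers$position, sep = "-"))
  }
  if (is.null(names(spacers))) {
    names(spacers) <- paste0("spacer", seq_along(spacers))
  }
  targets <- load_targets(targets)
  if (length(targets) == 0) stop("target database is empty")

  hits <- list()
  for (ti in seq_along(targets)) {
    subject <- Biostrings::DNAString(targets[[ti]])
    for (si in seq_along(spacers)) {
      sp <- spacers[[si]]
      len <- nchar(sp)
      if (len < min_length || len > length(subject)) next
      max_mm <- floor(len * (1 - min_identity))
      strands <- if (both_strands) c("+", "-") else "+"
      for (strand in strands) {
        pat <- if (strand == "+") sp else revcomp(sp)
        m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm)
        if (length(m) == 0) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                          starting.at = IRanges::start(m),
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          target = names(targets)[ti], start = IRanges::start(m) - 1L,
          end = IRanges::end(m), strand = strand,
          spacer = names(spacers)[si], length = len,
          mismatches = as.integer(mm),
          identity = 1 - as.integer(mm) / len,
          score = (len - as.integer(mm)) - as.integer(mm),
          exact = as.integer(mm) == 0L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(target = character(0), start = integer(0), end = integer(0),
               strand = character(0), spacer = character(0), length = integer(0),
               mismatches = integer(0), identity = numeric(0), score = integer(0),
               exact = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

load_targets <- function(targets) {
  if (is.character(targets) && length(targets) == 1 && file.exists(targets)) {
    ss <- Biostrings::readDNAStringSet(targets)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (!is.character(targets)) stop("targets must be sequences or a FASTA path")
  toupper(targets)
}

#' Flanking context of a protospacer hit
#'
#' Returns `k` nt of target sequence immediately upstream (5') and
#' downstream (3') of a protospacer hit, strand-aware: for minus-strand hits
#' the contexts are reverse-complemented and swapped so "upstream" is always
#' 5' of the protospacer on the matched strand. This is where the
#' protospacer-associated motif (PAM, a dinucleotide in *Sulfolobus*) sits;
#' no motif calling is done here, only context extraction.
#'
#' @param hit one row of [search_protospacers()] output.
#' @param targets the same target set the hit came from.
#' @param k context length in nt (default 2, the PAM width).
#' @return list with `upstream`, `downstream`, and `truncated` (TRUE when
#'   the hit is too close to a target boundary for full context).
#' @export
pam_context <- function(hit, targets, k = 2) {
  targets <- load_targets(targets)
  seq <- targets[[hit$target]]
  if (is.null(seq)) stop("unknown target: ", hit$target)
  if (hit$start < 0 || hit$end > nchar(seq)) stop("hit coordinates out of range")
  up_start <- max(0L, hit$start - k)
  up <- substring(seq, up_start + 1L, hit$start)
  down <- substring(seq, hit$end + 1L, min(nchar(seq), hit$end + k))
  truncated <- nchar(up) < k || nchar(down) < k
  if (hit$strand == "-") {
    res <- list(upstream = revcomp(down), downstream = revcomp(up),
                truncated = truncated)
  } else {
    res <- list(upstream = up, downstream = down, truncated = truncated)
  }
  res
}
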