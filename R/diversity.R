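# OTU binning, rarefaction, Chao1 richness, distances and rank abundance.

#' Pairwise p-distance between concatenated MLSA sequences
#'
#' Proportion of differing sites among columns comparable for the pair:
#' sites where either sequence carries `N` or a gap are skipped pairwise.
#'
#' @param profiles a [concatenate_profiles()] result, or a named character
#'   vector of equal-length sequences.
#' @return symmetric distance matrix (strains x strains), values in
#'   \[0, 1\].
#' @export
mlsa_distance <- function(profiles) {
  seqs <- if (inherits(profiles, "genotype_table")) profiles$concat else profiles
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1) {
    stop("concatenated sequences must have equal length")
  }
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !(chars[[i]] %in% c("N", "-")) & !(chars[[j]] %in% c("N", "-"))
      if (!any(ok)) {
        stop("no comparable sites between ", names(seqs)[i], " and ",
             names(seqs)[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(chars[[i]][ok] != chars[[j]][ok]) / sum(ok)
    }
  }
  d
}

#' Pairwise distance between coded spacer-array rows
#'
#' Fraction of differing columns among columns where neither strain is
#' missing data. A gap (`"-"`) against a spacer counts as a difference (the
#' spacer is genuinely absent); missing data (`NA`) is deleted pairwise.
#'
#' @param m a [coded_matrix()].
#' @param incomparable what to do with strain pairs whose sequenced columns
#'   are disjoint (e.g. complementary locus losses): `"error"` (default)
#'   names the offending pair; `"drop"` greedily removes the strains with
#'   most incomparable partners until every remaining pair is comparable,
#'   with a warning.
#' @return symmetric distance matrix over the (retained) rows of `m`.
#' @export
coded_array_distance <- function(m, incomparable = c("error", "drop")) {
  incomparable <- match.arg(incomparable)
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (incomparable == "drop") {
    repeat {
      pres <- !is.na(m)
      bad <- (pres %*% t(pres)) == 0       # pairs with zero shared columns
      diag(bad) <- FALSE
      if (!any(bad)) break
      worst <- which.max(rowSums(bad))
      warning("dropping strain ", rownames(m)[worst],
              " (no columns comparable with ", sum(bad[worst, ]),
              " other strain(s))")
      m <- m[-worst, , drop = FALSE]
      if (nrow(m) < 2) stop("fewer than 2 comparable strains remain")
    }
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Bin individuals into OTUs at a distance cutoff
#'
#' Furthest-neighbour (complete-linkage) clustering: an OTU is a set of
#' individuals whose maximum pairwise distance does not exceed the cutoff.
#' `cutoff = 0` (or `"unique"`) groups identical individuals only.
#'
#' @param d symmetric distance matrix.
#' @param cutoff distance threshold in \[0, 1\], or `"unique"`.
#' @param method linkage for the underlying clustering (default
#'   `"complete"`; `"single"`/`"average"` for sensitivity checks).
#' @return named integer vector: OTU id per individual.
#' @export
bin_otus <- function(d, cutoff, method = "complete") {
  if (identical(cutoff, "unique")) cutoff <- 0
  stopifnot(is.numeric(cutoff), cutoff >= 0, cutoff <= 1)
  n <- nrow(d)
  if (n == 1) return(stats::setNames(1L, rownames(d)))
  hc <- stats::hclust(stats::as.dist(d), method = method)
  stats::setNames(unname(stats::cutree(hc, h = cutoff)), rownames(d))
}

#' Analytic individual-based rarefaction
#'
#' Expected number of OTUs in a random subsample of n individuals,
#' \deqn{E[S_n] = S - \sum_i \binom{N - N_i}{n} / \binom{N}{n},}
#' computed for n = 1..N with log-binomials for stability. The curve ends
#' exactly at the observed richness.
#'
#' @param assignment an OTU assignment ([bin_otus()]) or an abundance
#'   vector (counts per OTU).
#' @param abundances logical: `assignment` already holds abundances
#'   (default: treat as per-individual OTU ids).
#' @return data.frame with `n` and `expected_otus`.
#' @export
rarefaction_curve <- function(assignment, abundances = FALSE) {
  ab <- if (abundances) as.numeric(assignment) else
    as.numeric(table(assignment))
  stopifnot(length(ab) >= 1, all(ab >= 1))
  N <- sum(ab); S <- length(ab)
  expected <- vapply(seq_len(N), function(n) {
    S - sum(exp(lchoose(N - ab, n) - lchoose(N, n)))
  }, numeric(1))
  data.frame(n = seq_len(N), expected_otus = expected)
}

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1,
#' \deqn{\hat{S} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1)),}
#' where F1/F2 are the singleton and doubleton OTU counts; the classical
#' form \eqn{S_{obs} + F_1^2 / (2 F_2)} is reported alongside (NA when
#' F2 = 0).
#'
#' @inheritParams rarefaction_curve
#' @return object of class `diversity_estimate`: list with `S_obs`, `F1`,
#'   `F2`, `chao1` (bias-corrected), `chao1_classic`, `N`.
#' @export
chao1 <- function(assignment, abundances = FALSE) {
  ab <- if (abundances) as.numeric(assignment) else
    as.numeric(table(assignment))
  stopifnot(length(ab) >= 1, all(ab >= 1))
  S <- length(ab)
  F1 <- sum(ab == 1); F2 <- sum(ab == 2)
  structure(
    list(S_obs = S, F1 = F1, F2 = F2,
         chao1 = S + F1 * (F1 - 1) / (2 * (F2 + 1)),
         chao1_classic = if (F2 > 0) S + F1^2 / (2 * F2) else NA_real_,
         N = sum(ab)),
    class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf(
    "<diversity_estimate> S_obs %d (F1 %d, F2 %d), Chao1 %.2f%s from %d individuals\n",
    x$S_obs, x$F1, x$F2, x$chao1,
    if (!is.na(x$chao1_classic)) sprintf(" (classic %.2f)", x$chao1_classic)
    else "", x$N))
  invisible(x)
}

#' Rank-abundance table of groupings
#'
#' Groups (MLSA genotypes, CRISPR ancestral groups, OTUs...) sorted by size,
#' largest first; ties broken by group id for determinism.
#'
#' @param groups vector of group ids, one per individual (or a named
#'   abundance table via `abundances = TRUE`).
#' @param abundances logical, as in [rarefaction_curve()].
#' @return data.frame: `rank`, `group`, `n`.
#' @export
rank_abundance <- function(groups, abundances = FALSE) {
  if (length(groups) == 0) {
    return(data.frame(rank = integer(0), group = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- if (abundances) stats::setNames(as.integer(groups),
                                         names(groups) %||% seq_along(groups))
  else table(groups)
  ids <- names(tab); n <- as.integer(tab)
  ord <- order(-n, ids)
  data.frame(rank = seq_along(ord), group = ids[ord], n = n[ord],
             stringsAsFactors = FALSE)
}
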