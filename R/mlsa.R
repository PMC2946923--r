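# MLSA allele assignment, genotype profiles and epidemic-structure summary.
# Locus sequences arrive pre-aligned (equal length per locus); alignment
# itself is routine and out of scope here.

#' Assign allele ids at one MLSA locus
#'
#' Sequences identical at the locus share an allele; any nucleotide
#' polymorphism from the dominant allele defines a new one. Allele 1 is the
#' most frequent sequence (ties: lexicographically smallest); further
#' alleles are numbered by decreasing frequency, then first appearance. By
#' default `N` is treated as an ambiguity that matches any base, so
#' single-read ambiguities do not split alleles; because N-compatibility is
#' not transitive, groups are merged greedily into the largest (then
#' earliest) compatible allele.
#'
#' @param sequences named character vector (strain -> aligned sequence), all
#'   the same length.
#' @param n_wildcard treat `N` as matching anything (default TRUE).
#' @return named integer vector of allele ids per strain, with attribute
#'   `allele_seq` (representative sequence per allele id).
#' @export
assign_alleles <- function(sequences, n_wildcard = TRUE) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)))
  sequences <- toupper(sequences)
  if (length(unique(nchar(sequences))) != 1) {
    stop("sequences at one locus must be equal length", call. = FALSE)
  }
  tab <- table(sequences)
  seqs <- names(tab)
  ord <- order(-as.integer(tab), seqs)
  seqs <- seqs[ord]; counts <- as.integer(tab)[ord]

  compatible <- function(x, y) {
    cx <- strsplit(x, "", fixed = TRUE)[[1]]
    cy <- strsplit(y, "", fixed = TRUE)[[1]]
    all(cx == cy | cx == "N" | cy == "N")
  }

  rep_seq <- character(0)   # representative per allele id
  allele_of_seq <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (n_wildcard && length(rep_seq)) {
      for (a in seq_along(rep_seq)) {
        if (compatible(seqs[i], rep_seq[a])) { hit <- a; break }
      }
    } else if (!n_wildcard) {
      hit <- match(seqs[i], rep_seq, nomatch = 0L)
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, seqs[i])
      hit <- length(rep_seq)
    }
    allele_of_seq[i] <- hit
  }
  ids <- allele_of_seq[match(sequences, seqs)]
  structure(stats::setNames(ids, names(sequences)), allele_seq = rep_seq)
}

#' Concatenate MLSA loci into genotype profiles
#'
#' Builds the per-strain allele-id vector over all loci, the concatenated
#' sequence, and the SNP count against a reference strain (sites where
#' either sequence is `N` or a gap are skipped). Strains missing any locus
#' are excluded with a warning.
#'
#' @param alignments named list (locus -> named character vector of aligned
#'   sequences per strain), in the desired locus order.
#' @param reference reference strain id for SNP counts (default: first
#'   strain present at every locus).
#' @param n_wildcard passed to [assign_alleles()].
#' @return object of class `genotype_table`: list with `alleles` (strain x
#'   locus integer matrix), `concat` (named character), `snps_vs_ref`
#'   (named integer), `reference`, `loci`, `genotype` (integer id per
#'   strain; identical allele vectors share an id, numbered by decreasing
#'   frequency).
#' @export
concatenate_profiles <- function(alignments, reference = NULL,
                                 n_wildcard = TRUE) {
  stopifnot(is.list(alignments), length(alignments) >= 1,
            !is.null(names(alignments)))
  loci <- names(alignments)
  all_strains <- sort(unique(unlist(lapply(alignments, names))))
  present <- vapply(all_strains, function(s) {
    all(vapply(alignments, function(al) s %in% names(al), logical(1)))
  }, logical(1))
  if (any(!present)) {
    warning("excluding strain(s) missing a locus: ",
            paste(all_strains[!present], collapse = ", "))
  }
  strains <- all_strains[present]
  if (length(strains) == 0) stop("no strain is present at every locus")
  reference <- reference %||% strains[1]
  if (!reference %in% strains) {
    stop("reference strain '", reference, "' not present at every locus")
  }

  alleles <- matrix(NA_integer_, length(strains), length(loci),
                    dimnames = list(strains, loci))
  for (l in loci) {
    alleles[, l] <- assign_alleles(alignments[[l]][strains], n_wildcard)[strains]
  }
  concat <- vapply(strains, function(s) {
    paste(vapply(alignments, function(al) toupper(al[[s]]), character(1)),
          collapse = "")
  }, character(1))

  ref_chars <- strsplit(concat[[reference]], "", fixed = TRUE)[[1]]
  snps <- vapply(strains, function(s) {
    sc <- strsplit(concat[[s]], "", fixed = TRUE)[[1]]
    ok <- !(sc %in% c("N", "-")) & !(ref_chars %in% c("N", "-"))
    sum(sc[ok] != ref_chars[ok])
  }, integer(1))

  prof_key <- apply(alleles, 1, paste, collapse = "-")
  tab <- sort(table(prof_key), decreasing = TRUE)
  genotype <- stats::setNames(match(prof_key, names(tab)), strains)

  structure(
    list(alleles = alleles, concat = concat, snps_vs_ref = snps,
         reference = reference, loci = loci, genotype = genotype),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype_table> %d strains x %d loci (%d bp concatenated), %d genotypes, reference %s\n",
    nrow(x$alleles), length(x$loci), nchar(x$concat[[1]]),
    length(unique(x$genotype)), x$reference))
  invisible(x)
}

#' Epidemic-structure summary of MLSA genotypes
#'
#' Genotypes are identical allele-id vectors. Reports the size-ranked
#' genotype table and the dominant genotype's share of strains: a high
#' dominant fraction amid rare recombinant genotypes is the signature of an
#' epidemic population structure.
#'
#' @param profiles a [concatenate_profiles()] result.
#' @return list: `n_strains`, `n_genotypes`, `dominant_fraction`,
#'   `rank_abundance` (data.frame rank/group/n).
#' @export
epidemic_summary <- function(profiles) {
  stopifnot(inherits(profiles, "genotype_table"))
  ra <- rank_abundance(profiles$genotype)
  list(n_strains = length(profiles$genotype),
       n_genotypes = nrow(ra),
       dominant_fraction = ra$n[1] / length(profiles$genotype),
       rank_abundance = ra)
}

#' Load one-FASTA-per-locus MLSA alignments
#'
#' Each file holds the pre-aligned sequences of one locus; headers are
#' strain ids (anything after the first `|` is dropped).
#'
#' @param paths named character vector of FASTA paths (names = locus ids;
#'   defaults to file base names).
#' @return named list suitable for [concatenate_profiles()].
#' @export
load_mlsa_fasta <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  }
  lapply(paths, function(p) {
    ss <- Biostrings::readDNAStringSet(p)
    strains <- vapply(strsplit(names(ss), "|", fixed = TRUE), `[`, character(1), 1)
    stats::setNames(as.character(ss), strains)
  })
}
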