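# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately written without reusing the package's internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mk_array <- function(strain, spacers, locus = "C", end = "leader") {
  spacer_array(strain = strain, locus = locus, end = end, spacers = spacers)
}

# exhaustive per-offset Hamming scan for a pattern on both strands;
# returns candidate hits (start 0-based, end exclusive, mismatches, strand)
oracle_repeat_scan <- function(sequence, pattern, max_mm) {
  sc <- strsplit(sequence, "")[[1]]
  hits <- data.frame(start = integer(0), end = integer(0),
                     mismatches = integer(0), strand = character(0))
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pattern else rc(pattern)
    pc <- strsplit(p, "")[[1]]
    L <- length(pc)
    if (strand == "-" && p == pattern) next
    for (s in 0:(length(sc) - L)) {
      mm <- sum(sc[(s + 1):(s + L)] != pc)
      if (mm <= max_mm) {
        hits <- rbind(hits, data.frame(start = s, end = s + L,
                                       mismatches = mm, strand = strand))
      }
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

# plain-R best ungapped overlap, the reference for the compiled kernel:
# admissible overlaps (>= min_overlap) outrank the rest, then identity,
# overlap, |offset|
oracle_pair_match <- function(a, b, min_identity = 0.88, min_overlap = 17) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- NULL
  for (off in (1 - lb):(la - 1)) {
    i1 <- max(1, 1 + off); i2 <- min(la, lb + off)
    ov <- i2 - i1 + 1
    if (ov < 1) next
    snps <- sum(ca[i1:i2] != cb[(i1 - off):(i2 - off)])
    cand <- list(offset = off, overlap = ov, snps = snps,
                 identity = 1 - snps / ov, admissible = ov >= min_overlap)
    take <- if (is.null(best)) TRUE
    else if (cand$admissible != best$admissible) cand$admissible
    else if (abs(cand$identity - best$identity) > 1e-12)
      cand$identity > best$identity
    else if (cand$overlap != best$overlap) cand$overlap > best$overlap
    else abs(cand$offset) < abs(best$offset)
    if (take) best <- cand
  }
  best$is_match <- best$admissible &&
    (best$overlap - best$snps) >= min_identity * best$overlap - 1e-9
  best
}

# connected components of the fuzzy-match graph via igraph (single linkage)
oracle_cluster_count <- function(seqs, min_identity = 0.88, min_overlap = 17) {
  n <- length(seqs)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_pair_match(seqs[i], seqs[j], min_identity,
                            min_overlap)$is_match) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# optimal alignment score by enumerating every order-compatible matching
# of equal symbols (independent of the DP)
oracle_align_score <- function(sa, sb, match = 2, gap = -1) {
  best <- -Inf
  recurse <- function(i, j, k) {
    # k matches chosen so far using a[1..i), b[1..j)
    if (i > length(sa) || j > length(sb)) {
      sc <- match * k + gap * (length(sa) - k + length(sb) - k)
      best <<- max(best, sc)
      return()
    }
    recurse(i + 1, j, k)            # skip a_i
    recurse(i, j + 1, k)            # skip b_j
    if (sa[i] == sb[j]) recurse(i + 1, j + 1, k + 1)
  }
  recurse(1, 1, 0)
  best
}

# brute-force furthest-neighbour clustering at a cutoff
oracle_complete_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL; bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        cd <- max(d[clusters[[i]], clusters[[j]]])
        if (cd < bestd) { bestd <- cd; best <- c(i, j) }
      }
    }
    if (is.null(best) || bestd > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  out
}

# Monte-Carlo individual-based rarefaction
oracle_rarefy_mc <- function(abund, n, draws = 1e5) {
  pop <- rep(seq_along(abund), abund)
  vals <- replicate(draws, length(unique(sample(pop, n))))
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(draws))
}

# write a named character vector as FASTA and parse it into arrays
sim_to_arrays <- function(sim) {
  f <- tempfile(fileext = ".fasta")
  on.exit(unlink(f))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$crispr), f)
  load_locus_fasta(f)
}

# run the spacer pipeline (extract, catalog, classify, losses) on one sim
run_pipeline <- function(sim) {
  arrays <- sim_to_arrays(sim)
  st <- spacer_table(arrays)
  ct <- build_catalog(st)
  list(arrays = arrays, spacers = st, catalog = ct,
       pairs = classify_acquisitions(ct, arrays),
       losses = population_losses(arrays))
}
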