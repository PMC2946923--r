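test_that("identical spacers match at offset 0 over their full length", {
  set.seed(31)
  s <- rand_dna(39)
  m <- pair_match(s, s)
  expect_true(m$is_match)
  expect_equal(m$offset, 0)
  expect_equal(m$overlap, 39)
  expect_equal(m$identity, 1)
})

test_that("a 5-nt shifted substring gives the offset signature", {
  set.seed(32)
  s <- rand_dna(39)
  m <- pair_match(s, substring(s, 6, 39))
  expect_true(m$is_match)
  expect_equal(m$offset, 5)
  expect_equal(m$overlap, 34)
  expect_equal(m$snps, 0)
})

test_that("the 88% rule admits at most 4 SNPs over a full 39-nt overlap", {
  set.seed(33)
  s <- rand_dna(39)
  mutate_at <- function(x, pos) {
    for (p in pos) {
      substring(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substring(x, p, p))[1]
    }
    x
  }
  # 4 SNPs: 35/39 = 0.897 >= 0.88 -> match; 5 SNPs: 34/39 = 0.872 -> no
  expect_true(pair_match(s, mutate_at(s, c(3, 10, 20, 30)))$is_match)
  expect_false(pair_match(s, mutate_at(s, c(3, 10, 20, 30, 36)))$is_match)
})

test_that("pair_match agrees with the plain-R oracle and is symmetric", {
  set.seed(34)
  for (i in 1:40) {
    la <- sample(17:41, 1); lb <- sample(17:41, 1)
    a <- rand_dna(la)
    b <- if (runif(1) < 0.5) rand_dna(lb) else {
      # correlated case: substring of a plus noise
      start <- sample.int(max(1, la - lb + 1), 1)
      x <- substring(paste0(a, rand_dna(lb)), start, start + lb - 1)
      x
    }
    m <- pair_match(a, b)
    o <- oracle_pair_match(a, b)
    expect_equal(m$offset, o$offset)
    expect_equal(m$overlap, o$overlap)
    expect_equal(m$snps, o$snps)
    expect_equal(m$is_match, o$is_match)
    # symmetry: verdict identical, offset negated
    m2 <- pair_match(b, a)
    expect_equal(m2$is_match, m$is_match)
    expect_equal(m2$offset, -m$offset)
  }
})

test_that("full-length identical spacers of length >= 17 always match", {
  set.seed(35)
  for (L in c(17, 20, 39)) {
    s <- rand_dna(L)
    expect_true(pair_match(s, s)$is_match)
  }
})

test_that("exact classes and single-linkage clusters behave as defined", {
  set.seed(36)
  s1 <- rand_dna(39)
  ct <- build_catalog(c(s1, s1, rand_dna(39)))
  expect_equal(ct$n_exact, 2)
  expect_equal(ct$n_clusters, 2)

  # transitivity: A~B and B~C match, A~C does not
  b <- rand_dna(39)
  mut <- function(x, pos) {
    for (p in pos) substring(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                 substring(x, p, p))[1]
    x
  }
  a <- mut(b, c(1, 2, 3, 4))
  c_ <- mut(b, c(36, 37, 38, 39))
  expect_true(pair_match(a, b)$is_match)
  expect_true(pair_match(b, c_)$is_match)
  expect_false(pair_match(a, c_)$is_match)
  ct2 <- build_catalog(c(a, b, c_))
  expect_equal(ct2$n_clusters, 1)
  expect_equal(ct2$n_exact, 3)
})

test_that("cluster count equals the graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(37)
  seqs <- replicate(60, rand_dna(39))
  # plant 10 near-duplicate pairs (0-3 SNPs, some shifted)
  for (i in 1:10) {
    src <- seqs[i]
    x <- src
    for (p in sample(39, sample(0:3, 1))) {
      substring(x, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substring(x, p, p))[1]
    }
    if (runif(1) < 0.5) x <- substring(x, sample(1:4, 1), 39)
    seqs <- c(seqs, x)
  }
  ct <- build_catalog(seqs)
  expect_equal(ct$n_clusters, oracle_cluster_count(seqs))
})

test_that("cluster count is monotone as the identity threshold loosens", {
  set.seed(38)
  seqs <- replicate(40, rand_dna(39))
  counts <- vapply(c(0.98, 0.88, 0.75), function(mi) {
    build_catalog(seqs, min_identity = mi)$n_clusters
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exact classes refine fuzzy clusters", {
  set.seed(39)
  sim <- simulate_population(
    sim_config(n_strains = 6, n_founders = 2, extra_steps = 2), seed = 8)
  st <- spacer_table(sim_to_arrays(sim))
  ct <- build_catalog(st)
  # every exact class maps into exactly one cluster
  tab <- unique(ct$spacers[, c("exact_class", "cluster")])
  expect_equal(nrow(tab), ct$n_exact)
  expect_true(ct$n_clusters <= ct$n_exact)
})

test_that("protospacer search finds planted hits exactly", {
  set.seed(40)
  target <- rand_dna(5000)
  sp <- substring(target, 1001, 1039)
  hits <- search_protospacers(c(x = sp), c(virus = target))
  planted <- hits[hits$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_true(planted$exact)
  expect_equal(planted$start, 1000)
  expect_equal(planted$end, 1039)
  expect_equal(planted$score, 39)
  # absent spacer: no hits
  expect_equal(nrow(search_protospacers(c(y = rand_dna(39)),
                                        c(virus = target))), 0)
})

test_that("protospacer hits equal the exhaustive per-offset oracle", {
  set.seed(41)
  targets <- stats::setNames(replicate(4, rand_dna(800)), paste0("t", 1:4))
  spacers <- character(0)
  for (i in 1:12) {
    t <- sample(4, 1)
    s0 <- sample(700, 1)
    sp <- substring(targets[[t]], s0, s0 + 38)
    for (p in sample(39, sample(0:3, 1))) {
      substring(sp, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substring(sp, p, p))[1]
    }
    if (runif(1) < 0.3) sp <- revcomp(sp)
    spacers <- c(spacers, sp)
  }
  names(spacers) <- paste0("sp", seq_along(spacers))
  hits <- search_protospacers(spacers, targets, min_identity = 0.9)
  # oracle: scan every offset of every target on both strands
  oracle <- list()
  for (tn in names(targets)) {
    tc <- strsplit(targets[[tn]], "")[[1]]
    for (sn in names(spacers)) {
      for (strand in c("+", "-")) {
        pc <- strsplit(if (strand == "+") spacers[[sn]] else
          revcomp(spacers[[sn]]), "")[[1]]
        L <- length(pc)
        for (s in 0:(length(tc) - L)) {
          mm <- sum(tc[(s + 1):(s + L)] != pc)
          if (mm <= floor(L * 0.1)) {
            oracle[[length(oracle) + 1L]] <-
              sprintf("%s:%s:%d:%s:%d", tn, sn, s, strand, mm)
          }
        }
      }
    }
  }
  got <- sprintf("%s:%s:%d:%s:%d", hits$target, hits$spacer, hits$start,
                 hits$strand, hits$mismatches)
  expect_setequal(got, unlist(oracle))
})

test_that("PAM context extraction is strand-aware and boundary-safe", {
  targets <- c(v = "AACCGGTTAACCGGTTAACC")
  hit <- data.frame(target = "v", start = 8, end = 12, strand = "+")
  ctx <- pam_context(hit, targets, k = 2)
  expect_equal(ctx$upstream, substring(targets[["v"]], 7, 8))
  expect_equal(ctx$downstream, substring(targets[["v"]], 13, 14))
  expect_false(ctx$truncated)

  # minus strand: contexts swap and reverse-complement
  hitm <- data.frame(target = "v", start = 8, end = 12, strand = "-")
  ctxm <- pam_context(hitm, targets, k = 2)
  expect_equal(ctxm$upstream, revcomp(substring(targets[["v"]], 13, 14)))
  expect_equal(ctxm$downstream, revcomp(substring(targets[["v"]], 7, 8)))

  hit0 <- data.frame(target = "v", start = 0, end = 4, strand = "+")
  ctx0 <- pam_context(hit0, targets, k = 2)
  expect_equal(ctx0$upstream, "")
  expect_true(ctx0$truncated)
})
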