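test_that("allele assignment groups identical sequences, dominant first", {
  seqs <- stats::setNames(rep("ACGTACGT", 5), paste0("s", 1:5))
  expect_equal(as.integer(assign_alleles(seqs)), rep(1L, 5))

  seqs2 <- stats::setNames(c(rep("ACGTACGT", 3), "ACGTACTT"), paste0("s", 1:4))
  al <- assign_alleles(seqs2)
  expect_equal(as.integer(al), c(1L, 1L, 1L, 2L))
})

test_that("N is an ambiguity, not a new allele, unless asked otherwise", {
  seqs <- stats::setNames(c("ACGTACGT", "ACGTACGT", "ACGNACGT"),
                          paste0("s", 1:3))
  expect_equal(as.integer(assign_alleles(seqs)), c(1L, 1L, 1L))
  expect_equal(as.integer(assign_alleles(seqs, n_wildcard = FALSE)),
               c(1L, 1L, 2L))
})

test_that("allele ids are stable under strain permutation", {
  set.seed(70)
  base <- rand_dna(60)
  v1 <- base; substring(v1, 10, 10) <- "A"; substring(v1, 11, 11) <- "C"
  seqs <- stats::setNames(c(base, base, base, v1, v1), paste0("s", 1:5))
  a1 <- assign_alleles(seqs)
  perm <- sample(names(seqs))
  a2 <- assign_alleles(seqs[perm])
  expect_equal(as.integer(a2[names(seqs)]), as.integer(a1))
})

test_that("concatenation length and reference SNP counts are exact", {
  set.seed(71)
  l1 <- stats::setNames(replicate(3, rand_dna(300)), paste0("s", 1:3))
  l2 <- stats::setNames(replicate(3, rand_dna(400)), paste0("s", 1:3))
  prof <- concatenate_profiles(list(locA = l1, locB = l2), reference = "s1")
  expect_equal(unique(nchar(prof$concat)), 700)
  expect_equal(unname(prof$snps_vs_ref[["s1"]]), 0)
  # oracle recount for another strain
  c1 <- strsplit(prof$concat[["s1"]], "")[[1]]
  c2 <- strsplit(prof$concat[["s2"]], "")[[1]]
  expect_equal(unname(prof$snps_vs_ref[["s2"]]), sum(c1 != c2))
})

test_that("strains missing a locus are excluded with a warning", {
  l1 <- stats::setNames(rep("ACGT", 3), paste0("s", 1:3))
  l2 <- stats::setNames(rep("TTTT", 2), paste0("s", 1:2))
  expect_warning(prof <- concatenate_profiles(list(a = l1, b = l2)),
                 "missing a locus")
  expect_equal(sort(names(prof$concat)), c("s1", "s2"))
})

test_that("epidemic summary reports the dominant genotype fraction", {
  # 19 of 39 strains share one genotype: the near-half-dominant regime
  seqs <- c(rep("AAAA", 19), replicate(20, rand_dna(4)))
  names(seqs) <- paste0("s", 1:39)
  prof <- concatenate_profiles(list(loc = seqs), reference = "s1")
  es <- epidemic_summary(prof)
  expect_equal(es$n_strains, 39)
  expect_gte(es$dominant_fraction, 19 / 39)
  expect_equal(es$rank_abundance$n[1], max(table(prof$genotype)))

  all_same <- stats::setNames(rep("ACGT", 5), paste0("s", 1:5))
  prof2 <- concatenate_profiles(list(loc = all_same))
  expect_equal(epidemic_summary(prof2)$dominant_fraction, 1)
})

test_that("simulated MLSA SNP counts match the planted event log", {
  sim <- simulate_population(
    sim_config(n_strains = 8, n_founders = 1, extra_steps = 2,
               mutation_rate = 2e-5, conversion_rate = 0), seed = 17)
  prof <- concatenate_profiles(sim$mlsa, reference = "S01")
  # with a single founder and no conversion, differences between a strain
  # and the root are exactly its surviving planted mutations
  root <- paste(sim$truth$mlsa_root, collapse = "")
  for (s in names(prof$concat)) {
    rc <- strsplit(root, "")[[1]]
    sc <- strsplit(prof$concat[[s]], "")[[1]]
    muts <- sum(rc != sc)
    log_muts <- sum(vapply(sim$truth$logs[[s]], function(e)
      e$type == "mut", logical(1)))
    expect_lte(muts, log_muts)   # back-mutations can only reduce the count
  }
})
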