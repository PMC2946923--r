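test_that("p-distance skips N and gap columns pairwise", {
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(mlsa_distance(seqs)["a", "b"], 0)

  seqs2 <- c(a = paste(rep("A", 1000), collapse = ""),
             b = paste(c(rep("A", 999), "C"), collapse = ""))
  expect_equal(mlsa_distance(seqs2)["a", "b"], 0.001)

  seqs3 <- c(a = "ACGTNCGTAC", b = "AC-TACGTTC")
  # comparable columns: 1,2,4,6,7,8,9,10 (N and '-' dropped); one differs
  expect_equal(mlsa_distance(seqs3)["a", "b"], 1 / 8)

  set.seed(80)
  x <- rand_dna(500); y <- rand_dna(500)
  d <- mlsa_distance(c(a = x, b = y))["a", "b"]
  expect_equal(d, mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]))
})

test_that("coded-array distance counts gaps as differences, NA as missing", {
  m <- rbind(a = c("s1", "s2", "s3"), b = c("s1", "s2", "s3"))
  expect_equal(coded_array_distance(m)["a", "b"], 0)

  m2 <- rbind(a = c("s1", "s2"), b = c("s3", "-"))
  expect_equal(coded_array_distance(m2)["a", "b"], 1)

  m3 <- rbind(a = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8", NA, "s9"),
              b = c("s1", "x2", "s3", "x4", "s5", "-", "s7", "s8", "s9", NA))
  # 8 comparable columns, 3 differ
  expect_equal(coded_array_distance(m3)["a", "b"], 3 / 8)

  m4 <- rbind(a = c("s1", NA), b = c(NA, "s2"))
  expect_error(coded_array_distance(m4), "no comparable")
  m5 <- rbind(a = c("s1", NA), b = c(NA, "s2"), c = c("s1", "s2"))
  expect_warning(d5 <- coded_array_distance(m5, incomparable = "drop"))
  expect_equal(nrow(d5), 2)
})

test_that("OTU binning matches brute-force complete linkage", {
  set.seed(81)
  x <- matrix(runif(24), 12, 2)
  d <- as.matrix(stats::dist(x)); d <- d / max(d)
  rownames(d) <- colnames(d) <- paste0("i", 1:12)
  for (cutoff in c(0.1, 0.3, 0.6)) {
    got <- bin_otus(d, cutoff)
    want <- oracle_complete_linkage(d, cutoff)
    # same partition up to labels
    expect_equal(length(unique(paste(got, want))), length(unique(got)))
    expect_equal(length(unique(got)), length(unique(want)))
  }
  expect_equal(length(unique(bin_otus(d, 1))), 1)
  expect_equal(length(unique(bin_otus(d, 0))), 12)
})

test_that("OTU count is non-increasing in the cutoff", {
  set.seed(82)
  d <- as.matrix(stats::dist(matrix(runif(30), 15, 2)))
  rownames(d) <- colnames(d) <- paste0("i", 1:15)
  counts <- vapply(c(0, 0.1, 0.2, 0.5, 1),
                   function(ct) length(unique(bin_otus(d, ct))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rarefaction endpoints and degenerate cases are exact", {
  one <- rarefaction_curve(c(7), abundances = TRUE)
  expect_equal(one$expected_otus, rep(1, 7))

  distinct <- rarefaction_curve(rep(1, 6), abundances = TRUE)
  expect_equal(distinct$expected_otus, 1:6)

  set.seed(83)
  ab <- c(9, 4, 3, 2, 1, 1)
  rc <- rarefaction_curve(ab, abundances = TRUE)
  expect_equal(rc$expected_otus[length(rc$expected_otus)], length(ab))
  expect_true(all(diff(rc$expected_otus) >= -1e-12))
})

test_that("analytic rarefaction agrees with Monte-Carlo resampling", {
  set.seed(84)
  ab <- c(5, 3, 1, 1)
  rc <- rarefaction_curve(ab, abundances = TRUE)
  mc <- oracle_rarefy_mc(ab, 2, draws = 1e5)
  expect_lt(abs(rc$expected_otus[2] - mc["mean"]), 3 * mc["se"])
  mc5 <- oracle_rarefy_mc(ab, 5, draws = 1e5)
  expect_lt(abs(rc$expected_otus[5] - mc5["mean"]), 3 * mc5["se"])
})

test_that("rarefaction and Chao1 agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(85)
  ab <- c(12, 7, 4, 2, 2, 1, 1, 1)
  rc <- rarefaction_curve(ab, abundances = TRUE)
  for (n in c(3, 10, 20)) {
    expect_equal(rc$expected_otus[n], as.numeric(vegan::rarefy(ab, n)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  est <- vegan::estimateR(ab)
  expect_equal(chao1(ab, abundances = TRUE)$chao1,
               as.numeric(est["S.chao1"]), tolerance = 1e-9)
})

test_that("Chao1 follows the bias-corrected formula", {
  est <- chao1(c(1, 1, 2), abundances = TRUE)
  expect_equal(est$S_obs, 3)
  expect_equal(est$F1, 2)
  expect_equal(est$F2, 1)
  expect_equal(est$chao1, 3.5)

  no_singletons <- chao1(c(3, 4, 2), abundances = TRUE)
  expect_equal(no_singletons$chao1, 3)
  all_big <- chao1(c(5, 7, 3), abundances = TRUE)
  expect_equal(all_big$chao1, all_big$S_obs)

  set.seed(86)
  for (i in 1:10) {
    ab <- sample(1:6, sample(3:12, 1), replace = TRUE)
    est <- chao1(ab, abundances = TRUE)
    expect_gte(est$chao1, est$S_obs)
    if (est$F1 <= 1) expect_equal(est$chao1, est$S_obs)
  }
})

test_that("rank abundance sorts by size with deterministic ties", {
  got <- rank_abundance(c(rep("A", 5), rep("B", 2), rep("C", 2)))
  expect_equal(got$n, c(5, 2, 2))
  expect_equal(got$group, c("A", "B", "C"))
  expect_equal(nrow(rank_abundance(character(0))), 0)
})
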