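set.seed(60)
pool <- replicate(20, rand_dna(39))

test_that("one shared spacer does not link arrays at min_run 2", {
  a <- mk_array("x", c(pool[1], pool[2], pool[3]))
  b <- mk_array("y", c(pool[1], pool[10], pool[11]))
  g <- group_ancestral(list(a, b), min_run = 2)
  expect_equal(length(unique(g$membership$group)), 2)
})

test_that("trailer-only shared runs link strains and are flagged", {
  lx <- mk_array("x", pool[1:4], end = "leader")
  ly <- mk_array("y", pool[5:8], end = "leader")
  tx <- mk_array("x", pool[15:17], end = "trailer")
  ty <- mk_array("y", pool[15:17], end = "trailer")
  g <- group_ancestral(list(lx, ly, tx, ty))
  expect_equal(length(unique(g$membership$group)), 1)
  expect_true(g$links$trailer_only)
})

test_that("grouping is invariant to input order", {
  sim <- simulate_population(
    sim_config(n_strains = 8, n_founders = 3, extra_steps = 2), seed = 14)
  arrays <- sim_to_arrays(sim)
  arrs_c <- Filter(function(a) a$locus == "C", arrays)
  g1 <- group_ancestral(arrs_c)
  set.seed(99)
  g2 <- group_ancestral(sample(arrs_c))
  m <- merge(g1$membership, g2$membership, by = "strain")
  # same partition up to label renaming
  expect_equal(length(unique(paste(m$group.x, m$group.y))),
               length(unique(m$group.x)))
  expect_equal(length(unique(m$group.x)), length(unique(m$group.y)))
})

test_that("ancestral groups recover the founder partition on simulations", {
  sim <- simulate_population(
    sim_config(n_strains = 10, n_founders = 3, extra_steps = 2), seed = 15)
  arrays <- sim_to_arrays(sim)
  for (l in c("C", "A1")) {
    arrs <- Filter(function(a) a$locus == l, arrays)
    g <- group_ancestral(arrs)
    truth_part <- sim$truth$founder_of[g$membership$strain]
    s <- summary_stats(sim$truth, groups = stats::setNames(list(g), l))
    expect_gte(s$ancestral_ari, 0.99)
  }
})

test_that("leader spacers planted internally are reported, disjoint sets are not", {
  leader <- mk_array("x", pool[1:3], end = "leader")
  full <- mk_array("y", c(pool[4:15], pool[2]), end = "full")
  hits <- leader_internal_check(list(leader), list(full), leader_depth = 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$leader_position, 2)
  expect_equal(hits$internal_position, 13)

  full2 <- mk_array("y", pool[4:16], end = "full")
  expect_equal(nrow(leader_internal_check(list(leader), list(full2))), 0)
})

test_that("shared arrays yield no acquisition pairs", {
  a <- mk_array("x", pool[1:6])
  b <- mk_array("y", pool[1:6])
  ct <- build_catalog(spacer_table(list(a, b)))
  pairs <- classify_acquisitions(ct, list(a, b))
  expect_true(all(pairs$status == "ancestral"))
  expect_equal(sum(pairs$status == "acquisition"), 0)
})

test_that("an offset leader match between unrelated strains is an acquisition", {
  set.seed(61)
  src <- rand_dna(45)
  sp_x <- substring(src, 1, 39)
  sp_y <- substring(src, 5, 43)   # offset 4, no SNPs
  a <- mk_array("x", c(sp_x, pool[1:4]), end = "leader")
  b <- mk_array("y", c(sp_y, pool[10:13]), end = "leader")
  ct <- build_catalog(spacer_table(list(a, b)))
  pairs <- classify_acquisitions(ct, list(a, b))
  acq <- pairs[pairs$status == "acquisition", ]
  expect_equal(nrow(acq), 1)
  expect_equal(acq$end_class, "leader-leader")
  expect_equal(abs(acq$offset), 4)
  expect_equal(acq$snps, 0)
})

test_that("two consecutive exact shared spacers are excluded, one is not", {
  # unrelated leader contexts sharing two adjacent identical spacers
  a <- mk_array("x", c(pool[1], pool[2], pool[3], pool[4]), end = "leader")
  b <- mk_array("y", c(pool[10], pool[2], pool[3], pool[11]), end = "leader")
  ct <- build_catalog(spacer_table(list(a, b)))
  pairs <- classify_acquisitions(ct, list(a, b))
  excl <- pairs[pairs$status == "excluded", ]
  expect_equal(nrow(excl), 2)
  expect_true(all(excl$reason == "consecutive-exact"))

  # a single isolated exact pair stays a candidate acquisition
  a2 <- mk_array("x", c(pool[1], pool[2], pool[5]), end = "leader")
  b2 <- mk_array("y", c(pool[10], pool[2], pool[11]), end = "leader")
  ct2 <- build_catalog(spacer_table(list(a2, b2)))
  pairs2 <- classify_acquisitions(ct2, list(a2, b2))
  expect_equal(pairs2$status, "acquisition")
})

test_that("every cross-strain fuzzy match gets exactly one verdict", {
  sim <- simulate_population(
    sim_config(n_strains = 8, n_founders = 2, extra_steps = 2), seed = 16)
  pl <- run_pipeline(sim)
  expect_true(all(pl$pairs$status %in% c("ancestral", "excluded",
                                         "acquisition")))
  expect_true(all(pl$pairs$strain_a != pl$pairs$strain_b))
  expect_false(any(duplicated(pl$pairs[, c("strain_a", "locus_a", "end_a",
                                           "position_a", "strain_b",
                                           "locus_b", "end_b",
                                           "position_b")])))
})

test_that("end summary counts and fractions are correct", {
  empty <- acquisition_end_summary(
    data.frame(status = character(0), end_class = character(0)))
  expect_equal(empty$n, c(0L, 0L, 0L))
  df <- data.frame(
    status = rep("acquisition", 10),
    end_class = c(rep("leader-leader", 4), rep("trailer-trailer", 3),
                  rep("mixed", 3)))
  s <- acquisition_end_summary(df)
  expect_equal(s$fraction, c(0.4, 0.3, 0.3))
})
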