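small_cfg <- function(...) {
  sim_config(n_strains = 8, n_founders = 2, extra_steps = 2, ...)
}

test_that("identical seeds give identical output, different seeds differ", {
  s1 <- simulate_population(small_cfg(), seed = 5)
  s2 <- simulate_population(small_cfg(), seed = 5)
  expect_identical(s1$crispr, s2$crispr)
  expect_identical(s1$mlsa, s2$mlsa)
  expect_identical(s1$viruses, s2$viruses)
  s3 <- simulate_population(small_cfg(), seed = 6)
  expect_false(identical(s1$crispr, s3$crispr))
})

test_that("the zero-rate null model collapses to one clone", {
  sim <- simulate_population(
    sim_config(n_strains = 6, n_founders = 1, acquisition_rate = 0,
               loss_rate = 0, locus_loss_prob = 0, mutation_rate = 0,
               conversion_rate = 0, extra_steps = 2), seed = 30)
  arrays <- sim_to_arrays(sim)
  seqs <- vapply(arrays, function(a) paste(a$spacers$sequence, collapse = "+"),
                 character(1))
  loci <- vapply(arrays, function(a) a$locus, character(1))
  for (l in unique(loci)) {
    expect_length(unique(seqs[loci == l]), 1)
    g <- group_ancestral(arrays[loci == l])
    expect_length(unique(g$membership$group), 1)
  }
  prof <- concatenate_profiles(sim$mlsa)
  expect_equal(epidemic_summary(prof)$dominant_fraction, 1)
  expect_equal(nrow(population_losses(arrays)), 0)
  ct <- build_catalog(spacer_table(arrays))
  pairs <- classify_acquisitions(ct, arrays)
  expect_equal(sum(pairs$status == "acquisition"), 0)
  # no events at all in the logs
  expect_true(all(vapply(sim$truth$logs, length, integer(1)) == 0))
})

test_that("replaying the event log reproduces every strain exactly", {
  sim <- simulate_population(small_cfg(loss_rate = 0.05), seed = 31)
  rp <- replay(sim$truth)
  for (s in names(rp)) {
    expect_identical(rp[[s]]$arrays, sim$truth$arrays_final[[s]])
    expect_identical(rp[[s]]$mlsa, sim$truth$mlsa_final[[s]])
  }
})

test_that("a corrupted log is rejected on replay", {
  sim <- simulate_population(small_cfg(mutation_rate = 2e-5), seed = 32)
  truth <- sim$truth
  mut_strain <- NULL
  for (s in names(truth$logs)) {
    if (any(vapply(truth$logs[[s]], function(e) e$type == "mut",
                   logical(1)))) { mut_strain <- s; break }
  }
  skip_if(is.null(mut_strain), "no mutation event drawn")
  i <- which(vapply(truth$logs[[mut_strain]], function(e) e$type == "mut",
                    logical(1)))[1]
  ev <- truth$logs[[mut_strain]][[i]]
  ev$from <- setdiff(c("A", "C", "G", "T"), ev$from)[1]
  truth$logs[[mut_strain]][[i]] <- ev
  expect_error(replay(truth), "corrupted log")
})

test_that("every emitted spacer traces to a PAM-adjacent virus window", {
  sim <- simulate_population(small_cfg(), seed = 33)
  em <- sim$truth$emitted
  pam <- sim$config$pam
  for (k in seq_len(nrow(em))) {
    v <- sim$viruses[[em$virus[k]]]
    window <- substring(v, em$vstart[k] + 1, em$vend[k])
    if (em$strand[k] == "+") {
      expect_identical(window, em$sequence[k])
      expect_identical(substring(v, em$vstart[k] - 1, em$vstart[k]), pam)
    } else {
      expect_identical(revcomp(window), em$sequence[k])
      expect_identical(revcomp(substring(v, em$vend[k] + 1, em$vend[k] + 2)),
                       pam)
    }
  }
})

test_that("fresh acquisitions sit leader-most and shared trailers persist", {
  sim <- simulate_population(small_cfg(), seed = 34)
  for (s in names(sim$truth$logs)) {
    log <- sim$truth$logs[[s]]
    acq <- Filter(function(e) e$type == "acq", log)
    if (length(acq) == 0) next
    last <- acq[[length(acq)]]
    arr <- sim$truth$arrays_final[[s]][[last$locus]]
    lost <- any(vapply(log, function(e)
      e$type == "loss" && e$locus == last$locus && 1 %in%
        (e$start_pos:(e$start_pos + e$run - 1)), logical(1)))
    if (arr$present && !lost) {
      expect_equal(arr$event[1], last$event)
    }
  }
})

test_that("partition similarity is invariant to strain relabelling", {
  x <- c(1, 1, 2, 2, 3, 3)
  y <- c(2, 2, 1, 1, 3, 3)
  expect_equal(spacerdiv:::adjusted_rand(x, y), 1)
  set.seed(90)
  a <- sample(3, 20, replace = TRUE)
  b <- sample(3, 20, replace = TRUE)
  perm <- sample(20)
  expect_equal(spacerdiv:::adjusted_rand(a, b),
               spacerdiv:::adjusted_rand(a[perm], b[perm]))
  skip_if_not_installed("mclust")
  expect_equal(spacerdiv:::adjusted_rand(a, b),
               mclust::adjustedRandIndex(a, b))
})

test_that("simulator files round-trip through the writers", {
  dir <- tempfile()
  sim <- simulate_population(small_cfg(), seed = 35, out_dir = dir)
  expect_true(file.exists(file.path(dir, "crispr.fasta")))
  expect_true(file.exists(file.path(dir, "viruses.fasta")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  arrays <- load_locus_fasta(file.path(dir, "crispr.fasta"))
  expect_length(arrays, length(sim$crispr))
  mlsa <- load_mlsa_fasta(file.path(dir, paste0("mlsa_", names(sim$mlsa),
                                                ".fasta")))
  expect_equal(unname(mlsa[[1]]), unname(sim$mlsa[[1]]))
  unlink(dir, recursive = TRUE)
})
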