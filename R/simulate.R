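# Forward simulator of a hot-spring host population: CRISPR arrays evolving
# by leader-end acquisition from a shared PAM-constrained virus pool, spacer
# loss and locus loss; MLSA loci evolving by point mutation and gene
# conversion between coexisting lineages. Emits the same FASTA shapes the
# analysis modules consume, plus a ground-truth event log.

#' Simulation configuration
#'
#' Defaults emulate the study population: 39 strains, up to three CRISPR
#' loci (C with the 25-nt C repeat; A1/A2 with the 24-nt A repeat), spacers
#' of ~39 nt between repeats, leader-end hypervariability with conserved
#' trailers, spacer-loss runs with mean 2 and maximum 5, 12 MLSA loci
#' totalling 6684 bp, and a small shared virus pool with a dinucleotide PAM
#' so that independent acquisitions of overlapping protospacers arise
#' naturally. Acquisition/loss rates are free parameters (no empirical
#' estimates exist); defaults are chosen to reproduce the qualitative
#' regime: diverged leaders, shared trailers, a dominant MLSA genotype near
#' half the sample.
#'
#' @param n_strains number of sampled strains.
#' @param n_founders founding lineages with independent root arrays.
#' @param loci named character vector: locus id -> repeat family.
#' @param root_array_size spacers per locus in each founder.
#' @param n_viruses,virus_length the shared virus pool (default: three SSV-sized 15-kb genomes).
#' @param pam protospacer-adjacent dinucleotide required 5' of every
#'   acquired protospacer.
#' @param spacer_lengths integer vector of admissible spacer lengths
#'   (sampled uniformly; default 37:41, mean 39).
#' @param acquisition_rate per-locus, per-lineage, per-step probability of
#'   acquiring one new leader spacer.
#' @param loss_rate per-locus, per-lineage, per-step probability of one
#'   loss event.
#' @param loss_run_mean,loss_run_max truncated-geometric run-length law for
#'   consecutive lost spacers.
#' @param locus_loss_prob per-locus, per-step probability of losing the
#'   whole locus.
#' @param mlsa_loci,mlsa_locus_length MLSA loci count and aligned length
#'   (12 x 557 = 6684 bp).
#' @param mutation_rate per-site, per-step MLSA substitution probability.
#' @param conversion_rate per-lineage, per-step probability of a gene
#'   conversion importing a tract from another coexisting lineage.
#' @param conversion_tract conversion tract length (nt).
#' @param leader_depth,trailer_depth spacers sequenced from each end.
#' @param full_fraction fraction of strains whose loci are emitted fully
#'   sequenced.
#' @param extra_steps evolution steps after the last lineage split
#'   (terminal divergence).
#' @param flank_length random flanking sequence outside the outermost
#'   repeats in emitted records.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_strains = 39, n_founders = 4,
                       loci = c(C = "C", A1 = "A", A2 = "A"),
                       root_array_size = 20,
                       n_viruses = 3, virus_length = 15000, pam = "GG",
                       spacer_lengths = 37:41,
                       acquisition_rate = 0.25, loss_rate = 0.01,
                       loss_run_mean = 2, loss_run_max = 5,
                       locus_loss_prob = 0.002,
                       mlsa_loci = 12, mlsa_locus_length = 557,
                       mutation_rate = 2.5e-6, conversion_rate = 0.02,
                       conversion_tract = 500,
                       leader_depth = 10, trailer_depth = 10,
                       full_fraction = 0.2, extra_steps = 5,
                       flank_length = 15) {
  cfg <- as.list(environment())
  pam <- check_dna(pam, "pam", allow_n = FALSE)
  if (nchar(pam) != 2) stop("pam must be a dinucleotide")
  rates <- c(acquisition_rate, loss_rate, locus_loss_prob, mutation_rate,
             conversion_rate)
  if (any(rates < 0) || any(rates[c(1, 2, 3, 5)] > 1)) {
    stop("rates must be probabilities in [0, 1]")
  }
  if (n_strains < n_founders || n_founders < 1) {
    stop("need 1 <= n_founders <= n_strains")
  }
  if (length(loci) < 1 || length(loci) > 3 || is.null(names(loci))) {
    stop("loci must be a named vector of 1-3 locus families")
  }
  if (loss_run_mean < 1 || loss_run_mean > loss_run_max) {
    stop("loss_run_mean must lie in [1, loss_run_max]")
  }
  if (virus_length < max(spacer_lengths) + nchar(pam)) {
    stop("viruses are shorter than spacer + PAM")
  }
  cfg$pam <- pam
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d strains / %d founders; loci %s; %d viruses x %d nt (PAM %s); acq %.2f, loss %.2f (runs mean %.1f max %d); MLSA %d x %d bp\n",
    x$n_strains, x$n_founders, paste(names(x$loci), collapse = ","),
    x$n_viruses, x$virus_length, x$pam, x$acquisition_rate, x$loss_rate,
    x$loss_run_mean, x$loss_run_max, x$mlsa_loci, x$mlsa_locus_length))
  invisible(x)
}

# geometric success probability giving the target mean on support 1..max
trunc_geom_p <- function(mean, max) {
  if (mean <= 1) return(1)
  if (mean >= (1 + max) / 2) return(1e-9)
  tg_mean <- function(p) {
    k <- seq_len(max)
    w <- (1 - p)^(k - 1) * p
    sum(k * w) / sum(w)
  }
  stats::uniroot(function(p) tg_mean(p) - mean, c(1e-9, 1 - 1e-9))$root
}

rtrunc_geom <- function(n, p, max) {
  k <- seq_len(max)
  w <- (1 - p)^(k - 1) * p
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# PAM-adjacent acquisition sites for one virus: data.frame of windows the
# protospacer may occupy, per strand, in plus-strand 0-based half-open
# coordinates. The PAM sits immediately 5' of the protospacer on the
# matched strand and is not part of the spacer.
pam_sites <- function(virus, pam, max_len) {
  find <- function(s, p) {
    hits <- gregexpr(p, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  }
  n <- nchar(virus)
  plus <- find(virus, pam)                     # PAM start, 0-based
  plus <- plus[plus + 2 + max_len <= n]        # window must fit
  minus <- find(revcomp(virus), pam)
  minus <- minus[minus + 2 + max_len <= n]
  list(plus = plus, minus = minus, length = n)
}

# One acquisition draw. A window overlapping one the array already carries
# (same virus and strand) is redrawn: immunity against that region already
# exists, so re-acquisition is suppressed — and identical spacers within
# one array are avoided. After `max_tries` rejections the draw is accepted
# anyway (degenerate configs with very few PAM sites).
draw_spacer <- function(viruses, sites, cfg, existing = NULL,
                        max_tries = 50) {
  tries <- 0
  repeat {
    tries <- tries + 1
    v <- sample(length(viruses), 1)
    strand <- sample(c("+", "-"), 1)
    cand <- if (strand == "+") sites[[v]]$plus else sites[[v]]$minus
    if (length(cand) == 0) next
    p <- cand[sample.int(length(cand), 1)]
    len <- cfg$spacer_lengths[sample.int(length(cfg$spacer_lengths), 1)]
    n <- sites[[v]]$length
    if (strand == "+") {
      start <- p + 2L; end <- start + len
    } else {
      # coordinates of the protospacer on the plus strand
      rc_start <- p + 2L; rc_end <- rc_start + len
      start <- n - rc_end; end <- n - rc_start
    }
    if (!is.null(existing) && tries <= max_tries) {
      clash <- vapply(existing, function(e) {
        e$virus == v && e$strand == strand &&
          e$start < end && e$end > start
      }, logical(1))
      if (any(clash)) next
    }
    seq <- substring(viruses[[v]], start + 1L, end)
    if (strand == "-") seq <- revcomp(seq)
    return(list(virus = v, strand = strand, start = start, end = end,
                seq = seq))
  }
}

#' Simulate a hot-spring population
#'
#' Discrete-step binary lineage process: founders carry independent root
#' arrays (themselves PAM-adjacent draws from the virus pool); at each step
#' every extant lineage may acquire a leader spacer, lose a run of spacers,
#' lose a locus, mutate MLSA sites, or import a conversion tract from a
#' coexisting lineage; one lineage splits per step until `n_strains` are
#' extant, then `extra_steps` more steps run. Arrays are emitted clipped to
#' the configured end depths (leader/trailer fragments) except for a
#' fully-sequenced subset, as repeat-interleaved locus sequences with
#' `strain|locus|end` headers.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param out_dir optional directory: writes `crispr.fasta`,
#'   `mlsa_<locus>.fasta`, `viruses.fasta` and `truth.json`.
#' @return object of class `sim_population`: list with `crispr` (named
#'   character, FASTA records), `mlsa` (list locus -> named character),
#'   `viruses`, and `truth` (tree, founder partition, per-strain event
#'   logs, final states, emitted-spacer provenance, full-strain subset).
#' @export
simulate_population <- function(config = sim_config(), seed = 1,
                                out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config

  viruses <- stats::setNames(
    vapply(seq_len(cfg$n_viruses), function(i) random_dna(cfg$virus_length),
           character(1)),
    sprintf("virus%02d", seq_len(cfg$n_viruses)))
  sites <- lapply(viruses, pam_sites, pam = cfg$pam,
                  max_len = max(cfg$spacer_lengths))
  if (all(vapply(sites, function(s) length(s$plus) + length(s$minus),
                 integer(1)) == 0)) {
    stop("no PAM site in any virus; increase virus_length")
  }

  loss_p <- trunc_geom_p(cfg$loss_run_mean, cfg$loss_run_max)
  event_counter <- 0L
  acq_registry <- list()
  new_event <- function(d) {
    event_counter <<- event_counter + 1L
    acq_registry[[event_counter]] <<- d
    event_counter
  }

  mlsa_root <- stats::setNames(
    vapply(seq_len(cfg$mlsa_loci), function(i) random_dna(cfg$mlsa_locus_length),
           character(1)),
    sprintf("locus%02d", seq_len(cfg$mlsa_loci)))

  make_founder <- function(fid) {
    genome_draws <- list()   # immunity is genome-wide: reject across loci
    arrays <- lapply(names(cfg$loci), function(l) {
      draws <- list()
      for (i in seq_len(cfg$root_array_size)) {
        d <- draw_spacer(viruses, sites, cfg, existing = genome_draws)
        d$event <- new_event(d)
        draws[[i]] <- d
        genome_draws[[length(genome_draws) + 1L]] <<- d
      }
      list(present = TRUE,
           seq = vapply(draws, `[[`, character(1), "seq"),
           event = vapply(draws, `[[`, integer(1), "event"))
    })
    names(arrays) <- names(cfg$loci)
    list(node = fid, founder = fid, arrays = arrays, mlsa = mlsa_root,
         log = list())
  }

  pop <- lapply(seq_len(cfg$n_founders), make_founder)
  node_counter <- as.integer(cfg$n_founders)
  tree <- data.frame(parent = integer(0), child = integer(0))
  roots <- lapply(pop, function(s) list(arrays = s$arrays, mlsa = s$mlsa))

  evolve_step <- function(state) {
    for (l in names(cfg$loci)) {
      arr <- state$arrays[[l]]
      if (!arr$present) next
      if (stats::runif(1) < cfg$acquisition_rate) {
        own <- unlist(lapply(state$arrays, `[[`, "event"))
        d <- draw_spacer(viruses, sites, cfg,
                         existing = acq_registry[own])
        d$event <- new_event(d)
        arr$seq <- c(d$seq, arr$seq)
        arr$event <- c(d$event, arr$event)
        state$log[[length(state$log) + 1L]] <-
          list(type = "acq", locus = l, event = d$event, virus = d$virus,
               start = d$start, end = d$end, strand = d$strand, seq = d$seq)
      }
      if (length(arr$seq) > 1 && stats::runif(1) < cfg$loss_rate) {
        k <- min(rtrunc_geom(1, loss_p, cfg$loss_run_max),
                 length(arr$seq) - 1L)
        start <- sample.int(length(arr$seq) - k + 1L, 1)
        idx <- start:(start + k - 1L)
        state$log[[length(state$log) + 1L]] <-
          list(type = "loss", locus = l, start_pos = start, run = k,
               lost_events = arr$event[idx])
        arr$seq <- arr$seq[-idx]; arr$event <- arr$event[-idx]
      }
      if (stats::runif(1) < cfg$locus_loss_prob) {
        arr$present <- FALSE; arr$seq <- character(0); arr$event <- integer(0)
        state$log[[length(state$log) + 1L]] <- list(type = "locus_loss",
                                                    locus = l)
      }
      state$arrays[[l]] <- arr
    }
    for (l in names(state$mlsa)) {
      n_mut <- stats::rbinom(1, cfg$mlsa_locus_length, cfg$mutation_rate)
      if (n_mut > 0) {
        pos <- sample.int(cfg$mlsa_locus_length, n_mut)
        for (p in pos) {
          from <- substring(state$mlsa[[l]], p, p)
          to <- sample(setdiff(DNA_BASES, from), 1)
          substring(state$mlsa[[l]], p, p) <- to
          state$log[[length(state$log) + 1L]] <-
            list(type = "mut", locus = l, pos = p, from = from, to = to)
        }
      }
    }
    state
  }

  run_round <- function() {
    pop <<- lapply(pop, evolve_step)
    # gene conversion between coexisting lineages
    if (length(pop) > 1) {
      for (i in seq_along(pop)) {
        if (stats::runif(1) < cfg$conversion_rate) {
          donor <- sample(setdiff(seq_along(pop), i), 1)
          l <- sample(names(mlsa_root), 1)
          start <- sample.int(cfg$mlsa_locus_length, 1)
          end <- min(cfg$mlsa_locus_length, start + cfg$conversion_tract - 1L)
          bases <- substring(pop[[donor]]$mlsa[[l]], start, end)
          substring(pop[[i]]$mlsa[[l]], start, end) <- bases
          pop[[i]]$log[[length(pop[[i]]$log) + 1L]] <-
            list(type = "conv", locus = l, start = start, len = end - start + 1L,
                 donor = pop[[donor]]$node, bases = bases)
        }
      }
    }
  }

  while (length(pop) < cfg$n_strains) {
    run_round()
    i <- sample.int(length(pop), 1)
    node_counter <- node_counter + 1L
    child <- pop[[i]]
    child$node <- node_counter
    tree <- rbind(tree, data.frame(parent = pop[[i]]$node,
                                   child = node_counter))
    pop[[length(pop) + 1L]] <- child
  }
  for (s in seq_len(cfg$extra_steps)) run_round()

  # emission
  strains <- sprintf("S%02d", seq_along(pop))
  for (i in seq_along(pop)) pop[[i]]$strain <- strains[i]
  n_full <- round(cfg$full_fraction * cfg$n_strains)
  full_strains <- sort(sample(strains, n_full))
  repeats <- builtin_repeats()

  crispr <- character(0)
  origin <- list()
  emit <- function(state, l, end, idx) {
    arr <- state$arrays[[l]]
    fam <- cfg$loci[[l]]
    rep_seq <- repeats[[fam]]$sequence
    body <- paste0(rep_seq, paste0(arr$seq[idx], rep_seq, collapse = ""))
    header <- paste(state$strain, l, end, sep = "|")
    crispr[header] <<- paste0(random_dna(cfg$flank_length), body,
                              random_dna(cfg$flank_length))
    evs <- acq_registry[arr$event[idx]]
    origin[[length(origin) + 1L]] <<- data.frame(
      strain = state$strain, locus = l, end = end,
      position = seq_along(idx), event = arr$event[idx],
      virus = vapply(evs, `[[`, integer(1), "virus"),
      vstart = vapply(evs, `[[`, integer(1), "start"),
      vend = vapply(evs, `[[`, integer(1), "end"),
      strand = vapply(evs, `[[`, character(1), "strand"),
      sequence = arr$seq[idx], stringsAsFactors = FALSE)
  }
  for (state in pop) {
    for (l in names(cfg$loci)) {
      arr <- state$arrays[[l]]
      if (!arr$present || length(arr$seq) == 0) next
      n <- length(arr$seq)
      if (state$strain %in% full_strains ||
          n <= cfg$leader_depth + cfg$trailer_depth) {
        emit(state, l, "full", seq_len(n))
      } else {
        emit(state, l, "leader", seq_len(cfg$leader_depth))
        emit(state, l, "trailer", (n - cfg$trailer_depth + 1L):n)
      }
    }
  }
  origin <- if (length(origin)) do.call(rbind, origin) else
    data.frame(strain = character(0), locus = character(0), end = character(0),
               position = integer(0), event = integer(0), virus = integer(0),
               vstart = integer(0), vend = integer(0), strand = character(0),
               sequence = character(0), stringsAsFactors = FALSE)

  mlsa <- lapply(names(mlsa_root), function(l) {
    stats::setNames(vapply(pop, function(s) s$mlsa[[l]], character(1)), strains)
  })
  names(mlsa) <- names(mlsa_root)

  truth <- list(
    seed = as.integer(seed),
    tree = tree,
    founder_of = stats::setNames(vapply(pop, `[[`, integer(1), "founder"),
                                 strains),
    node_of = stats::setNames(vapply(pop, `[[`, integer(1), "node"), strains),
    roots = roots,
    mlsa_root = mlsa_root,
    logs = stats::setNames(lapply(pop, `[[`, "log"), strains),
    arrays_final = stats::setNames(lapply(pop, `[[`, "arrays"), strains),
    mlsa_final = stats::setNames(lapply(pop, `[[`, "mlsa"), strains),
    emitted = origin,
    full_strains = full_strains
  )

  res <- structure(
    list(crispr = crispr, mlsa = mlsa, viruses = viruses, truth = truth,
         config = cfg, seed = as.integer(seed)),
    class = "sim_population")
  if (!is.null(out_dir)) write_sim_population(res, out_dir)
  res
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "<sim_population> %d strains, %d CRISPR records (%d spacers emitted), %d MLSA loci, %d viruses [seed %d]\n",
    x$config$n_strains, length(x$crispr), nrow(x$truth$emitted),
    length(x$mlsa), length(x$viruses), x$seed))
  invisible(x)
}

#' Write simulator output to FASTA files
#'
#' @param sim a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_population <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "crispr.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$crispr), p)
  paths <- c(paths, p)
  for (l in names(sim$mlsa)) {
    p <- file.path(dir, paste0("mlsa_", l, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$mlsa[[l]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "viruses.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$viruses), p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Replay a ground-truth event log
#'
#' Rebuilds every strain's final CRISPR arrays and MLSA sequences by
#' applying its event log to its founder's root state. Replay must
#' reproduce the simulator's emitted states exactly; it is the round-trip
#' check that the log is complete.
#'
#' @param truth the `truth` component of a [simulate_population()] result.
#' @return list per strain: `arrays` (per locus: present/seq/event) and
#'   `mlsa`.
#' @export
replay <- function(truth) {
  out <- lapply(names(truth$logs), function(strain) {
    fid <- truth$founder_of[[strain]]
    arrays <- truth$roots[[fid]]$arrays
    mlsa <- truth$roots[[fid]]$mlsa
    for (ev in truth$logs[[strain]]) {
      switch(ev$type,
        acq = {
          arr <- arrays[[ev$locus]]
          arr$seq <- c(ev$seq, arr$seq)
          arr$event <- c(ev$event, arr$event)
          arrays[[ev$locus]] <- arr
        },
        loss = {
          arr <- arrays[[ev$locus]]
          idx <- ev$start_pos:(ev$start_pos + ev$run - 1L)
          if (max(idx) > length(arr$seq)) {
            stop("corrupted log: loss past array end in ", strain)
          }
          arr$seq <- arr$seq[-idx]; arr$event <- arr$event[-idx]
          arrays[[ev$locus]] <- arr
        },
        locus_loss = {
          arrays[[ev$locus]] <- list(present = FALSE, seq = character(0),
                                     event = integer(0))
        },
        mut = {
          if (substring(mlsa[[ev$locus]], ev$pos, ev$pos) != ev$from) {
            stop("corrupted log: mutation base mismatch in ", strain)
          }
          substring(mlsa[[ev$locus]], ev$pos, ev$pos) <- ev$to
        },
        conv = {
          substring(mlsa[[ev$locus]], ev$start,
                    ev$start + ev$len - 1L) <- ev$bases
        },
        stop("unknown event type: ", ev$type)
      )
    }
    list(arrays = arrays, mlsa = mlsa)
  })
  stats::setNames(out, names(truth$logs))
}

#' Ground-truth independent-acquisition pairs among emitted spacers
#'
#' Two emitted spacers in different strains form a true independent
#' acquisition pair when they come from different acquisition events whose
#' protospacer windows lie on the same virus and strand and overlap by at
#' least `min_overlap` nt (the copies are identical over the overlap, so
#' the identity threshold is met by construction). Pairs sharing an event
#' id are inherited, i.e. ancestral.
#'
#' @param truth the `truth` component of a [simulate_population()] result.
#' @param min_overlap minimum window overlap (default 17 nt).
#' @return data.frame of instance pairs (strain/locus/end/position both
#'   sides, virus, overlap).
#' @export
true_acquisition_pairs <- function(truth, min_overlap = 17) {
  em <- truth$emitted
  out <- list()
  # only windows on the same virus+strand can pair
  groups <- split(seq_len(nrow(em)), paste(em$virus, em$strand))
  for (g in groups) {
    if (length(g) < 2) next
    for (ii in seq_along(g)[-length(g)]) {
      for (jj in (ii + 1):length(g)) {
        i <- g[ii]; j <- g[jj]
        if (em$strain[i] == em$strain[j]) next
        if (em$event[i] == em$event[j]) next
        ov <- min(em$vend[i], em$vend[j]) - max(em$vstart[i], em$vstart[j])
        if (ov >= min_overlap) {
          out[[length(out) + 1L]] <- data.frame(
            strain_a = em$strain[i], locus_a = em$locus[i],
            end_a = em$end[i], position_a = em$position[i],
            strain_b = em$strain[j], locus_b = em$locus[j],
            end_b = em$end[j], position_b = em$position[j],
            virus = em$virus[i], overlap = ov, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else {
    data.frame(strain_a = character(0), locus_a = character(0),
               end_a = character(0), position_a = integer(0),
               strain_b = character(0), locus_b = character(0),
               end_b = character(0), position_b = integer(0),
               virus = integer(0), overlap = integer(0),
               stringsAsFactors = FALSE)
  }
}

# unordered instance-pair keys for matching detected vs true pairs
pair_keys <- function(df) {
  ka <- paste(df$strain_a, df$locus_a, df$end_a, df$position_a, sep = "|")
  kb <- paste(df$strain_b, df$locus_b, df$end_b, df$position_b, sep = "|")
  paste(pmin(ka, kb), pmax(ka, kb), sep = "~")
}

# adjusted Rand index between two partitions over the same elements
adjusted_rand <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) return(1)
  tab <- table(x, y)
  a <- rowSums(tab); b <- colSums(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Recovery report: analysis results against simulator ground truth
#'
#' @param truth the `truth` component of a [simulate_population()] result.
#' @param losses deduplicated loss events (see [detect_losses()]); the same
#'   physical loss seen against several partners should be collapsed by
#'   (strain, locus, end, after_position, run_length) before calling.
#' @param groups named list locus -> [group_ancestral()] result (optional).
#' @param pairs a [classify_acquisitions()] result (optional).
#' @return list of recovery metrics: loss-run mean/max/count, per-locus
#'   adjusted Rand index of ancestral groups vs the founder partition,
#'   acquisition precision/recall, and the leader-leader fraction of
#'   detected acquisition pairs.
#' @export
summary_stats <- function(truth, losses = NULL, groups = NULL, pairs = NULL) {
  out <- list()
  if (!is.null(losses)) {
    out$loss_runs_detected <- nrow(losses)
    out$loss_run_mean <- if (nrow(losses)) mean(losses$run_length) else NA_real_
    out$loss_run_max <- if (nrow(losses)) max(losses$run_length) else NA_integer_
  }
  if (!is.null(groups)) {
    out$ancestral_ari <- vapply(names(groups), function(l) {
      mem <- groups[[l]]$membership
      adjusted_rand(mem$group, truth$founder_of[mem$strain])
    }, numeric(1))
  }
  if (!is.null(pairs)) {
    detected <- pairs[pairs$status == "acquisition", , drop = FALSE]
    truth_pairs <- true_acquisition_pairs(truth)
    dk <- pair_keys(detected); tk <- pair_keys(truth_pairs)
    out$n_detected_pairs <- length(dk)
    out$n_true_pairs <- length(tk)
    # precision against ancestry: a detected pair is correct iff its two
    # spacers trace to *different* acquisition events (pairs with window
    # overlap just under the truth cutoff can still legitimately satisfy
    # the sequence-level match rule, and are still independent)
    em <- truth$emitted
    ek <- paste(em$strain, em$locus, em$end, em$position, sep = "|")
    ev_a <- em$event[match(paste(detected$strain_a, detected$locus_a,
                                 detected$end_a, detected$position_a,
                                 sep = "|"), ek)]
    ev_b <- em$event[match(paste(detected$strain_b, detected$locus_b,
                                 detected$end_b, detected$position_b,
                                 sep = "|"), ek)]
    out$acquisition_precision <- if (length(dk)) mean(ev_a != ev_b) else NA_real_
    out$acquisition_recall <- if (length(tk)) mean(tk %in% dk) else NA_real_
    ends <- acquisition_end_summary(pairs)
    out$leader_leader_fraction <-
      ends$fraction[ends$end_class == "leader-leader"]
  }
  out
}
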