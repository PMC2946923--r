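# Ancestral grouping, the leader-internal check, and independent-acquisition
# classification.

# All fragment pairings of two strains at one locus. Cross-end pairs are
# included: when arrays are short the leader and trailer windows overlap,
# and shared context there is real ancestry evidence (a disjoint pair just
# aligns with zero match columns).
compatible_pairs <- function(arrs_a, arrs_b) {
  out <- list()
  for (x in arrs_a) {
    for (y in arrs_b) {
      out[[length(out) + 1L]] <- list(x = x, y = y)
    }
  }
  out
}

comparison_label <- function(x, y) {
  if (x$end == y$end && x$end != "full") x$end
  else if (x$end == "full" || y$end == "full") "full"
  else "cross"
}

#' Group arrays of one locus by shared ancestry
#'
#' Two arrays are ancestrally related when identical spacers occur in the
#' same spacer context: their spacer-level alignment contains at least
#' `min_run` match columns in a row, allowing loss gaps between them (and
#' mismatch columns cannot occur, see [align_arrays()]). Strains are grouped
#' by single linkage over these pairwise links; singletons are permitted.
#' Links supported only by trailer-end fragments are flagged
#' `trailer_only` — pairs whose sole remaining evidence of common ancestry
#' is the conserved trailer end.
#'
#' @param arrays list of [spacer_array()]s, all from one locus (leader,
#'   trailer and/or full fragments).
#' @param min_run minimum number of match columns to link two strains
#'   (default 2: "multiple identical spacers in a row").
#' @return object of class `ancestral_groups`: list with `membership`
#'   (data.frame strain, group), `links` (strain_a, strain_b, end, n_match,
#'   trailer_only), `locus`, `min_run`.
#' @export
group_ancestral <- function(arrays, min_run = 2) {
  stopifnot(min_run >= 1)
  if (length(arrays) == 0) stop("no arrays given")
  loci <- unique(vapply(arrays, function(a) a$locus, character(1)))
  if (length(loci) != 1) {
    stop("arrays span multiple loci (", paste(loci, collapse = ", "),
         "); group one locus at a time", call. = FALSE)
  }
  strains <- sort(unique(vapply(arrays, function(a) a$strain, character(1))))
  by_strain <- lapply(strains, function(s) {
    Filter(function(a) a$strain == s, arrays)
  })
  names(by_strain) <- strains

  parent <- uf_new(length(strains))
  links <- list()
  n <- length(strains)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        evid <- list()
        for (p in compatible_pairs(by_strain[[i]], by_strain[[j]])) {
          aln <- align_arrays(p$x, p$y, check_ends = FALSE)
          if (aln$n_match >= min_run) {
            evid[[length(evid) + 1L]] <- data.frame(
              end = comparison_label(p$x, p$y), n_match = aln$n_match,
              stringsAsFactors = FALSE)
          }
        }
        if (length(evid)) {
          ev <- do.call(rbind, evid)
          parent <- uf_union(parent, i, j)
          links[[length(links) + 1L]] <- data.frame(
            strain_a = strains[i], strain_b = strains[j],
            end = paste(sort(unique(ev$end)), collapse = "+"),
            n_match = max(ev$n_match),
            trailer_only = all(ev$end == "trailer"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  comp <- uf_components(parent)
  structure(
    list(
      membership = data.frame(strain = strains, group = comp,
                              stringsAsFactors = FALSE),
      links = if (length(links)) do.call(rbind, links) else
        data.frame(strain_a = character(0), strain_b = character(0),
                   end = character(0), n_match = integer(0),
                   trailer_only = logical(0), stringsAsFactors = FALSE),
      locus = loci, min_run = min_run
    ),
    class = "ancestral_groups"
  )
}

#' @export
print.ancestral_groups <- function(x, ...) {
  cat(sprintf("<ancestral_groups> locus %s: %d strains in %d groups (min_run %d)\n",
              x$locus, nrow(x$membership), length(unique(x$membership$group)),
              x$min_run))
  invisible(x)
}

#' Search leader-end spacers inside other strains' full loci
#'
#' If leader-end hypervariability arose from loss at the leader rather than
#' new acquisition, leader spacers of one strain should reappear internally
#' (past the leader region) in fully sequenced loci of other strains. This
#' check searches every leader-end spacer (exact identity) against internal
#' positions of every other strain's full arrays; an empty result supports
#' acquisition at the leader.
#'
#' When the two strains are ancestrally related at the locus, a shared
#' spacer shifted past the depth cutoff merely by a difference in
#' acquisition counts still sits in its shared context (a match column of
#' the pairwise alignment); with `exclude_aligned` (the default) such
#' in-context matches are not reported — only out-of-context internal
#' relocations count.
#'
#' @param leader_arrays [spacer_array()]s with end `"leader"`.
#' @param full_arrays [spacer_array()]s with end `"full"`.
#' @param leader_depth positions `<= leader_depth` of a full array count as
#'   its leader region and are excluded from the internal search (default
#'   10).
#' @param exclude_aligned drop hits that occupy a match column in the
#'   alignment of the two fragments when the strains are ancestrally
#'   linked there (default TRUE).
#' @param min_run ancestral-link threshold used by `exclude_aligned`.
#' @return data.frame of hits: leader_strain, leader_locus, leader_position,
#'   full_strain, full_locus, internal_position, sequence. Zero rows is the
#'   expected outcome.
#' @export
leader_internal_check <- function(leader_arrays, full_arrays,
                                  leader_depth = 10, exclude_aligned = TRUE,
                                  min_run = 2) {
  hits <- list()
  for (la in leader_arrays) {
    if (la$end != "leader") next
    for (fa in full_arrays) {
      if (fa$end != "full" || fa$strain == la$strain) next
      internal <- fa$spacers[fa$spacers$position > leader_depth, , drop = FALSE]
      if (nrow(internal) == 0) next
      aln <- NULL
      for (k in seq_len(nrow(la$spacers))) {
        where <- which(internal$sequence == la$spacers$sequence[k])
        for (w in where) {
          if (exclude_aligned && la$locus == fa$locus) {
            if (is.null(aln)) aln <- align_arrays(la, fa)
            if (aln$n_match >= min_run) {
              in_ctx <- any(!is.na(aln$columns$a_pos) &
                              !is.na(aln$columns$b_pos) &
                              aln$columns$a_pos == la$spacers$position[k] &
                              aln$columns$b_pos == internal$position[w])
              if (in_ctx) next
            }
          }
          hits[[length(hits) + 1L]] <- data.frame(
            leader_strain = la$strain, leader_locus = la$locus,
            leader_position = la$spacers$position[k],
            full_strain = fa$strain, full_locus = fa$locus,
            internal_position = internal$position[w],
            sequence = la$spacers$sequence[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits)) {
    res <- do.call(rbind, hits); rownames(res) <- NULL; res
  } else {
    data.frame(leader_strain = character(0), leader_locus = character(0),
               leader_position = integer(0), full_strain = character(0),
               full_locus = character(0), internal_position = integer(0),
               sequence = character(0), stringsAsFactors = FALSE)
  }
}

#' Classify cross-strain fuzzy spacer matches
#'
#' Every fuzzy match (88%/17-nt rule) between spacers of two different
#' strains is placed in exactly one of three classes:
#'
#' * `ancestral` — the two strains are ancestrally related at the locus
#'   (some compatible fragment alignment between them has at least
#'   `min_run` match columns) and the pair itself sits in a match column of
#'   its own fragments' alignment: the shared spacer context marks common
#'   descent, not independent acquisition. Discarded from the acquisition
#'   count. An isolated identical pair between otherwise unrelated arrays
#'   is *not* ancestral — a single self-aligning spacer is no context.
#' * `excluded` — part of a run of at least two consecutive 100%-identity
#'   full-length pairs between the two strains in the same relative order;
#'   two consecutive exact shared spacers are overwhelmingly inheritance
#'   even without wider context, so these are conservatively removed.
#' * `acquisition` — the remainder: independent acquisitions of nearly the
#'   same protospacer, annotated with offset/SNP signature and end class
#'   (leader-leader, trailer-trailer, or mixed).
#'
#' @param catalog a [build_catalog()] result over the spacers of `arrays`.
#' @param arrays the list of [spacer_array()]s the catalog was built from.
#' @param min_run ancestral-link threshold, as in [group_ancestral()].
#' @param leader_depth for `"full"` arrays, positions `<= leader_depth`
#'   classify as leader-end (default 10); fragment metadata is used
#'   otherwise.
#' @return object of class `acquisition_pairs`: data.frame with one row per
#'   candidate pair (strain/locus/end/position for both sides, offset,
#'   overlap, identity, snps, end_class, status, reason).
#' @export
classify_acquisitions <- function(catalog, arrays, min_run = 2,
                                  leader_depth = 10) {
  stopifnot(inherits(catalog, "spacer_catalog"))
  st <- catalog$spacers
  st$row <- seq_len(nrow(st))
  key <- paste(st$strain, st$locus, st$end, sep = "|")
  akeys <- vapply(arrays, function(a) paste(a$strain, a$locus, a$end, sep = "|"),
                  character(1))
  arr_idx <- match(key, akeys)
  if (anyNA(arr_idx)) {
    stop("catalog spacers do not all map onto the supplied arrays")
  }

  # class-level fuzzy edges, keyed "i:j" with i < j
  edges <- catalog$matches
  edge_key <- paste(pmin(edges$class_a, edges$class_b),
                    pmax(edges$class_a, edges$class_b), sep = ":")

  # candidate instance pairs: same exact class, or fuzzy-matched classes
  by_class <- split(st$row, st$exact_class)
  cand <- list()
  add_pairs <- function(rows_a, rows_b, cand) {
    for (ra in rows_a) {
      for (rb in rows_b) {
        if (ra < rb && st$strain[ra] != st$strain[rb]) {
          cand[[length(cand) + 1L]] <- c(ra, rb)
        } else if (rb < ra && st$strain[ra] != st$strain[rb]) {
          cand[[length(cand) + 1L]] <- c(rb, ra)
        }
      }
    }
    cand
  }
  for (cls in names(by_class)) {
    rows <- by_class[[cls]]
    if (length(rows) > 1) {
      for (u in seq_along(rows)[-length(rows)]) {
        cand <- add_pairs(rows[u], rows[(u + 1):length(rows)], cand)
      }
    }
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      cand <- add_pairs(by_class[[as.character(edges$class_a[k])]],
                        by_class[[as.character(edges$class_b[k])]], cand)
    }
  }
  if (length(cand) == 0) {
    return(empty_acquisitions(min_run, leader_depth))
  }
  cand <- unique(do.call(rbind, cand))

  aln_cache <- new.env(parent = emptyenv())
  get_alignment <- function(ia, ib) {
    ck <- paste(ia, ib, sep = "~")
    if (!is.null(aln_cache[[ck]])) return(aln_cache[[ck]])
    x <- arrays[[ia]]; y <- arrays[[ib]]
    aln <- if (x$locus == y$locus) {
      align_arrays(x, y, check_ends = FALSE)
    } else {
      NA
    }
    aln_cache[[ck]] <- aln
    aln
  }

  # strain-pair ancestral linkage at a locus: any compatible fragment
  # alignment with >= min_run match columns
  strain_arr <- split(seq_along(arrays),
                      vapply(arrays, function(a) paste(a$strain, a$locus, sep = "|"),
                             character(1)))
  link_cache <- new.env(parent = emptyenv())
  strains_linked <- function(sa, sb, locus) {
    ck <- paste(sa, sb, locus, sep = "|")
    if (!is.null(link_cache[[ck]])) return(link_cache[[ck]])
    ia_all <- strain_arr[[paste(sa, locus, sep = "|")]] %||% integer(0)
    ib_all <- strain_arr[[paste(sb, locus, sep = "|")]] %||% integer(0)
    linked <- FALSE
    for (ia in ia_all) {
      for (ib in ib_all) {
        aln <- get_alignment(ia, ib)
        if (inherits(aln, "array_alignment") && aln$n_match >= min_run) {
          linked <- TRUE
          break
        }
      }
      if (linked) break
    }
    link_cache[[ck]] <- linked
    linked
  }

  end_class_of <- function(row) {
    e <- st$end[row]
    if (e == "full") {
      if (st$position[row] <= leader_depth) "leader" else "trailer"
    } else e
  }

  res <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ra <- cand[k, 1]; rb <- cand[k, 2]
    ca <- st$exact_class[ra]; cb <- st$exact_class[rb]
    if (ca == cb) {
      offset <- 0L; overlap <- st$length[ra]; identity <- 1; snps <- 0L
    } else {
      e <- edges[match(paste(min(ca, cb), max(ca, cb), sep = ":"), edge_key), ]
      # edge orientation: stored as class_a vs class_b
      flip <- !(e$class_a == ca)
      offset <- if (flip) -e$offset else e$offset
      overlap <- e$overlap; identity <- e$identity; snps <- e$snps
    }

    # length of the consecutive-exact run through this pair: adjacent
    # positions in both fragments occupied by identical spacers
    exact_run_length <- function() {
      same_a <- st$row[key == key[ra]]
      same_b <- st$row[key == key[rb]]
      run <- 1L
      for (d in c(-1L, 1L)) {
        step <- d
        repeat {
          na_ <- same_a[st$position[same_a] == st$position[ra] + step]
          nb_ <- same_b[st$position[same_b] == st$position[rb] + step]
          if (length(na_) == 1 && length(nb_) == 1 &&
              st$exact_class[na_] == st$exact_class[nb_]) {
            run <- run + 1L
            step <- step + d
          } else break
        }
      }
      run
    }

    status <- "acquisition"; reason <- ""
    if (st$locus[ra] == st$locus[rb] &&
        strains_linked(st$strain[ra], st$strain[rb], st$locus[ra])) {
      aln <- get_alignment(arr_idx[ra], arr_idx[rb])
      if (inherits(aln, "array_alignment")) {
        pa <- aln$columns$a_pos
        pb <- aln$columns$b_pos
        in_match_col <- any(!is.na(pa) & !is.na(pb) &
                              pa == st$position[ra] & pb == st$position[rb])
        if (in_match_col) {
          run <- if (ca == cb) exact_run_length() else 0L
          len_a <- length(arrays[[arr_idx[ra]]])
          len_b <- length(arrays[[arr_idx[rb]]])
          if (run >= 2 && aln$n_match <= run && run < len_a && run < len_b) {
            # an isolated exact run embedded in otherwise conflicting
            # context on both sides: too short to call ancestry, too
            # consistent to call independent acquisition
            status <- "excluded"; reason <- "consecutive-exact"
          } else {
            status <- "ancestral"
            reason <- "match column in ancestral alignment"
          }
        }
      }
    }
    if (status == "acquisition" && ca == cb && exact_run_length() >= 2) {
      status <- "excluded"; reason <- "consecutive-exact"
    }

    ea <- end_class_of(ra); eb <- end_class_of(rb)
    end_class <- if (ea == "leader" && eb == "leader") "leader-leader"
    else if (ea == "trailer" && eb == "trailer") "trailer-trailer"
    else "mixed"

    res[[k]] <- data.frame(
      strain_a = st$strain[ra], locus_a = st$locus[ra], end_a = st$end[ra],
      position_a = st$position[ra],
      strain_b = st$strain[rb], locus_b = st$locus[rb], end_b = st$end[rb],
      position_b = st$position[rb],
      offset = offset, overlap = overlap, identity = identity, snps = snps,
      end_class = end_class, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("acquisition_pairs", "data.frame"),
            min_run = min_run, leader_depth = leader_depth)
}

empty_acquisitions <- function(min_run, leader_depth) {
  structure(
    data.frame(strain_a = character(0), locus_a = character(0),
               end_a = character(0), position_a = integer(0),
               strain_b = character(0), locus_b = character(0),
               end_b = character(0), position_b = integer(0),
               offset = integer(0), overlap = integer(0),
               identity = numeric(0), snps = integer(0),
               end_class = character(0), status = character(0),
               reason = character(0), stringsAsFactors = FALSE),
    class = c("acquisition_pairs", "data.frame"),
    min_run = min_run, leader_depth = leader_depth)
}

#' Summarise acquisition pairs by sequenced end
#'
#' Counts and fractions of independent-acquisition pairs that are
#' leader-leader (both recent acquisitions), trailer-trailer, or mixed.
#'
#' @param pairs a [classify_acquisitions()] result (rows with status other
#'   than `"acquisition"` are ignored).
#' @return data.frame: end_class, n, fraction (fractions sum to 1, or all
#'   counts zero when no pairs).
#' @export
acquisition_end_summary <- function(pairs) {
  keep <- pairs[pairs$status == "acquisition", , drop = FALSE]
  classes <- c("leader-leader", "trailer-trailer", "mixed")
  n <- vapply(classes, function(cl) sum(keep$end_class == cl), integer(1))
  data.frame(end_class = classes, n = n,
             fraction = if (sum(n) > 0) n / sum(n) else rep(0, 3),
             stringsAsFactors = FALSE, row.names = NULL)
}
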