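#' Construct a spacer array
#'
#' An ordered run of spacers from one strain at one CRISPR locus, oriented
#' leader to trailer (position 1 = leader-most spacer of the sequenced
#' fragment). Normally produced by [extract_spacers()] or
#' [load_locus_fasta()] rather than built by hand.
#'
#' @param strain strain identifier.
#' @param locus locus identifier, one of `"C"`, `"A1"`, `"A2"` (free-form
#'   identifiers accepted).
#' @param end which end of the locus the fragment covers: `"leader"`,
#'   `"trailer"` or `"full"`.
#' @param spacers character vector of spacer sequences, leader-most first.
#' @param flank_left,flank_right sequence outside the outermost repeats
#'   (recorded, never emitted as spacers).
#' @param source_record FASTA record id the array came from.
#' @return object of class `spacer_array` with a `spacers` data.frame
#'   (`position`, `sequence`, `length`).
#' @export
spacer_array <- function(strain, locus, end = c("leader", "trailer", "full"),
                         spacers, flank_left = "", flank_right = "",
                         source_record = NA_character_) {
  end <- match.arg(end)
  spacers <- toupper(as.character(spacers))
  if (length(spacers) < 1) stop("a spacer_array needs at least one spacer")
  if (any(nchar(spacers) == 0)) stop("zero-length spacer in spacer_array")
  structure(
    list(
      strain = as.character(strain), locus = as.character(locus), end = end,
      spacers = data.frame(position = seq_along(spacers), sequence = spacers,
                           length = nchar(spacers), stringsAsFactors = FALSE),
      flank_left = flank_left, flank_right = flank_right,
      source_record = source_record
    ),
    class = "spacer_array"
  )
}

#' @export
print.spacer_array <- function(x, ...) {
  cat(sprintf("<spacer_array> strain %s, locus %s, %s end: %d spacers (%d-%d nt)\n",
              x$strain, x$locus, x$end, nrow(x$spacers),
              min(x$spacers$length), max(x$spacers$length)))
  invisible(x)
}

#' @export
length.spacer_array <- function(x) nrow(x$spacers)

#' @export
as.data.frame.spacer_array <- function(x, ...) {
  cbind(data.frame(strain = x$strain, locus = x$locus, end = x$end,
                   stringsAsFactors = FALSE),
        x$spacers)
}

#' Flatten a list of spacer arrays into one spacer table
#'
#' @param arrays list of `spacer_array` objects.
#' @return data.frame with columns strain, locus, end, position, sequence,
#'   length — one row per spacer.
#' @export
spacer_table <- function(arrays) {
  if (length(arrays) == 0) {
    return(data.frame(strain = character(0), locus = character(0),
                      end = character(0), position = integer(0),
                      sequence = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(arrays, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Extract spacers from a repeat-delimited locus sequence
#'
#' Finds repeat hits with [find_repeats()] and emits the substrings strictly
#' between consecutive hits as spacers, leader to trailer. If the repeat is
#' found on the minus strand the sequence is reverse-complemented first so
#' the emitted array is always leader-to-trailer. Sequence outside the
#' outermost repeats is kept as flanking context. Zero-length inter-repeat
#' gaps (sequencing artifacts) are skipped with a warning and positions are
#' renumbered consecutively.
#'
#' @inheritParams spacer_array
#' @param sequence the locus fragment DNA.
#' @param repeat_def a [repeat_definition()].
#' @param max_mismatches passed to [find_repeats()].
#' @return a [spacer_array()].
#' @export
extract_spacers <- function(sequence, strain, locus,
                            end = c("leader", "trailer", "full"),
                            repeat_def, max_mismatches = 2,
                            source_record = NA_character_) {
  end <- match.arg(end)
  sequence <- check_dna(sequence, "locus sequence")
  if (nchar(sequence) == 0) stop("empty input sequence", call. = FALSE)
  rec <- if (is.na(source_record)) paste(strain, locus, end, sep = "|") else source_record

  hits <- find_repeats(sequence, repeat_def, max_mismatches)
  # orient to the majority strand; ties go to "+"
  if (nrow(hits) >= 1 && sum(hits$strand == "-") > sum(hits$strand == "+")) {
    sequence <- revcomp(sequence)
    hits <- find_repeats(sequence, repeat_def, max_mismatches)
  }
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) < 2) {
    stop("unparseable locus: fewer than 2 repeat hits in record '", rec, "'",
         call. = FALSE)
  }

  starts <- hits$end[-nrow(hits)]        # 0-based start of each spacer
  ends <- hits$start[-1]                 # exclusive end
  spacers <- substring(sequence, starts + 1L, ends)
  if (any(nchar(spacers) == 0)) {
    warning("skipping ", sum(nchar(spacers) == 0),
            " zero-length spacer(s) in record '", rec, "'")
    spacers <- spacers[nchar(spacers) > 0]
  }
  if (length(spacers) == 0) {
    stop("unparseable locus: no spacers between repeats in record '", rec, "'",
         call. = FALSE)
  }
  spacer_array(strain = strain, locus = locus, end = end, spacers = spacers,
               flank_left = substring(sequence, 1, hits$start[1]),
               flank_right = substring(sequence, hits$end[nrow(hits)] + 1L,
                                       nchar(sequence)),
               source_record = rec)
}

#' Load CRISPR locus fragments from a FASTA file
#'
#' Headers must follow the metadata pattern `strain|locus|end` (field order
#' configurable), with an optional fourth field `X` flagging a strain known
#' to lack the locus (such records are excluded and reported with status
#' `"X"`, mirroring the locus-absent convention). Records whose repeats
#' cannot be parsed are reported with status `"NA"` — a locus that could not
#' be sequenced — and skipped.
#'
#' @param path FASTA file of locus fragments.
#' @param repeats named list of [repeat_definition()]s keyed by locus family
#'   (default [builtin_repeats()]).
#' @param max_mismatches passed to [find_repeats()].
#' @param fields header field order (default `c("strain","locus","end")`).
#' @param locus_family function mapping a locus id to its repeat family
#'   (default: first character, so C -> C, A1/A2 -> A).
#' @return list of [spacer_array()]s with attribute `status`: a data.frame
#'   (record, strain, locus, end, status, message) covering every record.
#' @export
load_locus_fasta <- function(path, repeats = builtin_repeats(),
                             max_mismatches = 2,
                             fields = c("strain", "locus", "end"),
                             locus_family = function(locus) substr(locus, 1, 1)) {
  seqs <- Biostrings::readDNAStringSet(path)
  arrays <- list()
  status <- data.frame(record = character(0), strain = character(0),
                       locus = character(0), end = character(0),
                       status = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  if (length(seqs) == 0) {
    warning("empty FASTA: ", path)
    return(structure(arrays, status = status))
  }
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(parts) < length(fields)) {
      stop("malformed header (expected '",
           paste(fields, collapse = "|"), "'): record '", header, "'",
           call. = FALSE)
    }
    meta <- stats::setNames(as.list(parts[seq_along(fields)]), fields)
    extra <- if (length(parts) > length(fields)) parts[-seq_along(fields)] else character(0)
    if ("X" %in% extra) {
      status <- rbind(status, data.frame(
        record = header, strain = meta$strain, locus = meta$locus,
        end = meta$end, status = "X", message = "locus not present",
        stringsAsFactors = FALSE))
      next
    }
    fam <- locus_family(meta$locus)
    if (!fam %in% names(repeats)) {
      stop("no repeat definition for locus family '", fam, "' (record '",
           header, "')", call. = FALSE)
    }
    arr <- tryCatch(
      extract_spacers(as.character(seqs[[i]]), strain = meta$strain,
                      locus = meta$locus, end = meta$end,
                      repeat_def = repeats[[fam]],
                      max_mismatches = max_mismatches,
                      source_record = header),
      error = function(e) e
    )
    if (inherits(arr, "error")) {
      status <- rbind(status, data.frame(
        record = header, strain = meta$strain, locus = meta$locus,
        end = meta$end, status = "NA", message = conditionMessage(arr),
        stringsAsFactors = FALSE))
    } else {
      arrays[[length(arrays) + 1L]] <- arr
      status <- rbind(status, data.frame(
        record = header, strain = meta$strain, locus = meta$locus,
        end = meta$end, status = "ok", message = "",
        stringsAsFactors = FALSE))
    }
  }
  structure(arrays, status = status)
}
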