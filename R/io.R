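# Tab-separated exports of the main result shapes.

#' Write a spacer table to TSV
#'
#' One row per spacer: strain, locus, end, position, sequence, length.
#'
#' @param x list of [spacer_array()]s or a [spacer_table()] data.frame.
#' @param path output file.
#' @export
write_spacer_tsv <- function(x, path) {
  if (!is.data.frame(x)) x <- spacer_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coded array matrix to TSV
#'
#' One row per strain, one column per aligned spacer position; `.` marks a
#' gap (spacer absent) and `?` missing data, mirroring the figure
#' convention of white boxes for missing data.
#'
#' @param m a [coded_matrix()].
#' @param path output file.
#' @param codes optional recoding: named vector mapping spacer sequences to
#'   short codes; defaults to `c1, c2, ...` in column order of first use.
#' @export
write_coded_tsv <- function(m, path, codes = NULL) {
  if (is.null(codes)) {
    seqs <- unique(stats::na.omit(as.vector(t(m))))
    seqs <- setdiff(seqs, "-")
    codes <- stats::setNames(paste0("c", seq_along(seqs)), seqs)
  }
  out <- m
  out[] <- ifelse(is.na(m), "?", ifelse(m == "-", ".",
                                        unname(codes[m])))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write classified spacer pairs to TSV
#'
#' @param pairs a [classify_acquisitions()] result.
#' @param path output file.
#' @param only_acquisitions drop ancestral/excluded rows (default FALSE).
#' @export
write_pairs_tsv <- function(pairs, path, only_acquisitions = FALSE) {
  df <- as.data.frame(pairs)
  if (only_acquisitions) df <- df[df$status == "acquisition", , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
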