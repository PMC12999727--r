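# Gap-threshold alignment trimming: keep exactly the columns whose non-gap
# fraction reaches the threshold (the usual -gt style column filter applied
# before tree building).

#' Trim alignment columns by gap fraction
#'
#' @param alignment named character vector of equal-length aligned rows
#'   (gaps as `-`).
#' @param gap_threshold minimum non-gap fraction a column needs to be kept;
#'   default 0.8.
#' @return a `trimmed_alignment`: list with `sequence_ids`, `kept_columns`
#'   (1-based indices into the untrimmed alignment) and `rows` (the trimmed
#'   aligned rows).
#' @export
trim_alignment <- function(alignment, gap_threshold = 0.8) {
  stopifnot(length(alignment) >= 1L, !is.null(names(alignment)),
            gap_threshold > 0, gap_threshold <= 1)
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  nongap <- colMeans(mat != "-")
  keep <- which(nongap >= gap_threshold)
  if (length(keep) == 0L)
    stop("no columns pass gap_threshold = ", gap_threshold,
         "; lower the threshold")
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(list(sequence_ids = names(alignment),
                 kept_columns = keep,
                 rows = stats::setNames(rows, names(alignment))),
            class = "trimmed_alignment")
}

#' @export
print.trimmed_alignment <- function(x, ...) {
  cat("trimmed_alignment:", length(x$sequence_ids), "rows,",
      length(x$kept_columns), "columns kept\n")
  invisible(x)
}

#' Write aligned rows to FASTA (e.g. for external tree software)
#'
#' @param rows named character vector of aligned rows, or a
#'   `trimmed_alignment`.
#' @param path output path.
#' @export
write_alignment_fasta <- function(rows, path) {
  if (inherits(rows, "trimmed_alignment")) rows <- rows$rows
  writeLines(as.vector(rbind(paste0(">", names(rows)), unname(rows))), path)
  invisible(path)
}
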