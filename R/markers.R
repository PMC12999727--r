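# Marker search: assigns catalog markers to proteins by global-alignment
# similarity against the seed sequences. This is the package's stand-in for
# profile-HMM genome annotation: self-contained and exactly reproducible.

.empty_hits <- function() {
  data.frame(genome_id = character(), protein_id = character(),
             marker_id = character(), best_seed_label = character(),
             identity = numeric(), coverage = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Search a genome's proteins for catalog markers
#'
#' Every protein is globally aligned against every seed; a marker is assigned
#' when the best seed meets the marker's identity and coverage thresholds.
#' Per protein, at most one marker per category is reported (the
#' highest-scoring; ties broken by seed score, then lexicographically
#' smallest seed label, then marker id), while distinct proteins may hit the
#' same marker (real multi-copy genes). Proteins containing characters
#' outside the 20-letter alphabet plus `X` are skipped with a warning.
#'
#' @param genome a `genome_record`.
#' @param catalog a `marker_catalog`.
#' @return data.frame of hits: `genome_id`, `protein_id`, `marker_id`,
#'   `best_seed_label`, `identity`, `coverage`, `score`, sorted by
#'   (`protein_id`, `marker_id`) so output is invariant to protein order.
#' @export
search_markers <- function(genome, catalog) {
  stopifnot(inherits(genome, "genome_record"),
            inherits(catalog, "marker_catalog"))
  idx <- catalog$seed_index
  seeds <- stats::setNames(idx$sequence,
                           paste(idx$marker_id, idx$label, sep = "\r"))
  out <- list()
  for (i in seq_len(nrow(genome$proteins))) {
    pid <- genome$proteins$protein_id[i]
    seq <- genome$proteins$sequence[i]
    if (!is_valid_protein(seq)) {
      warning("skipping protein ", pid, " of ", genome$genome_id,
              ": illegal characters in sequence", call. = FALSE)
      next
    }
    res <- align_to_seeds(seq, seeds)
    res$marker_id <- idx$marker_id
    res$seed_label <- idx$label
    res$category <- idx$category
    pass <- res$identity >= idx$min_identity & res$coverage >= idx$min_coverage
    res <- res[pass, , drop = FALSE]
    if (!nrow(res)) next
    # best seed per marker, then best marker per category
    res <- res[order(-res$score, res$seed_label, res$marker_id), ]
    res <- res[!duplicated(res$marker_id), , drop = FALSE]
    res <- res[order(-res$score, res$marker_id), ]
    res <- res[!duplicated(res$category), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      genome_id = genome$genome_id, protein_id = pid,
      marker_id = res$marker_id, best_seed_label = res$seed_label,
      identity = res$identity, coverage = res$coverage, score = res$score,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$protein_id, hits$marker_id), ]
  rownames(hits) <- NULL
  hits
}

#' Search several genomes for catalog markers
#'
#' @param genomes list of `genome_record`.
#' @inheritParams search_markers
#' @return combined hits data.frame (see [search_markers()]).
#' @export
search_markers_all <- function(genomes, catalog) {
  res <- lapply(genomes, search_markers, catalog = catalog)
  out <- do.call(rbind, c(res, list(.empty_hits())))
  rownames(out) <- NULL
  out
}

#' Read precomputed marker annotations from TSV
#'
#' Lets users substitute an external annotation step for [search_markers()].
#' Expected columns: `genome_id`, `protein_id`, `marker_id`; optional
#' `identity` and `coverage` (absent values are recorded as the sentinel 1.0
#' and the hit flagged as imported).
#'
#' @param path TSV file with a header line.
#' @param catalog a `marker_catalog` used to vet `marker_id`s.
#' @param on_unknown `"warn"` (drop rows with unknown markers, warning) or
#'   `"error"`.
#' @return hits data.frame as from [search_markers()], plus a `provenance`
#'   column (`"imported"`).
#' @export
read_annotation_table <- function(path, catalog,
                                  on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(inherits(catalog, "marker_catalog"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("genome_id", "protein_id", "marker_id")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  unknown <- !tab$marker_id %in% names(catalog$markers)
  if (any(unknown)) {
    msg <- paste0("unknown marker_id(s) in annotation table: ",
                  paste(unique(tab$marker_id[unknown]), collapse = ", "))
    if (on_unknown == "error") stop(msg)
    warning(msg, " - ", sum(unknown), " row(s) dropped", call. = FALSE)
    tab <- tab[!unknown, , drop = FALSE]
  }
  n <- nrow(tab)
  data.frame(genome_id = as.character(tab$genome_id),
             protein_id = as.character(tab$protein_id),
             marker_id = as.character(tab$marker_id),
             best_seed_label = rep(NA_character_, n),
             identity = if ("identity" %in% names(tab))
               ifelse(is.na(tab$identity), 1.0, tab$identity) else rep(1.0, n),
             coverage = if ("coverage" %in% names(tab))
               ifelse(is.na(tab$coverage), 1.0, tab$coverage) else rep(1.0, n),
             score = rep(NA_real_, n),
             provenance = rep("imported", n),
             stringsAsFactors = FALSE)
}

#' Write marker hits to TSV
#'
#' @param hits hits data.frame.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
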