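# GenomeRecord: a genome's identity, taxonomy and ordered protein list.
# Locus indices are 0-based ordinal positions in annotation (file) order; no
# nucleotide coordinates are used anywhere.

#' Construct a genome record
#'
#' @param genome_id unique genome identifier.
#' @param proteins data.frame with columns `protein_id`, `sequence`, and
#'   optionally `locus_index` (0-based, strictly increasing; defaults to file
#'   order).
#' @param strain_label display label (defaults to `genome_id`).
#' @param taxonomy named list/vector with any of `domain`, `phylum`, `class`,
#'   `order`, `genus`, `species`.
#' @return a `genome_record`.
#' @export
genome_record <- function(genome_id, proteins, strain_label = genome_id,
                          taxonomy = list()) {
  stopifnot(is.character(genome_id), nzchar(genome_id),
            is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  if (is.null(proteins$locus_index))
    proteins$locus_index <- seq_len(nrow(proteins)) - 1L
  if (nrow(proteins)) {
    stopifnot(!anyDuplicated(proteins$protein_id),
              all(diff(proteins$locus_index) > 0),
              all(proteins$locus_index >= 0))
  }
  proteins$sequence <- toupper(proteins$sequence)
  tax <- list(domain = NA_character_, phylum = NA_character_,
              class = NA_character_, order = NA_character_,
              genus = NA_character_, species = NA_character_)
  tax[names(taxonomy)] <- as.list(taxonomy)
  structure(list(genome_id = genome_id, strain_label = strain_label,
                 taxonomy = tax,
                 proteins = proteins[, c("protein_id", "sequence",
                                         "locus_index")]),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record", x$genome_id, "-", nrow(x$proteins), "proteins\n")
  invisible(x)
}

#' Read protein FASTA into genome records
#'
#' A single-genome file yields one record named after `genome_id` (default:
#' the file name without extension). A multi-genome file uses `sep` to split
#' each header into `genome_id<sep>protein_id`.
#'
#' @param path protein FASTA file.
#' @param genome_id genome id for single-genome files; `NULL` to split
#'   headers on `sep`.
#' @param sep separator between genome id and protein id in headers.
#' @param taxonomy passed to [genome_record()] (single-genome mode only).
#' @return list of `genome_record` objects, named by genome id.
#' @export
read_genome_fasta <- function(path, genome_id = NULL, sep = "|",
                              taxonomy = list()) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  if (!is.null(genome_id) || !any(grepl(sep, ids, fixed = TRUE))) {
    gid <- genome_id %||% sub("\\.(fa|faa|fasta)$", "", basename(path))
    prot <- data.frame(protein_id = ids, sequence = unname(seqs),
                       stringsAsFactors = FALSE)
    recs <- list(genome_record(gid, prot, taxonomy = taxonomy))
    names(recs) <- gid
    return(recs)
  }
  gids <- vapply(strsplit(ids, sep, fixed = TRUE), `[[`, "", 1L)
  pids <- sub(paste0("^[^", sep, "]*", if (sep == "|") "\\|" else sep), "",
              ids)
  recs <- lapply(split(seq_along(ids), gids), function(i)
    genome_record(gids[i[1]],
                  data.frame(protein_id = pids[i], sequence = unname(seqs[i]),
                             stringsAsFactors = FALSE)))
  recs[order(names(recs))]
}

#' Write genome records to protein FASTA
#'
#' @param genomes list of `genome_record`.
#' @param path output file; headers are `genome_id|protein_id`.
#' @param sep header separator.
#' @export
write_genome_fasta <- function(genomes, path, sep = "|") {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  lines <- unlist(lapply(genomes, function(g) {
    as.vector(rbind(paste0(">", g$genome_id, sep, g$proteins$protein_id),
                    g$proteins$sequence))
  }))
  writeLines(lines, path)
  invisible(path)
}
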