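# Representative-strain selection: one strain per genus with demonstrated
# autotrophic growth, every strain of genera lacking such evidence.

#' Select representative genomes per genus
#'
#' Genera containing at least one evidence-positive strain contribute exactly
#' one genome (the lexicographically smallest `strain_label`); genera with no
#' evidence-positive strain contribute all their genomes. Rows with a missing
#' genus are excluded with a warning.
#'
#' @param metadata data.frame with columns `genome_id`, `strain_label`,
#'   `genus`, and `evidence` (`"demonstrated"`, `"reported_negative"` or
#'   `"untested"`; logical `TRUE`/`FALSE` is also accepted).
#' @return character vector of selected genome ids (deterministic order:
#'   genus, then strain label).
#' @export
select_representatives <- function(metadata) {
  if (nrow(metadata) == 0L) return(character(0))
  stopifnot(all(c("genome_id", "strain_label", "genus", "evidence") %in%
                  names(metadata)))
  ev <- metadata$evidence
  pos <- if (is.logical(ev)) ev %in% TRUE else ev == "demonstrated"
  miss <- is.na(metadata$genus) | !nzchar(metadata$genus)
  if (any(miss)) {
    warning("excluding ", sum(miss), " genome(s) with missing genus: ",
            paste(metadata$genome_id[miss], collapse = ", "), call. = FALSE)
    metadata <- metadata[!miss, , drop = FALSE]
    pos <- pos[!miss]
  }
  out <- character(0)
  for (g in sort(unique(metadata$genus))) {
    rows <- metadata[metadata$genus == g, , drop = FALSE]
    if (any(pos[metadata$genus == g])) {
      cand <- rows[pos[metadata$genus == g], , drop = FALSE]
      out <- c(out, cand$genome_id[order(cand$strain_label)][1])
    } else {
      out <- c(out, rows$genome_id[order(rows$strain_label)])
    }
  }
  out
}
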