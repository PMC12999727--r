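# RbcL form classification against a labelled reference panel, and
# small-subunit (rbcS) co-occurrence / colocalization checks.

FORM_LEVELS <- c("IA", "IB", "IC", "ID", "IE", "I_THERMUS", "I_PRIME",
                 "I_DOUBLE_PRIME", "I_ALPHA", "I_ANAERO", "II", "III", "IV",
                 "UNASSIGNED")

#' Read an RbcL form reference panel from FASTA
#'
#' Headers must carry `form=<label>`; free text after the form tag is kept as
#' the entry's provenance note. Every form except `UNASSIGNED` needs at
#' least one entry overall, and ref ids must be unique.
#'
#' @param path FASTA file.
#' @return a `reference_panel`: data.frame with `ref_id`, `form`,
#'   `sequence`, `provenance`.
#' @export
read_reference_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty panel file: ", path)
  hdr <- names(aa)
  ref_id <- sub("\\s.*$", "", hdr)
  form <- sub(".*form=(\\S+).*", "\\1", hdr)
  prov <- ifelse(grepl("provenance=", hdr),
                 sub(".*provenance=(\\S+).*", "\\1", hdr), NA_character_)
  if (anyDuplicated(ref_id)) stop("duplicate ref_id in panel")
  bad <- setdiff(unique(form), setdiff(FORM_LEVELS, "UNASSIGNED"))
  if (length(bad)) stop("unknown form label(s) in panel: ",
                        paste(bad, collapse = ", "))
  structure(data.frame(ref_id = ref_id, form = form,
                       sequence = as.character(aa), provenance = prov,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("reference_panel", "data.frame"))
}

#' Bundled default RbcL form panel (synthetic entries)
#'
#' @return a `reference_panel`.
#' @export
default_panel <- function() {
  read_reference_panel(system.file("extdata", "rbcl_panel_synthetic.fasta",
                                   package = "cbbscan", mustWork = TRUE))
}

#' Assign a RubisCO form to an RbcL sequence
#'
#' Nearest-reference classification: the query is aligned to every panel
#' entry; the best-identity reference's form is called when identity >=
#' `identity_floor` and the margin over the best reference of any *other*
#' form is >= `margin_floor`. Otherwise (including exact inter-form ties and
#' queries shorter than 100 residues) the call is `UNASSIGNED` - an
#' unassigned copy is preferred over a wrong form.
#'
#' @param seq amino-acid sequence.
#' @param panel a `reference_panel`.
#' @param identity_floor minimum identity to the nearest reference
#'   (default 0.45).
#' @param margin_floor minimum identity gap to the best other-form reference
#'   (default 0.02).
#' @return one-row data.frame: `form`, `nearest_ref_id`,
#'   `identity_to_nearest`, `margin`.
#' @export
assign_form <- function(seq, panel, identity_floor = 0.45,
                        margin_floor = 0.02) {
  stopifnot(inherits(panel, "reference_panel"), nrow(panel) >= 1L)
  if (nchar(seq) < 100L) {
    warning("query shorter than 100 residues: returning UNASSIGNED",
            call. = FALSE)
    return(data.frame(form = "UNASSIGNED", nearest_ref_id = NA_character_,
                      identity_to_nearest = NA_real_, margin = NA_real_,
                      stringsAsFactors = FALSE))
  }
  res <- align_to_seeds(seq, stats::setNames(panel$sequence, panel$ref_id))
  res$form <- panel$form
  res <- res[order(-res$identity, res$label), ]
  best <- res[1L, ]
  other <- res[res$form != best$form, ]
  best_other <- if (nrow(other)) max(other$identity) else 0
  margin <- best$identity - best_other
  tie <- nrow(other) > 0 && best_other == best$identity
  form <- if (!tie && best$identity >= identity_floor &&
              margin >= margin_floor) best$form else "UNASSIGNED"
  data.frame(form = form, nearest_ref_id = best$label,
             identity_to_nearest = best$identity, margin = margin,
             stringsAsFactors = FALSE)
}

#' Classify every RbcL copy of a genome
#'
#' Runs [assign_form()] on each protein with a K01601 hit and attaches rbcS
#' presence/colocalization from [detect_rbcs()].
#'
#' @param genome a `genome_record`.
#' @param hits marker hits for this genome (from [search_markers()]).
#' @param panel a `reference_panel`.
#' @param window colocalization window in loci (default 5).
#' @inheritParams assign_form
#' @return data.frame with one row per RbcL copy: `genome_id`, `protein_id`,
#'   `form`, `nearest_ref_id`, `identity_to_nearest`, `margin`,
#'   `rbcs_present`, `rbcs_colocalized`.
#' @export
assign_forms_genome <- function(genome, hits, panel, window = 5L,
                                identity_floor = 0.45, margin_floor = 0.02) {
  rbcl <- hits[hits$marker_id == "K01601", , drop = FALSE]
  rbcs <- hits[hits$marker_id == "rbcS", , drop = FALSE]
  if (!nrow(rbcl))
    return(data.frame(genome_id = character(), protein_id = character(),
                      form = character(), nearest_ref_id = character(),
                      identity_to_nearest = numeric(), margin = numeric(),
                      rbcs_present = logical(), rbcs_colocalized = logical(),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(rbcl)), function(i) {
    pid <- rbcl$protein_id[i]
    seq <- genome$proteins$sequence[genome$proteins$protein_id == pid]
    a <- assign_form(seq, panel, identity_floor, margin_floor)
    rs <- detect_rbcs(genome, rbcl[i, ], rbcs, window)
    cbind(data.frame(genome_id = genome$genome_id, protein_id = pid,
                     stringsAsFactors = FALSE),
          a,
          data.frame(rbcs_present = rs[["present"]],
                     rbcs_colocalized = rs[["colocalized"]]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect rbcS presence and operon-like colocalization with an rbcL copy
#'
#' Colocalization is strand-agnostic and uses ordinal locus indices: an rbcS
#' hit within `window` loci of the rbcL copy counts as colocalized.
#'
#' @param genome a `genome_record`.
#' @param rbcl_hit one-row hits data.frame for the rbcL copy.
#' @param rbcs_hits hits data.frame of rbcS hits in the genome.
#' @param window maximum |locus index difference| (default 5).
#' @return named logical vector `c(present=, colocalized=)`.
#' @export
detect_rbcs <- function(genome, rbcl_hit, rbcs_hits, window = 5L) {
  locus <- function(pids)
    genome$proteins$locus_index[match(pids, genome$proteins$protein_id)]
  present <- nrow(rbcs_hits) > 0L
  coloc <- FALSE
  if (present) {
    lr <- locus(rbcl_hit$protein_id[1])
    ls <- locus(rbcs_hits$protein_id)
    coloc <- any(abs(ls - lr) <= window, na.rm = TRUE)
  }
  c(present = present, colocalized = coloc)
}
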