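# Reporting: joins trait profiles with strain metadata and produces the
# taxon-level count matrix (strains x predicted metabolism) and the
# isolation-environment breakdowns per RubisCO form.

ENV_LEVELS <- c("marine", "terrestrial", "rhizosphere_plant", "engineered",
                "organism_hosted", "food", "unknown")
EVIDENCE_LEVELS <- c("demonstrated", "reported_negative", "untested")

SUMMARY_FORM_COLS <- c("IA", "IB", "IC", "IE", "I_THERMUS", "II")
SUMMARY_COUNT_COLS <- c("total", SUMMARY_FORM_COLS, "h2_oxidation",
                        "sulfur_oxidation", "microaerophilic", "aerobic",
                        "sulfur_reduction", "nitrate_reduction",
                        "photosynthesis")

#' Join trait profiles with strain metadata
#'
#' Adds taxonomy, autotrophy evidence and isolation environment to each
#' profile row. Profiles without metadata get `evidence = "untested"` and
#' `environment = "unknown"` with a warning. A genus-level evidence flag
#' (`genus_evidence`) is set when any member of the genus is demonstrated.
#'
#' @param profiles data.frame from [profiles_to_df()].
#' @param metadata data.frame with columns `genome_id`, `phylum`, `order`,
#'   `genus`, `evidence`, `environment` (and optionally `plant_associated`,
#'   a logical marking organism-hosted strains from plant material).
#' @return annotated records data.frame.
#' @export
join_evidence <- function(profiles, metadata) {
  stopifnot(is.data.frame(profiles), "genome_id" %in% names(profiles))
  if (anyDuplicated(metadata$genome_id))
    stop("duplicate genome_id in metadata: ",
         paste(unique(metadata$genome_id[duplicated(metadata$genome_id)]),
               collapse = ", "))
  bad_ev <- setdiff(unique(metadata$evidence), EVIDENCE_LEVELS)
  if (length(bad_ev)) stop("unknown evidence value(s): ",
                           paste(bad_ev, collapse = ", "))
  bad_env <- setdiff(unique(metadata$environment), ENV_LEVELS)
  if (length(bad_env)) stop("unknown environment value(s): ",
                            paste(bad_env, collapse = ", "))
  i <- match(profiles$genome_id, metadata$genome_id)
  if (anyNA(i))
    warning(sum(is.na(i)), " profile(s) lack metadata; recorded as ",
            "untested/unknown", call. = FALSE)
  rec <- profiles
  rec$phylum <- ifelse(is.na(i), NA_character_, metadata$phylum[i])
  rec$order <- ifelse(is.na(i), NA_character_, metadata$order[i])
  rec$genus <- ifelse(is.na(i), NA_character_, metadata$genus[i])
  rec$evidence <- ifelse(is.na(i), "untested", metadata$evidence[i])
  rec$environment <- ifelse(is.na(i), "unknown", metadata$environment[i])
  rec$plant_associated <- if ("plant_associated" %in% names(metadata))
    ifelse(is.na(i), FALSE, metadata$plant_associated[i] %in% TRUE)
  else FALSE
  demo_genera <- unique(rec$genus[rec$evidence == "demonstrated"])
  rec$genus_evidence <- !is.na(rec$genus) & rec$genus %in% demo_genera
  rec
}

.has_form <- function(records, form) {
  vapply(strsplit(records$forms_present, ";", fixed = TRUE),
         function(f) form %in% f, logical(1))
}

.count_row <- function(records) {
  counts <- c(total = nrow(records))
  for (f in SUMMARY_FORM_COLS) counts[f] <- sum(.has_form(records, f))
  counts["h2_oxidation"] <- sum(records$h2_uptake)
  counts["sulfur_oxidation"] <- sum(records$sulfur_oxidation != "none")
  counts["microaerophilic"] <- sum(records$oxygen_microaerophilic_highaff)
  counts["aerobic"] <- sum(records$oxygen_aerobic_lowaff)
  counts["sulfur_reduction"] <- sum(records$sulfur_reduction)
  counts["nitrate_reduction"] <- sum(records$nitrate_reduction)
  counts["photosynthesis"] <- sum(records$photosystem_ii)
  counts
}

#' Summarize annotated records into a taxon-level count matrix
#'
#' One row per (phylum, order) plus a total row per phylum and a grand-total
#' row; columns are strain counts, per-form counts, electron-donor counts,
#' electron-acceptor counts and the photosystem count. Totals are computed
#' by summation, and column-wise conservation (grand total = sum of phylum
#' totals = sum of order rows) is asserted on every produced table.
#'
#' @param records annotated records from [join_evidence()].
#' @param scope `"untested_genera"` (default; keep only strains of genera
#'   with no demonstrated member, the scope the headline count matrix uses)
#'   or `"all"`.
#' @return a `summary_table` data.frame with columns `level`
#'   (`order`/`phylum`/`grand_total`), `phylum`, `taxon` and the count
#'   columns.
#' @export
summarize_strains <- function(records, scope = c("untested_genera", "all")) {
  scope <- match.arg(scope)
  if (scope == "untested_genera")
    records <- records[!records$genus_evidence, , drop = FALSE]
  rows <- list()
  phyla <- sort(unique(records$phylum))
  for (ph in phyla) {
    ph_rec <- records[records$phylum %in% ph, , drop = FALSE]
    ords <- sort(unique(ph_rec$order))
    ord_rows <- lapply(ords, function(o) {
      cnt <- .count_row(ph_rec[ph_rec$order %in% o, , drop = FALSE])
      cbind(data.frame(level = "order", phylum = ph, taxon = o,
                       stringsAsFactors = FALSE), as.data.frame(t(cnt)))
    })
    ph_tot <- Reduce(`+`, lapply(ord_rows, function(r)
      as.numeric(r[SUMMARY_COUNT_COLS])))
    rows <- c(rows,
              list(cbind(data.frame(level = "phylum", phylum = NA_character_,
                                    taxon = ph, stringsAsFactors = FALSE),
                         as.data.frame(t(stats::setNames(ph_tot,
                                                         SUMMARY_COUNT_COLS))))),
              ord_rows)
  }
  grand <- if (length(rows)) {
    ph_rows <- Filter(function(r) r$level == "phylum", rows)
    Reduce(`+`, lapply(ph_rows, function(r) as.numeric(r[SUMMARY_COUNT_COLS])))
  } else rep(0, length(SUMMARY_COUNT_COLS))
  tab <- rbind(
    cbind(data.frame(level = "grand_total", phylum = NA_character_,
                     taxon = "total counts of strains",
                     stringsAsFactors = FALSE),
          as.data.frame(t(stats::setNames(grand, SUMMARY_COUNT_COLS)))),
    do.call(rbind, rows))
  rownames(tab) <- NULL
  for (cc in SUMMARY_COUNT_COLS) tab[[cc]] <- as.integer(tab[[cc]])
  tab <- structure(tab, class = c("summary_table", "data.frame"))
  check_conservation(tab)
  tab
}

#' Check column-wise conservation of a summary table
#'
#' Asserts, for every count column, that each phylum-total row equals the sum
#' of its order rows and that the grand total equals the sum of phylum
#' totals.
#'
#' @param tab a `summary_table`.
#' @return invisibly `TRUE`; stops with a message naming the offending
#'   column/taxon otherwise.
#' @export
check_conservation <- function(tab) {
  stopifnot(all(c("level", "phylum", "taxon") %in% names(tab)))
  for (cc in intersect(SUMMARY_COUNT_COLS, names(tab))) {
    for (ph in tab$taxon[tab$level == "phylum"]) {
      s <- sum(tab[[cc]][tab$level == "order" & tab$phylum %in% ph])
      t <- tab[[cc]][tab$level == "phylum" & tab$taxon == ph]
      if (s != t)
        stop("conservation violated in column '", cc, "' for phylum ", ph,
             ": orders sum to ", s, " but total row says ", t)
    }
    s <- sum(tab[[cc]][tab$level == "phylum"])
    t <- tab[[cc]][tab$level == "grand_total"]
    if (length(t) && s != t)
      stop("conservation violated in column '", cc,
           "': phylum totals sum to ", s, " but grand total says ", t)
  }
  invisible(TRUE)
}

#' Write a summary table as TSV (zeros rendered as blanks)
#'
#' Zero counts in every column except `total` are written as empty cells,
#' matching the dialect of published strain-count tables; [read_summary_table()]
#' maps them back to 0.
#'
#' @param tab a `summary_table`.
#' @param path output path.
#' @export
write_summary_table <- function(tab, path) {
  out <- tab
  for (cc in setdiff(SUMMARY_COUNT_COLS, "total"))
    out[[cc]] <- ifelse(out[[cc]] == 0L, "", as.character(out[[cc]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path TSV path.
#' @return a `summary_table` (blank cells as 0).
#' @export
read_summary_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = c(level = "character",
                                          phylum = "character",
                                          taxon = "character"))
  for (cc in intersect(SUMMARY_COUNT_COLS, names(tab))) {
    v <- tab[[cc]]
    if (!is.numeric(v)) v <- suppressWarnings(as.integer(v))
    v[is.na(v)] <- 0L
    tab[[cc]] <- as.integer(v)
  }
  tab$phylum[tab$phylum %in% ""] <- NA_character_
  structure(tab, class = c("summary_table", "data.frame"))
}

#' Bundled transcription of the published strain-count summary table
#'
#' Order rows plus the printed phylum/grand-total rows of the published
#' summary of predicted metabolism for strains from genera lacking
#' autotrophy evidence, transcribed cell-for-cell (blank cells are 0).
#'
#' @return a `summary_table`.
#' @export
published_strain_counts <- function() {
  read_summary_table(system.file("extdata", "published_strain_counts.tsv",
                                 package = "cbbscan", mustWork = TRUE))
}

#' Expand a summary table's order rows into synthetic per-strain records
#'
#' Inverse-direction helper for exercising [summarize_strains()] against a
#' printed count matrix: for each order row, emits that many records and
#' marks the first *k* of them positive for each trait column (forms become
#' `forms_present` members, donor/acceptor columns become the corresponding
#' booleans, sulfur oxidation uses the `sqr_only` state). Marginal column
#' counts of the result match the input row by construction; multi-form
#' strains arise naturally when form counts exceed the strain count.
#'
#' @param tab a `summary_table` (only `level == "order"` rows are used).
#' @return annotated records data.frame suitable for [summarize_strains()].
#' @export
expand_counts_to_records <- function(tab) {
  ords <- tab[tab$level == "order", , drop = FALSE]
  recs <- lapply(seq_len(nrow(ords)), function(i) {
    r <- ords[i, ]
    n <- r$total
    if (n == 0L) return(NULL)
    idx <- seq_len(n)
    forms <- vapply(idx, function(j)
      paste(SUMMARY_FORM_COLS[vapply(SUMMARY_FORM_COLS,
                                     function(f) j <= r[[f]], logical(1))],
            collapse = ";"), "")
    data.frame(
      genome_id = sprintf("%s_%s_%02d", r$phylum, r$taxon, idx),
      h2_uptake = idx <= r$h2_oxidation,
      sulfur_oxidation = ifelse(idx <= r$sulfur_oxidation, "sqr_only",
                                "none"),
      oxygen_aerobic_lowaff = idx <= r$aerobic,
      oxygen_microaerophilic_highaff = idx <= r$microaerophilic,
      nitrate_reduction = idx <= r$nitrate_reduction,
      sulfur_reduction = idx <= r$sulfur_reduction,
      photosystem_ii = idx <= r$photosynthesis,
      forms_present = forms,
      phylum = r$phylum, order = r$taxon, genus = r$taxon,
      evidence = "untested", environment = "unknown",
      plant_associated = FALSE, genus_evidence = FALSE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Isolation-environment breakdown for strains carrying a given RubisCO form
#'
#' @param records annotated records from [join_evidence()].
#' @param form a form label (e.g. `"IA"`); `NULL` for all records.
#' @return one-row data.frame with one column per environment category
#'   (absent categories 0), a `total`, plus derived tallies
#'   `terrestrial_incl_rhizosphere` (terrestrial + rhizosphere) and
#'   `plant_associated` (rhizosphere + organism-hosted strains flagged as
#'   plant material).
#' @export
summarize_environments <- function(records, form = NULL) {
  if (!is.null(form))
    records <- records[.has_form(records, form), , drop = FALSE]
  counts <- vapply(ENV_LEVELS, function(e) sum(records$environment == e),
                   integer(1))
  out <- as.data.frame(t(counts))
  out$total <- nrow(records)
  out$terrestrial_incl_rhizosphere <-
    out$terrestrial + out$rhizosphere_plant
  out$plant_associated <- out$rhizosphere_plant +
    sum(records$environment == "organism_hosted" & records$plant_associated)
  out
}

#' Read a strain metadata TSV
#'
#' @param path TSV with columns `genome_id`, `phylum`, `order`, `genus`,
#'   `evidence`, `environment` (optional `strain_label`,
#'   `plant_associated`).
#' @return data.frame.
#' @export
read_strain_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "phylum", "order", "genus", "evidence",
            "environment")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md
}
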