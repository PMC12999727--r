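# Trait rule engine: maps marker presence to predicted electron donors,
# electron acceptors and phototrophy.
#
# Rules (all derivable from marker hits alone):
#   h2_uptake          any uptake hydrogenase (NiFe 1/2a-2e/4h/4i, FeFe A2/A3)
#   sulfur_oxidation   complete_sox  = soxA & soxB & soxX & soxY & soxZ
#                      partial_sox_lacking_soxB = soxA & soxX & soxY & soxZ & !soxB
#                      sqr_only      = sqr present, neither sox state
#                      none          otherwise
#   oxygen (low-affinity, "aerobic")        coxA&coxB | cyoA&cyoB&cyoC&cyoD
#   oxygen (high-affinity, "microaerophilic") ccoN&ccoO | cydA&cydB
#   nitrate_reduction  narG & narH
#   sulfur_reduction   dsrA & dsrB
#   photosystem_ii     pufL & pufM

UPTAKE_NIFE_GROUPS <- c("1", "2a", "2b", "2c", "2d", "2e", "4h", "4i")
UPTAKE_FEFE_GROUPS <- c("A2", "A3")

#' Classify a hydrogenase marker hit into family/group and uptake status
#'
#' The group is carried by the catalog marker that matched (hydrogenase seeds
#' are group-labelled, so the nearest-seed search already performed the group
#' call). Uptake hydrogenases are NiFe groups 1, 2a-2e, 4h, 4i and FeFe
#' groups A2, A3; other groups (e.g. NiFe 3b) are not H2-oxidizing in this
#' rule set.
#'
#' @param hit one-row hits data.frame whose `marker_id` is a hydrogenase
#'   marker (`hydrogenase:<family>:<group>`).
#' @param catalog a `marker_catalog`.
#' @return one-row data.frame: `protein_id`, `family`, `group`, `is_uptake`.
#' @export
classify_hydrogenase <- function(hit, catalog) {
  stopifnot(nrow(hit) == 1L)
  m <- catalog$markers[[hit$marker_id]]
  if (is.null(m) || m$category != "hydrogenase")
    stop("not a hydrogenase marker: ", hit$marker_id)
  parts <- strsplit(hit$marker_id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L || parts[1] != "hydrogenase")
    stop("malformed hydrogenase marker_id: ", hit$marker_id)
  family <- parts[2]; group <- parts[3]
  up <- (family == "NiFe" && group %in% UPTAKE_NIFE_GROUPS) ||
        (family == "FeFe" && group %in% UPTAKE_FEFE_GROUPS)
  data.frame(protein_id = hit$protein_id, family = family, group = group,
             is_uptake = up, stringsAsFactors = FALSE)
}

#' Classify all hydrogenase hits of a hit table
#'
#' @param hits hits data.frame.
#' @param catalog a `marker_catalog`.
#' @return data.frame (possibly 0-row) of hydrogenase calls.
#' @export
classify_hydrogenases <- function(hits, catalog) {
  hy <- hits[grepl("^hydrogenase:", hits$marker_id), , drop = FALSE]
  if (!nrow(hy))
    return(data.frame(protein_id = character(), family = character(),
                      group = character(), is_uptake = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(hy)), function(i)
    classify_hydrogenase(hy[i, ], catalog)))
  rownames(out) <- NULL
  out
}

#' Infer a genome's trait profile from marker hits
#'
#' @param hits marker hits for the genome.
#' @param hydro_calls hydrogenase calls from [classify_hydrogenases()].
#' @param assignments RbcL form assignments for the genome (may be 0-row).
#' @param genome_id genome identifier.
#' @return a `trait_profile` (list) with fields `genome_id`, `h2_uptake`,
#'   `sulfur_oxidation`, `oxygen_aerobic_lowaff`,
#'   `oxygen_microaerophilic_highaff`, `nitrate_reduction`,
#'   `sulfur_reduction`, `photosystem_ii`, `forms_present`.
#' @export
infer_traits <- function(hits, hydro_calls, assignments, genome_id) {
  if (nrow(hits) && !all(hits$genome_id == genome_id))
    stop("hits contain rows for other genomes than ", genome_id)
  p <- unique(hits$marker_id)
  has <- function(...) all(c(...) %in% p)
  sox_rest <- has("soxA", "soxX", "soxY", "soxZ")
  sulfur_ox <-
    if (sox_rest && has("soxB")) "complete_sox"
    else if (sox_rest) "partial_sox_lacking_soxB"
    else if (has("sqr")) "sqr_only"
    else "none"
  forms <- if (nrow(assignments)) unique(assignments$form) else character(0)
  structure(list(
    genome_id = genome_id,
    h2_uptake = nrow(hydro_calls) > 0 && any(hydro_calls$is_uptake),
    sulfur_oxidation = sulfur_ox,
    oxygen_aerobic_lowaff = has("coxA", "coxB") ||
      has("cyoA", "cyoB", "cyoC", "cyoD"),
    oxygen_microaerophilic_highaff = has("ccoN", "ccoO") ||
      has("cydA", "cydB"),
    nitrate_reduction = has("narG", "narH"),
    sulfur_reduction = has("dsrA", "dsrB"),
    photosystem_ii = has("pufL", "pufM"),
    forms_present = forms), class = "trait_profile")
}

#' Bind trait profiles into a data.frame
#'
#' `forms_present` is collapsed to a `;`-separated string.
#'
#' @param profiles list of `trait_profile`.
#' @return data.frame with one row per genome.
#' @export
profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(pr)
    data.frame(genome_id = pr$genome_id, h2_uptake = pr$h2_uptake,
               sulfur_oxidation = pr$sulfur_oxidation,
               oxygen_aerobic_lowaff = pr$oxygen_aerobic_lowaff,
               oxygen_microaerophilic_highaff =
                 pr$oxygen_microaerophilic_highaff,
               nitrate_reduction = pr$nitrate_reduction,
               sulfur_reduction = pr$sulfur_reduction,
               photosystem_ii = pr$photosystem_ii,
               forms_present = paste(sort(pr$forms_present), collapse = ";"),
               stringsAsFactors = FALSE)))
}

#' Predict plausible autotrophic growth modes
#'
#' Emits the cross-product of detected electron donors (H2 from uptake
#' hydrogenases; sulfur species from any sulfur-oxidation state) and
#' acceptors (O2 at either affinity class, nitrate, sulfur species), but only
#' for genomes whose RubisCO configuration is CO2-fixing eligible. A
#' phototrophy row is added when both photosystem-II reaction-center genes
#' are present; it is always flagged `CBB-not-necessarily-autotrophic`
#' because aerobic anoxygenic phototrophs carry CBB genes without autotrophic
#' growth, and when no donor is detected the note records the
#' redox-balancing interpretation.
#'
#' @param profile a `trait_profile`.
#' @param cbb one-row data.frame from [evaluate_eligibility()].
#' @return data.frame with columns `genome_id`, `donor`, `acceptor`, `mode`,
#'   `note` (0 rows when not eligible).
#' @export
predict_growth_modes <- function(profile, cbb) {
  stopifnot(inherits(profile, "trait_profile"), nrow(cbb) == 1L)
  if (!identical(profile$genome_id, cbb$genome_id))
    stop("profile and eligibility verdict are for different genomes")
  empty <- data.frame(genome_id = character(), donor = character(),
                      acceptor = character(), mode = character(),
                      note = character(), stringsAsFactors = FALSE)
  if (!isTRUE(cbb$eligible)) return(empty)
  donors <- c(if (profile$h2_uptake) "H2",
              if (profile$sulfur_oxidation != "none") "sulfur_species")
  acceptors <- c(if (profile$oxygen_aerobic_lowaff) "O2_aerobic",
                 if (profile$oxygen_microaerophilic_highaff)
                   "O2_microaerophilic",
                 if (profile$nitrate_reduction) "nitrate",
                 if (profile$sulfur_reduction) "sulfur_species")
  out <- empty
  if (length(donors) && length(acceptors)) {
    grid <- expand.grid(donor = donors, acceptor = acceptors,
                        stringsAsFactors = FALSE)
    out <- data.frame(genome_id = profile$genome_id, donor = grid$donor,
                      acceptor = grid$acceptor,
                      mode = "chemolithoautotrophy", note = "",
                      stringsAsFactors = FALSE)
  }
  if (profile$photosystem_ii) {
    note <- "CBB-not-necessarily-autotrophic"
    if (!length(donors))
      note <- paste(note, "no-donor-detected:possible-redox-balancing",
                    sep = ";")
    out <- rbind(out, data.frame(genome_id = profile$genome_id,
                                 donor = "light", acceptor = NA_character_,
                                 mode = "photoautotrophy", note = note,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Per-trait supporting marker evidence as JSON-ready list
#'
#' @param hits marker hits for one genome.
#' @param profile the genome's `trait_profile`.
#' @return nested list mapping each trait to the marker ids supporting it.
#' @export
trait_evidence <- function(hits, profile) {
  p <- unique(hits$marker_id)
  keep <- function(ids) intersect(ids, p)
  list(genome_id = profile$genome_id,
       h2_uptake = keep(grep("^hydrogenase:", p, value = TRUE)),
       sulfur_oxidation = keep(c("soxA", "soxB", "soxX", "soxY", "soxZ",
                                 "sqr")),
       oxygen_aerobic_lowaff = keep(c("coxA", "coxB", "cyoA", "cyoB", "cyoC",
                                      "cyoD")),
       oxygen_microaerophilic_highaff = keep(c("ccoN", "ccoO", "cydA",
                                               "cydB")),
       nitrate_reduction = keep(c("narG", "narH")),
       sulfur_reduction = keep(c("dsrA", "dsrB")),
       photosystem_ii = keep(c("pufL", "pufM")))
}
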