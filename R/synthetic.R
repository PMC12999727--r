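# Synthetic proteome simulator: emits genomes with known ground-truth trait
# profiles, CBB gene content and RbcL forms, so every pipeline stage can be
# exercised and benchmarked without external data.
#
# The mutation model is deliberately non-phylogenetic: substitutions are
# drawn uniformly over the 19 alternative residues and indels are off by
# default, so realized identity is controlled tightly. Decoy proteins are
# residue-shuffled catalog seeds (same composition, no homology).

#' Mutate a sequence to a target identity
#'
#' Substitutes `round((1 - target) * L)` positions (sampled without
#' replacement) with residues drawn uniformly from the 19 alternatives; the
#' realized global-alignment identity to the input is verified to be within
#' +/- 0.02 of the target. With `indels = TRUE` a small number of short
#' indels (geometric lengths) is additionally applied.
#'
#' Draws from the session RNG; seed it (or use [generate_proteomes()], which
#' seeds it from the spec) for reproducibility.
#'
#' @param seed_seq amino-acid sequence to mutate.
#' @param target_identity target identity in \[0.3, 1\].
#' @param indels add indels (default `FALSE`).
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seed_seq, target_identity, indels = FALSE) {
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1)
    stop("target_identity must be in (0, 1]")
  if (target_identity < 0.3)
    stop("target_identity below 0.3 is outside the classifier validity ",
         "range")
  if (target_identity == 1 && !indels) return(seed_seq)
  v0 <- strsplit(seed_seq, "", fixed = TRUE)[[1]]
  L <- length(v0)
  k <- round((1 - target_identity) * L)
  for (attempt in 1:5) {
    v <- v0
    if (k > 0) {
      idx <- sample(L, k)
      for (i in idx) v[i] <- sample(setdiff(AA_ALPHABET, v[i]), 1L)
    }
    if (indels) {
      n_ind <- stats::rbinom(1, 1, 0.5) + 1L
      for (z in seq_len(n_ind)) {
        len <- stats::rgeom(1, 0.5) + 1L
        pos <- sample(length(v) - len, 1L)
        if (stats::runif(1) < 0.5) v <- v[-(pos:(pos + len - 1L))]
        else v <- append(v, sample(AA_ALPHABET, len, replace = TRUE), pos)
      }
    }
    out <- paste(v, collapse = "")
    realized <- pairwise_identity(out, seed_seq)
    if (abs(realized - target_identity) <= 0.02) return(out)
  }
  stop("could not realize target identity ", target_identity,
       " within +/- 0.02 (last realized ", round(realized, 3), ")")
}

#' Specification for a synthetic genome cohort
#'
#' @param genomes list of per-genome truth lists (see
#'   [random_synthetic_spec()] for the generated structure).
#' @param rng_seed integer seed controlling all randomness of
#'   [generate_proteomes()].
#' @param target_identity identity of emitted genes to their seeds.
#' @param n_decoys shuffled decoy proteins per genome.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(genomes, rng_seed, target_identity = 0.85,
                           n_decoys = 8L) {
  stopifnot(length(genomes) >= 1L, is.numeric(rng_seed))
  structure(list(genomes = genomes, rng_seed = as.integer(rng_seed),
                 target_identity = target_identity,
                 n_decoys = as.integer(n_decoys)),
            class = "synthetic_spec")
}

#' Randomly sample a synthetic cohort specification
#'
#' Per genome: 0-2 RbcL copies with forms drawn from the panel's labels;
#' each donor/acceptor/photosystem trait is an independent coin flip at the
#' given prevalences; the four CBB steps are present with high probability
#' (RbcL presence is tied to having a copy); partial complexes (e.g. coxA
#' without coxB, narG without narH, pufL without pufM) and a non-uptake
#' hydrogenase are sprinkled in as distractors that must not flip any trait.
#'
#' @param n_genomes number of genomes.
#' @param rng_seed integer seed.
#' @param target_identity identity of emitted genes to their seeds
#'   (default 0.85).
#' @param forms pool of RbcL form labels to sample from.
#' @param prevalence named list of trait prevalences.
#' @param n_decoys decoy proteins per genome (default 8).
#' @return a `synthetic_spec`.
#' @export
random_synthetic_spec <- function(n_genomes, rng_seed,
                                  target_identity = 0.85,
                                  forms = setdiff(FORM_LEVELS, "UNASSIGNED"),
                                  prevalence = list(
                                    h2_uptake = 0.5, sulfur_ox_state =
                                      c(none = 0.4, complete_sox = 0.2,
                                        partial_sox_lacking_soxB = 0.2,
                                        sqr_only = 0.2),
                                    oxygen_aerobic = 0.5,
                                    oxygen_micro = 0.5, nitrate = 0.5,
                                    sulfur_red = 0.3, photosystem = 0.3,
                                    rbcs = 0.5),
                                  n_decoys = 8L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  coin <- function(p) stats::runif(1) < p
  genomes <- lapply(seq_len(n_genomes), function(i) {
    n_copies <- sample(0:2, 1L, prob = c(0.15, 0.65, 0.20))
    gf <- if (n_copies) sample(forms, n_copies) else character(0)
    list(genome_id = sprintf("syn%03d", i),
         domain = "bacteria",
         forms = gf,
         rbcs_present = coin(prevalence$rbcs),
         rbcs_offset = sample(1:10, 1L),
         step1_prk = coin(0.8),
         step3_pgk = coin(0.9),
         gap_marker = if (coin(0.9)) sample(GAP_ALTERNATIVES, 1L)
                      else NA_character_,
         h2_uptake = coin(prevalence$h2_uptake),
         uptake_group = sample(c(paste0("hydrogenase:NiFe:",
                                        UPTAKE_NIFE_GROUPS),
                                 paste0("hydrogenase:FeFe:",
                                        UPTAKE_FEFE_GROUPS)), 1L),
         nonuptake_distractor = coin(0.3),
         sulfur_oxidation = sample(names(prevalence$sulfur_ox_state), 1L,
                                   prob = prevalence$sulfur_ox_state),
         oxygen_aerobic = coin(prevalence$oxygen_aerobic),
         aerobic_complex = sample(c("cox", "cyo"), 1L),
         oxygen_micro = coin(prevalence$oxygen_micro),
         micro_complex = sample(c("cco", "cyd"), 1L),
         nitrate = coin(prevalence$nitrate),
         nitrate_distractor = coin(0.3),
         sulfur_red = coin(prevalence$sulfur_red),
         photosystem = coin(prevalence$photosystem),
         photo_distractor = coin(0.2))
  })
  synthetic_spec(genomes, rng_seed, target_identity, n_decoys)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.truth_marker_genes <- function(g) {
  # marker ids the genome must carry, in emission order
  ids <- character(0)
  if (g$step1_prk) ids <- c(ids, "K00855")
  if (g$step3_pgk) ids <- c(ids, "K00927")
  if (!is.na(g$gap_marker)) ids <- c(ids, g$gap_marker)
  if (g$h2_uptake) ids <- c(ids, g$uptake_group)
  if (g$nonuptake_distractor) ids <- c(ids, "hydrogenase:NiFe:3b")
  ids <- c(ids, switch(g$sulfur_oxidation,
                       complete_sox = c("soxA", "soxB", "soxX", "soxY",
                                        "soxZ"),
                       partial_sox_lacking_soxB = c("soxA", "soxX", "soxY",
                                                    "soxZ"),
                       sqr_only = "sqr",
                       none = character(0)))
  if (g$oxygen_aerobic)
    ids <- c(ids, if (g$aerobic_complex == "cox") c("coxA", "coxB")
                  else c("cyoA", "cyoB", "cyoC", "cyoD"))
  if (g$oxygen_micro)
    ids <- c(ids, if (g$micro_complex == "cco") c("ccoN", "ccoO")
                  else c("cydA", "cydB"))
  if (g$nitrate) ids <- c(ids, "narG", "narH")
  else if (g$nitrate_distractor) ids <- c(ids, "narG")
  if (g$sulfur_red) ids <- c(ids, "dsrA", "dsrB")
  if (g$photosystem) ids <- c(ids, "pufL", "pufM")
  else if (g$photo_distractor) ids <- c(ids, "pufL")
  ids
}

#' Ground-truth trait profile implied by a per-genome truth spec
#'
#' @param g one element of `spec$genomes`.
#' @return list in the shape of a `trait_profile` plus CBB step flags.
#' @export
synthetic_truth <- function(g) {
  list(genome_id = g$genome_id,
       h2_uptake = g$h2_uptake,
       sulfur_oxidation = g$sulfur_oxidation,
       oxygen_aerobic_lowaff = g$oxygen_aerobic,
       oxygen_microaerophilic_highaff = g$oxygen_micro,
       nitrate_reduction = g$nitrate,
       sulfur_reduction = g$sulfur_red,
       photosystem_ii = g$photosystem,
       forms = sort(g$forms),
       rbcs_present = g$rbcs_present && length(g$forms) > 0,
       step1_prk = g$step1_prk,
       step2_rbcl = length(g$forms) > 0,
       step3_pgk = g$step3_pgk,
       step4_gap = !is.na(g$gap_marker),
       complete = g$step1_prk && length(g$forms) > 0 && g$step3_pgk &&
         !is.na(g$gap_marker))
}

#' Generate synthetic proteomes with known ground truth
#'
#' For each genome in the spec: emits one mutated gene per true marker
#' (mutants of the catalog's first seed at the spec's target identity), RbcL
#' copies as mutants of each requested form's first panel reference, an rbcS
#' gene at the requested locus offset from the first RbcL copy when truth
#' says present, the spec'd partial-complex distractors, and residue-shuffled
#' decoy proteins. Output is byte-identical for a fixed `rng_seed`.
#'
#' @param spec a `synthetic_spec`.
#' @param catalog a `marker_catalog` (default bundled).
#' @param panel a `reference_panel` (default bundled).
#' @param out_dir if non-`NULL`, writes `<genome_id>.faa` files, a
#'   `metadata.tsv` and a `ground_truth.json` there.
#' @return list with `genomes` (list of `genome_record`), `truth` (list of
#'   [synthetic_truth()] entries) and `metadata` (data.frame).
#' @export
generate_proteomes <- function(spec, catalog = default_catalog(),
                               panel = default_panel(), out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  missing_forms <- setdiff(unique(unlist(lapply(spec$genomes, `[[`,
                                                "forms"))),
                           panel$form)
  if (length(missing_forms))
    stop("spec requests form(s) absent from the panel: ",
         paste(missing_forms, collapse = ", "))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$rng_seed)
  all_seeds <- catalog$seed_index
  genomes <- list(); truth <- list()
  for (g in spec$genomes) {
    ids <- .truth_marker_genes(g)
    prot <- list()
    add <- function(lst, name, seq) { lst[[length(lst) + 1L]] <-
      list(name = name, seq = seq); lst }
    for (k in seq_along(g$forms)) {
      ref <- panel[panel$form == g$forms[k], ][1L, ]
      prot <- add(prot, sprintf("rbcl%d", k),
                  mutate_sequence(ref$sequence, spec$target_identity))
    }
    for (mid in ids) {
      seed <- catalog$markers[[mid]]$seeds[[1L]]
      prot <- add(prot, gsub(":", "_", mid),
                  mutate_sequence(seed, spec$target_identity))
    }
    for (z in seq_len(spec$n_decoys)) {
      src <- all_seeds$sequence[sample(nrow(all_seeds), 1L)]
      prot <- add(prot, sprintf("decoy%02d", z),
                  paste(sample(strsplit(src, "")[[1]]), collapse = ""))
    }
    # shuffle gene order, then place rbcS at the requested offset from the
    # first RbcL copy
    prot <- prot[sample(length(prot))]
    nm <- vapply(prot, `[[`, "", "name")
    rbcs_true <- g$rbcs_present && length(g$forms) > 0
    if (rbcs_true) {
      seed <- catalog$markers[["rbcS"]]$seeds[[1L]]
      rbcs <- list(name = "rbcS",
                   seq = mutate_sequence(seed, spec$target_identity))
      anchor <- which(nm == "rbcl1")
      pos <- min(anchor + g$rbcs_offset - 1L, length(prot))
      # locus distance to rbcl1 = rbcs_offset (capped at the proteome end)
      prot <- append(prot, list(rbcs), after = pos)
    }
    pdf <- data.frame(
      protein_id = sprintf("p%03d_%s", seq_along(prot),
                           vapply(prot, `[[`, "", "name")),
      sequence = vapply(prot, `[[`, "", "seq"),
      stringsAsFactors = FALSE)
    genomes[[g$genome_id]] <-
      genome_record(g$genome_id, pdf,
                    taxonomy = list(domain = g$domain,
                                    phylum = "SynPhylum",
                                    order = "SynOrder",
                                    genus = "SynGenus",
                                    species = g$genome_id))
    truth[[g$genome_id]] <- synthetic_truth(g)
  }
  metadata <- data.frame(
    genome_id = names(genomes),
    strain_label = names(genomes),
    domain = vapply(spec$genomes, `[[`, "", "domain"),
    phylum = "SynPhylum", order = "SynOrder", genus = "SynGenus",
    evidence = "untested", environment = "unknown",
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (gid in names(genomes))
      write_genome_fasta(genomes[[gid]],
                         file.path(out_dir, paste0(gid, ".faa")))
    utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(genomes = genomes, truth = truth, metadata = metadata)
}
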