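# End-to-end convenience wrapper tying the stages together: marker search ->
# CBB status -> RbcL form assignment -> eligibility -> trait profile ->
# growth-mode predictions.

#' Scan one genome through the whole pipeline
#'
#' @param genome a `genome_record`.
#' @param catalog a `marker_catalog`.
#' @param panel a `reference_panel`.
#' @param window rbcS colocalization window in loci.
#' @param identity_floor,margin_floor form-call floors (see [assign_form()]).
#' @return list with `hits`, `cbb`, `assignments`, `verdict`, `profile`,
#'   `modes`.
#' @export
scan_genome <- function(genome, catalog = default_catalog(),
                        panel = default_panel(), window = 5L,
                        identity_floor = 0.45, margin_floor = 0.02) {
  hits <- search_markers(genome, catalog)
  cbb <- evaluate_cbb(hits, genome$genome_id)
  assignments <- assign_forms_genome(genome, hits, panel, window,
                                     identity_floor, margin_floor)
  verdict <- evaluate_eligibility(cbb, assignments,
                                  domain = domain_of(genome))
  hydro <- classify_hydrogenases(hits, catalog)
  profile <- infer_traits(hits, hydro, assignments, genome$genome_id)
  modes <- predict_growth_modes(profile, verdict)
  list(hits = hits, cbb = cbb, assignments = assignments, verdict = verdict,
       profile = profile, modes = modes)
}

#' Scan a list of genomes
#'
#' @param genomes list of `genome_record`.
#' @inheritParams scan_genome
#' @return list of data.frames `hits`, `cbb`, `assignments`, `verdicts`,
#'   `modes`, plus `profiles` (list) and `profiles_df`.
#' @export
scan_genomes <- function(genomes, catalog = default_catalog(),
                         panel = default_panel(), window = 5L,
                         identity_floor = 0.45, margin_floor = 0.02) {
  res <- lapply(genomes, scan_genome, catalog = catalog, panel = panel,
                window = window, identity_floor = identity_floor,
                margin_floor = margin_floor)
  bind <- function(field) {
    out <- do.call(rbind, lapply(res, `[[`, field))
    rownames(out) <- NULL
    out
  }
  profiles <- lapply(res, `[[`, "profile")
  list(hits = bind("hits"), cbb = bind("cbb"),
       assignments = bind("assignments"), verdicts = bind("verdict"),
       modes = bind("modes"), profiles = profiles,
       profiles_df = profiles_to_df(profiles))
}

## ---- benchmark experiments on synthetic data --------------------------------

#' End-to-end parameter-recovery experiment
#'
#' Generates a random synthetic cohort, runs the full pipeline, and compares
#' inferred trait profiles, CBB completeness and RbcL form sets against the
#' generator's ground truth.
#'
#' @param n_genomes cohort size (default 30).
#' @param target_identity identity of emitted genes to their seeds
#'   (default 0.85).
#' @param seed integer RNG seed.
#' @param catalog,panel reference data (default bundled).
#' @return list with per-genome comparison data.frame (`per_genome`) and
#'   summary rates: `trait_recovery`, `form_recovery`, `cbb_recovery`,
#'   `wrong_form_rate` (fractions in \[0, 1\]).
#' @export
recovery_experiment <- function(n_genomes = 30L, target_identity = 0.85,
                                seed = 1L, catalog = default_catalog(),
                                panel = default_panel()) {
  spec <- random_synthetic_spec(n_genomes, rng_seed = seed,
                                target_identity = target_identity)
  sim <- generate_proteomes(spec, catalog, panel)
  scan <- scan_genomes(sim$genomes, catalog, panel)
  trait_fields <- c("h2_uptake", "sulfur_oxidation", "oxygen_aerobic_lowaff",
                    "oxygen_microaerophilic_highaff", "nitrate_reduction",
                    "sulfur_reduction", "photosystem_ii")
  per <- lapply(names(sim$genomes), function(gid) {
    tr <- sim$truth[[gid]]
    pr <- scan$profiles[[gid]]
    asn <- scan$assignments[scan$assignments$genome_id == gid, ,
                            drop = FALSE]
    called <- sort(asn$form[asn$form != "UNASSIGNED"])
    traits_ok <- all(vapply(trait_fields,
                            function(f) identical(tr[[f]], pr[[f]]),
                            logical(1)))
    cbb_row <- scan$cbb[scan$cbb$genome_id == gid, ]
    data.frame(genome_id = gid,
               traits_ok = traits_ok,
               forms_ok = identical(called, tr$forms),
               wrong_form = length(setdiff(called, tr$forms)) > 0,
               cbb_ok = identical(cbb_row$complete, tr$complete),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_genome = per,
       trait_recovery = mean(per$traits_ok),
       form_recovery = mean(per$forms_ok),
       cbb_recovery = mean(per$cbb_ok),
       wrong_form_rate = mean(per$wrong_form),
       n = nrow(per))
}

#' Form-call recovery sweep over panel-seed mutants
#'
#' Mutates every form's first panel reference `n_per_form` times at the
#' given identity and re-assigns each mutant against the panel.
#'
#' @param n_per_form mutants per form (default 50).
#' @param target_identity mutation identity target.
#' @param seed integer RNG seed.
#' @param panel a `reference_panel`.
#' @return list with `recovery` (fraction assigned the true form),
#'   `unassigned_rate`, `wrong_form_rate`, and the per-mutant data.frame.
#' @export
form_recovery_sweep <- function(n_per_form = 50L, target_identity = 0.85,
                                seed = 1L, panel = default_panel()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  forms <- unique(panel$form)
  rows <- list()
  for (f in forms) {
    ref <- panel[panel$form == f, ][1L, ]
    for (z in seq_len(n_per_form)) {
      mut <- mutate_sequence(ref$sequence, target_identity)
      a <- assign_form(mut, panel)
      rows[[length(rows) + 1L]] <-
        data.frame(true_form = f, called_form = a$form,
                   identity_to_nearest = a$identity_to_nearest,
                   stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  list(recovery = mean(per$called_form == per$true_form),
       unassigned_rate = mean(per$called_form == "UNASSIGNED"),
       wrong_form_rate = mean(per$called_form != per$true_form &
                                per$called_form != "UNASSIGNED"),
       per_mutant = per)
}

#' Decoy false-positive experiment
#'
#' Builds residue-shuffled versions of randomly chosen catalog seeds and
#' counts how many produce any marker hit at the default thresholds.
#'
#' @param n number of decoys (default 200).
#' @param seed integer RNG seed.
#' @param catalog a `marker_catalog`.
#' @return list with `fp_rate` (fraction of decoys with >= 1 hit) and `n`.
#' @export
decoy_fp_experiment <- function(n = 200L, seed = 1L,
                                catalog = default_catalog()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  idx <- catalog$seed_index
  decoys <- vapply(seq_len(n), function(i) {
    src <- idx$sequence[sample(nrow(idx), 1L)]
    paste(sample(strsplit(src, "")[[1]]), collapse = "")
  }, "")
  g <- genome_record("decoys",
                     data.frame(protein_id = sprintf("d%03d", seq_len(n)),
                                sequence = decoys,
                                stringsAsFactors = FALSE))
  hits <- search_markers(g, catalog)
  list(fp_rate = length(unique(hits$protein_id)) / n, n = n)
}
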