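# Synthetic proteome generator: identity control, determinism, ground-truth
# consistency, and the leave-one-out CBB sweep.

test_that("mutate_sequence hits its identity target and validates input", {
  set.seed(801)
  s <- random_protein(200)
  expect_identical(mutate_sequence(s, 1.0), s)
  m85 <- mutate_sequence(s, 0.85)
  expect_equal(nw_oracle(m85, s)$identity, 0.85, tolerance = 0.021)
  m60 <- mutate_sequence(s, 0.60)
  expect_equal(nw_oracle(m60, s)$identity, 0.60, tolerance = 0.021)
  expect_error(mutate_sequence(s, 0.2), "validity")
  expect_error(mutate_sequence(s, 0), "\\(0, 1\\]")
  expect_error(mutate_sequence(s, 1.2), "\\(0, 1\\]")
  mi <- mutate_sequence(s, 0.85, indels = TRUE)
  expect_equal(nw_oracle(mi, s)$identity, 0.85, tolerance = 0.021)
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- random_synthetic_spec(4, rng_seed = 42)
  spec2 <- random_synthetic_spec(4, rng_seed = 42)
  expect_identical(spec, spec2)
  d1 <- tempfile(); d2 <- tempfile()
  generate_proteomes(spec, out_dir = d1)
  generate_proteomes(spec, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("every true-positive marker has an emitted, detectable gene", {
  spec <- random_synthetic_spec(4, rng_seed = 11)
  sim <- generate_proteomes(spec)
  cat_ <- default_catalog()
  for (gid in names(sim$genomes)) {
    hits <- search_markers(sim$genomes[[gid]], cat_)
    tr <- sim$truth[[gid]]
    if (tr$step1_prk) expect_true("K00855" %in% hits$marker_id)
    if (tr$step2_rbcl) expect_true("K01601" %in% hits$marker_id)
    if (tr$rbcs_present) expect_true("rbcS" %in% hits$marker_id)
    if (tr$sulfur_oxidation == "partial_sox_lacking_soxB") {
      expect_true(all(c("soxA", "soxX", "soxY", "soxZ") %in% hits$marker_id))
      expect_false("soxB" %in% hits$marker_id)
    }
  }
})

test_that("an unsatisfiable form request errors", {
  spec <- random_synthetic_spec(1, rng_seed = 5)
  spec$genomes[[1]]$forms <- "IA"
  pan <- default_panel()
  pan_no_ia <- pan[pan$form != "IA", ]
  class(pan_no_ia) <- c("reference_panel", "data.frame")
  expect_error(generate_proteomes(spec, panel = pan_no_ia), "IA")
})

test_that("removing any single CBB marker gene flips completeness off", {
  set.seed(802)
  cat_ <- default_catalog()
  pan <- default_panel()
  # a complete genome: PRK, rbcL, PGK, one GAP alternative
  seqs <- c(prk = mutate_sequence(unname(cat_$markers[["K00855"]]$seeds[[1]]),
                                  0.85),
            rbcl = mutate_sequence(pan$sequence[pan$form == "IC"][1], 0.85),
            pgk = mutate_sequence(unname(cat_$markers[["K00927"]]$seeds[[1]]),
                                  0.85),
            gap = mutate_sequence(unname(cat_$markers[["K00134"]]$seeds[[1]]),
                                  0.85),
            decoy = random_protein(150))
  mk <- function(s) genome_record("g", data.frame(
    protein_id = names(s), sequence = unname(s), stringsAsFactors = FALSE))
  full <- evaluate_cbb(search_markers(mk(seqs), cat_), "g")
  expect_true(full$complete)
  for (drop in c("prk", "rbcl", "pgk", "gap")) {
    st <- evaluate_cbb(search_markers(mk(seqs[names(seqs) != drop]), cat_),
                       "g")
    expect_false(st$complete)
  }
})
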