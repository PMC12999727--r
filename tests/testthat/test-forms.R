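# RbcL form assignment, rbcS detection, and representative selection.

test_that("every bundled panel entry is assigned its own form at identity 1
           with positive margin", {
  pan <- default_panel()
  for (i in seq_len(nrow(pan))) {
    a <- assign_form(pan$sequence[i], pan)
    expect_equal(a$form, pan$form[i])
    expect_equal(a$identity_to_nearest, 1.0)
    expect_gt(a$margin, 0)
  }
})

test_that("85% mutants recover their form; chimeras and short or distant
           queries go UNASSIGNED", {
  set.seed(401)
  pan <- default_panel()
  ie <- pan$sequence[pan$form == "IE"][1]
  mut <- substitute_fraction(ie, 0.15)
  a <- assign_form(mut, pan)
  expect_equal(a$form, "IE")
  # nearest-reference call cross-checked by exhaustive oracle alignment
  ids <- vapply(pan$sequence, function(r) nw_oracle(mut, r)$identity, 0)
  expect_equal(a$nearest_ref_id, pan$ref_id[which.max(ids)])
  expect_equal(a$identity_to_nearest, max(ids), tolerance = 1e-9)
  # balanced chimera of an IA and an IB reference: equally close to both
  # parents, so the inter-form margin sits below the floor
  ia <- strsplit(pan$sequence[pan$form == "IA"][1], "")[[1]]
  ib <- strsplit(pan$sequence[pan$form == "IB"][1], "")[[1]]
  diffs <- which(ia != ib)
  chi <- ia
  chi[diffs[seq_along(diffs) %% 2 == 0]] <-
    ib[diffs[seq_along(diffs) %% 2 == 0]]
  a2 <- assign_form(paste(chi, collapse = ""), pan)
  expect_lt(a2$margin, 0.02)
  expect_equal(a2$form, "UNASSIGNED")
  # short query
  expect_warning(a3 <- assign_form(paste(chi[1:60], collapse = ""), pan),
                 "100")
  expect_equal(a3$form, "UNASSIGNED")
  # random sequence: below the identity floor
  expect_equal(assign_form(random_protein(300), pan)$form, "UNASSIGNED")
})

test_that("rbcS presence and colocalization follow the locus window", {
  cat_ <- default_catalog()
  rbcl_seed <- unname(cat_$markers[["K01601"]]$seeds[[1]])
  rbcs_seed <- unname(cat_$markers[["rbcS"]]$seeds[[1]])
  mk <- function(gap) {
    pads <- replicate(25, random_protein(60))
    seqs <- c(rbcl_seed, pads[1:gap], rbcs_seed, pads[(gap + 1):25])
    genome_record("g", data.frame(
      protein_id = sprintf("p%02d", seq_along(seqs)), sequence = seqs,
      stringsAsFactors = FALSE))
  }
  set.seed(402)
  run <- function(g) {
    hits <- search_markers(g, cat_)
    detect_rbcs(g, hits[hits$marker_id == "K01601", ],
                hits[hits$marker_id == "rbcS", ], window = 5)
  }
  adj <- run(mk(gap = 0))    # adjacent loci
  expect_true(adj[["present"]]); expect_true(adj[["colocalized"]])
  far <- run(mk(gap = 19))   # ~20 loci away
  expect_true(far[["present"]]); expect_false(far[["colocalized"]])
  # no rbcS anywhere
  g0 <- genome_record("g", data.frame(protein_id = "p1",
                                      sequence = rbcl_seed,
                                      stringsAsFactors = FALSE))
  h0 <- search_markers(g0, cat_)
  none <- detect_rbcs(g0, h0[h0$marker_id == "K01601", ],
                      h0[h0$marker_id == "rbcS", ], 5)
  expect_false(none[["present"]]); expect_false(none[["colocalized"]])
})

test_that("representative selection keeps one strain of evidenced genera and
           all strains of unevidenced ones", {
  md <- data.frame(
    genome_id = paste0("g", 1:7),
    strain_label = c("ST 3", "ST 1", "ST 2", "ST 9", "ST 8", "ST 7",
                     "ST 5"),
    genus = c("Alpha", "Alpha", "Alpha", "Beta", "Beta", "Beta", "Beta"),
    evidence = c("demonstrated", "untested", "demonstrated", "untested",
                 "untested", "reported_negative", "untested"),
    stringsAsFactors = FALSE)
  sel <- select_representatives(md)
  # Alpha has evidence: smallest evidence-positive strain label (ST 2 -> g3)
  expect_equal(sum(startsWith(sel, "g") &
                     sel %in% c("g1", "g2", "g3")), 1L)
  expect_true("g3" %in% sel)
  # Beta lacks evidence: all four strains kept
  expect_setequal(intersect(sel, c("g4", "g5", "g6", "g7")),
                  c("g4", "g5", "g6", "g7"))
  # missing genus: excluded with a warning
  md$genus[4] <- NA
  expect_warning(sel2 <- select_representatives(md), "missing genus")
  expect_false("g4" %in% sel2)
  expect_equal(select_representatives(md[0, ]), character(0))
})
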