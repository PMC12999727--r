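# Hydrogenase classification and the trait rule engine.

test_that("hydrogenase groups map to the uptake list", {
  cat_ <- default_catalog()
  hit <- function(mid) data.frame(genome_id = "g", protein_id = "p1",
                                  marker_id = mid, stringsAsFactors = FALSE)
  h1 <- classify_hydrogenase(hit("hydrogenase:NiFe:1"), cat_)
  expect_equal(h1$group, "1"); expect_true(h1$is_uptake)
  h2 <- classify_hydrogenase(hit("hydrogenase:NiFe:3b"), cat_)
  expect_false(h2$is_uptake)   # 3b is not in the uptake list
  h3 <- classify_hydrogenase(hit("hydrogenase:FeFe:A3"), cat_)
  expect_equal(h3$family, "FeFe"); expect_true(h3$is_uptake)
  h4 <- classify_hydrogenase(hit("hydrogenase:NiFe:4h"), cat_)
  expect_true(h4$is_uptake)
  expect_error(classify_hydrogenase(hit("narG"), cat_), "not a hydrogenase")
})

test_that("worked trait examples follow the published rule set", {
  tp <- function(markers) infer_traits(hits_from_markers(markers), no_hydro,
                                       no_assign, "g")
  # sox set lacking only soxB
  expect_equal(tp(c("soxA", "soxX", "soxY", "soxZ"))$sulfur_oxidation,
               "partial_sox_lacking_soxB")
  expect_equal(tp(c("soxA", "soxB", "soxX", "soxY", "soxZ"))$sulfur_oxidation,
               "complete_sox")
  expect_equal(tp("sqr")$sulfur_oxidation, "sqr_only")
  # narG/narH are paired
  expect_false(tp("narG")$nitrate_reduction)
  expect_true(tp(c("narG", "narH"))$nitrate_reduction)
  # both oxygen classes can be true together
  both <- tp(c("coxA", "coxB", "ccoN", "ccoO"))
  expect_true(both$oxygen_aerobic_lowaff)
  expect_true(both$oxygen_microaerophilic_highaff)
  # photosystem is a conjunction
  expect_false(tp("pufL")$photosystem_ii)
  expect_true(tp(c("pufL", "pufM"))$photosystem_ii)
})

test_that("rule engine matches brute-force evaluation on random marker sets
           and is monotone", {
  core <- c("soxA", "soxB", "soxX", "soxY", "soxZ", "sqr", "coxA", "coxB",
            "ccoN", "ccoO", "cydA", "cydB", "narG", "narH", "pufL", "pufM")
  fields <- c("sulfur_oxidation", "oxygen_aerobic_lowaff",
              "oxygen_microaerophilic_highaff", "nitrate_reduction",
              "photosystem_ii")
  set.seed(601)
  for (k in 1:300) {
    present <- core[runif(length(core)) < 0.5]
    got <- infer_traits(hits_from_markers(present), no_hydro, no_assign, "g")
    want <- brute_traits(present)
    for (f in fields) expect_identical(got[[f]], want[[f]])
    # monotonicity: adding one marker never turns a boolean trait off, and
    # sulfur oxidation only moves toward completeness
    extra <- setdiff(core, present)
    if (length(extra)) {
      got2 <- infer_traits(hits_from_markers(c(present, sample(extra, 1))),
                           no_hydro, no_assign, "g")
      for (f in setdiff(fields, "sulfur_oxidation"))
        expect_gte(got2[[f]], got[[f]])
      rank <- c(none = 0, sqr_only = 1, partial_sox_lacking_soxB = 2,
                complete_sox = 3)
      # sqr_only is a fallback state, so compare within the sox ladder only
      if (got$sulfur_oxidation != "sqr_only")
        expect_gte(rank[got2$sulfur_oxidation], rank[got$sulfur_oxidation])
    }
  }
})

test_that("growth modes are the donor x acceptor cross-product, gated on
           eligibility", {
  mkprofile <- function(markers, uptake = FALSE) {
    hydro <- if (uptake)
      data.frame(protein_id = "ph", family = "NiFe", group = "1",
                 is_uptake = TRUE, stringsAsFactors = FALSE) else no_hydro
    infer_traits(hits_from_markers(markers), hydro, no_assign, "g")
  }
  ok <- data.frame(genome_id = "g", rubisco_copies_considered = 1L,
                   excluded_form_iv = 0L,
                   excluded_prk_lacking_form_iii = 0L, eligible = TRUE,
                   stringsAsFactors = FALSE)
  no <- ok; no$eligible <- FALSE
  pr <- mkprofile(c("narG", "narH", "coxA", "coxB"), uptake = TRUE)
  modes <- predict_growth_modes(pr, ok)
  expect_setequal(paste(modes$donor, modes$acceptor),
                  c("H2 O2_aerobic", "H2 nitrate"))
  # ineligible genome: no predictions at all
  expect_equal(nrow(predict_growth_modes(pr, no)), 0L)
  # phototroph without donors: flagged with the redox-balance caveat
  pr2 <- mkprofile(c("pufL", "pufM"))
  m2 <- predict_growth_modes(pr2, ok)
  expect_equal(m2$mode, "photoautotrophy")
  expect_match(m2$note, "CBB-not-necessarily-autotrophic")
  expect_match(m2$note, "redox")
  # sulfur donor from any oxidation state, sulfur acceptor from dsrAB
  pr3 <- mkprofile(c("sqr", "dsrA", "dsrB"))
  m3 <- predict_growth_modes(pr3, ok)
  expect_equal(paste(m3$donor, m3$acceptor), "sulfur_species sulfur_species")
})
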