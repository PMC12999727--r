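# Evidence joining, the taxon-level count matrix, and environment breakdowns.

mk_profiles <- function(n, prefix = "g") {
  data.frame(genome_id = paste0(prefix, seq_len(n)),
             h2_uptake = FALSE, sulfur_oxidation = "none",
             oxygen_aerobic_lowaff = FALSE,
             oxygen_microaerophilic_highaff = FALSE,
             nitrate_reduction = FALSE, sulfur_reduction = FALSE,
             photosystem_ii = FALSE, forms_present = "",
             stringsAsFactors = FALSE)
}

mk_metadata <- function(ids, genus = "Genus", evidence = "untested",
                        environment = "unknown") {
  data.frame(genome_id = ids, phylum = "Phy", order = "Ord", genus = genus,
             evidence = evidence, environment = environment,
             stringsAsFactors = FALSE)
}

test_that("join_evidence annotates, warns on gaps, and propagates genus
           evidence", {
  pr <- mk_profiles(3)
  md <- mk_metadata(pr$genome_id,
                    evidence = c("demonstrated", "untested", "untested"),
                    genus = c("A", "A", "B"))
  rec <- join_evidence(pr, md)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$genus_evidence, c(TRUE, TRUE, FALSE))
  # profile lacking metadata
  expect_warning(rec2 <- join_evidence(mk_profiles(2), md[1, ]),
                 "lack metadata")
  expect_equal(rec2$evidence[2], "untested")
  expect_equal(rec2$environment[2], "unknown")
  # duplicate metadata rows are a hard error
  expect_error(join_evidence(pr, rbind(md, md[1, ])), "duplicate")
})

test_that("summary tables conserve columns and survive a write/read
           round-trip", {
  tab <- published_strain_counts()
  rec <- expand_counts_to_records(tab)
  out <- summarize_strains(rec)          # asserts conservation internally
  expect_s3_class(out, "summary_table")
  # single record and empty input degenerate cases
  one <- rec[1, , drop = FALSE]
  t1 <- summarize_strains(one)
  expect_equal(t1$total[t1$level == "grand_total"], 1L)
  t0 <- summarize_strains(rec[0, , drop = FALSE])
  expect_equal(t0$total[t0$level == "grand_total"], 0L)
  # round-trip: cell-for-cell identical after TSV write/read
  f <- tempfile(fileext = ".tsv")
  write_summary_table(out, f)
  back <- read_summary_table(f)
  expect_equal(as.data.frame(back), as.data.frame(out))
  # a corrupted total violates conservation
  bad <- out
  bad$total[bad$level == "grand_total"] <- bad$total[bad$level ==
                                                       "grand_total"] + 1L
  expect_error(check_conservation(bad), "conservation")
})

test_that("summarize_strains is invariant to record order and respects the
           evidence scope", {
  tab <- published_strain_counts()
  rec <- expand_counts_to_records(tab)
  set.seed(701)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(as.data.frame(summarize_strains(shuf)),
               as.data.frame(summarize_strains(rec)))
  # demonstrated-genus strains drop out of the default scope
  rec2 <- rec
  rec2$genus_evidence[rec2$order == "Thermales"] <- TRUE
  out2 <- summarize_strains(rec2)
  expect_false("Thermales" %in% out2$taxon)
  expect_equal(out2$total[out2$level == "grand_total"],
               sum(!rec2$genus_evidence))
})

test_that("environment breakdowns count categories within a form stratum", {
  pr <- mk_profiles(6)
  pr$forms_present <- c("IA", "IA", "IA;IC", "IC", "", "IA")
  md <- mk_metadata(pr$genome_id,
                    environment = c("marine", "terrestrial",
                                    "rhizosphere_plant", "marine",
                                    "engineered", "organism_hosted"))
  rec <- join_evidence(pr, md)
  ia <- summarize_environments(rec, form = "IA")
  expect_equal(ia$total, 4L)
  expect_equal(ia$marine, 1L)
  expect_equal(ia$terrestrial_incl_rhizosphere, 2L)  # terrestrial + rhizo
  expect_equal(ia$organism_hosted, 1L)
  # empty stratum: all zeros
  ie <- summarize_environments(rec, form = "IE")
  env_cats <- c("marine", "terrestrial", "rhizosphere_plant", "engineered",
                "organism_hosted", "food", "unknown")
  expect_equal(ie$total, 0L)
  expect_true(all(ie[env_cats] == 0L))
  # single-category degenerate case
  md2 <- mk_metadata(pr$genome_id, environment = "marine")
  rec2 <- join_evidence(pr, md2)
  all_m <- summarize_environments(rec2)
  expect_equal(all_m$marine, 6L)
  expect_equal(all_m$total, 6L)
})
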