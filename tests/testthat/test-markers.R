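# Marker search: exact self-hits, threshold behaviour, determinism and
# permutation invariance, plus the imported-annotation path.

make_genome <- function(seqs, id = "g1") {
  genome_record(id, data.frame(protein_id = names(seqs),
                               sequence = unname(seqs),
                               stringsAsFactors = FALSE))
}

test_that("a protein identical to a seed hits that marker at identity 1", {
  cat_ <- default_catalog()
  seed <- cat_$markers[["K01601"]]$seeds[[1]]
  g <- make_genome(c(p1 = unname(seed)))
  hits <- search_markers(g, cat_)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$marker_id, "K01601")
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
})

test_that("unrelated proteins produce no hits", {
  set.seed(201)
  cat_ <- default_catalog()
  g <- make_genome(c(p1 = random_protein(250), p2 = random_protein(180)))
  expect_equal(nrow(search_markers(g, cat_)), 0L)
})

test_that("a ~60% mutant of a seed is still assigned at min_identity 0.40", {
  set.seed(202)
  cat_ <- default_catalog()
  seed <- unname(cat_$markers[["K00927"]]$seeds[[1]])
  mut <- substitute_fraction(seed, 0.40)
  # confirm the construction with the independent aligner
  expect_equal(nw_oracle(mut, seed)$identity, 0.60, tolerance = 0.02)
  hits <- search_markers(make_genome(c(p1 = mut)), cat_)
  expect_equal(hits$marker_id, "K00927")
  expect_gte(hits$identity, 0.40)
  # and the reported identity agrees with the oracle on the best seed
  best <- cat_$markers[["K00927"]]$seeds[[hits$best_seed_label]]
  expect_equal(hits$identity, nw_oracle(mut, unname(best))$identity,
               tolerance = 1e-9)
})

test_that("search is invariant to protein order and skips bad sequences", {
  set.seed(203)
  cat_ <- default_catalog()
  seqs <- c(p1 = unname(cat_$markers[["narG"]]$seeds[[1]]),
            p2 = unname(cat_$markers[["pufL"]]$seeds[[2]]),
            p3 = random_protein(150))
  h1 <- search_markers(make_genome(seqs), cat_)
  h2 <- search_markers(make_genome(rev(seqs)), cat_)
  expect_equal(h1[order(h1$protein_id), ], h2[order(h2$protein_id), ],
               ignore_attr = TRUE)
  expect_setequal(h1$marker_id, c("narG", "pufL"))
  # illegal characters: warn and continue with the rest
  bad <- c(p1 = "MKL-ZZ??", p2 = unname(cat_$markers[["sqr"]]$seeds[[1]]))
  expect_warning(h3 <- search_markers(make_genome(bad), cat_), "illegal")
  expect_equal(h3$marker_id, "sqr")
})

test_that("imported annotation tables are parsed, vetted and sentinelled", {
  cat_ <- default_catalog()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tprotein_id\tmarker_id",
               "g1\tp1\tK00855", "g1\tp2\tK01601", "g2\tp9\tsoxB"), f)
  hits <- read_annotation_table(f, cat_)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$identity == 1.0))
  expect_true(all(hits$provenance == "imported"))
  # unknown marker: warn + drop by default, hard error on request
  writeLines(c("genome_id\tprotein_id\tmarker_id",
               "g1\tp1\tK00855", "g1\tp2\tK99999"), f)
  expect_warning(h2 <- read_annotation_table(f, cat_), "K99999")
  expect_equal(h2$marker_id, "K00855")
  expect_error(read_annotation_table(f, cat_, on_unknown = "error"),
               "K99999")
  # header-only file -> empty hit list
  writeLines("genome_id\tprotein_id\tmarker_id", f)
  expect_equal(nrow(read_annotation_table(f, cat_)), 0L)
})
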