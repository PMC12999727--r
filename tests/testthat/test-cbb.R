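# CBB completeness logic and the eligibility exclusions.

test_that("worked completeness examples behave as specified", {
  h <- hits_from_markers(c("K00855", "K01601", "K00927", "K00134"))
  st <- evaluate_cbb(h, "g")
  expect_true(st$complete)
  expect_true(st$step4_gap)
  # missing PRK
  st2 <- evaluate_cbb(hits_from_markers(c("K01601", "K00927", "K05298")),
                      "g")
  expect_false(st2$step1_prk)
  expect_false(st2$complete)
  # no hits at all: a valid (all-false) state
  st3 <- evaluate_cbb(hits_from_markers(character(0)), "g")
  expect_false(any(unlist(st3[, c("step1_prk", "step2_rbcl", "step3_pgk",
                                  "step4_gap", "complete")])))
})

test_that("completeness equals brute-force boolean evaluation over all 2^6
           marker combinations and is monotone", {
  mk <- c("K00855", "K01601", "K00927", "K05298", "K00150", "K00134")
  for (m in 0:63) {
    present <- mk[bitwAnd(m, 2^(0:5)) > 0]
    st <- evaluate_cbb(hits_from_markers(present), "g")
    expect_identical(st$complete, brute_cbb_complete(present))
    # monotonicity: adding any one absent marker never turns complete off
    if (st$complete) next
    for (extra in setdiff(mk, present)) {
      st2 <- evaluate_cbb(hits_from_markers(c(present, extra)), "g")
      expect_gte(st2$complete, st$complete)
    }
  }
})

test_that("evaluate_cbb is idempotent and order-invariant over hits", {
  h <- hits_from_markers(c("K00134", "K00855", "K01601", "K00927"))
  st <- evaluate_cbb(h, "g")
  expect_identical(st, evaluate_cbb(h[rev(seq_len(nrow(h))), ], "g"))
  expect_identical(st, evaluate_cbb(rbind(h, h), "g"))
})

test_that("form IV and archaeal PRK-lacking form III copies never count", {
  complete <- evaluate_cbb(
    hits_from_markers(c("K00855", "K01601", "K00927", "K00134")), "g")
  no_prk <- evaluate_cbb(
    hits_from_markers(c("K01601", "K00927", "K00134")), "g")
  asn <- function(forms) data.frame(genome_id = rep("g", length(forms)),
                                    form = forms, stringsAsFactors = FALSE)
  # archaeon, one form III copy, PRK absent -> excluded, not eligible
  v <- evaluate_eligibility(no_prk, asn("III"), domain = "archaea")
  expect_false(v$eligible)
  expect_equal(v$excluded_prk_lacking_form_iii, 1L)
  # same configuration with PRK present: the copy counts
  v2 <- evaluate_eligibility(complete, asn("III"), domain = "archaea")
  expect_true(v2$eligible)
  expect_equal(v2$excluded_prk_lacking_form_iii, 0L)
  # bacterium with form III and a full CBB set is eligible
  v3 <- evaluate_eligibility(complete, asn("III"), domain = "bacteria")
  expect_true(v3$eligible)
  # a lone form IV copy is always excluded
  v4 <- evaluate_eligibility(complete, asn("IV"), domain = "bacteria")
  expect_false(v4$eligible)
  expect_equal(v4$excluded_form_iv, 1L)
  # multi-copy: one counted copy suffices
  v5 <- evaluate_eligibility(complete, asn(c("IV", "IC")),
                             domain = "bacteria")
  expect_true(v5$eligible)
  expect_equal(v5$rubisco_copies_considered, 2L)
})
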