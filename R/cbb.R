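# CBB-cycle completeness and eligibility rules. A genome is a CBB candidate
# when all four module steps are detected: PRK (K00855), RbcL (K01601), PGK
# (K00927), and any of the three GAPDH alternatives (K05298 / K00150 /
# K00134). Form IV RubisCO copies (RubisCO-like proteins) and archaeal
# PRK-lacking form III copies are never counted as CO2-fixing.

#' Evaluate CBB-cycle completeness for one genome
#'
#' @param hits marker hits data.frame (all rows must belong to `genome_id`).
#' @param genome_id genome identifier.
#' @return one-row data.frame: `genome_id`, `step1_prk`, `step2_rbcl`,
#'   `step3_pgk`, `step4_gap`, `complete`.
#' @export
evaluate_cbb <- function(hits, genome_id) {
  if (nrow(hits) && !all(hits$genome_id == genome_id))
    stop("hits contain rows for other genomes than ", genome_id)
  present <- unique(hits$marker_id)
  s1 <- "K00855" %in% present
  s2 <- "K01601" %in% present
  s3 <- "K00927" %in% present
  s4 <- any(GAP_ALTERNATIVES %in% present)
  data.frame(genome_id = genome_id, step1_prk = s1, step2_rbcl = s2,
             step3_pgk = s3, step4_gap = s4,
             complete = s1 && s2 && s3 && s4,
             stringsAsFactors = FALSE)
}

#' Evaluate whether a genome's RubisCO configuration is CO2-fixing eligible
#'
#' Applies the exclusion rules on top of CBB completeness: form IV copies
#' never count; form III copies in archaeal genomes count only when PRK is
#' present (PRK-lacking archaeal form III marks the pentose bisphosphate
#' pathway, not the CBB cycle). A genome is eligible when at least one copy
#' survives both exclusions and the CBB module is complete.
#'
#' @param status one-row data.frame from [evaluate_cbb()].
#' @param assignments RbcL assignments data.frame (column `form`), all for
#'   the same genome.
#' @param domain `"bacteria"` or `"archaea"`. Unknown taxonomy should be
#'   passed as `"bacteria"` (the archaeal exclusion is applied only on
#'   positive evidence of Archaea); see [domain_of()].
#' @return one-row data.frame: `genome_id`, `rubisco_copies_considered`,
#'   `excluded_form_iv`, `excluded_prk_lacking_form_iii`, `eligible`.
#' @export
evaluate_eligibility <- function(status, assignments,
                                 domain = c("bacteria", "archaea")) {
  domain <- match.arg(domain)
  stopifnot(nrow(status) == 1L)
  if (nrow(assignments) &&
      !is.null(assignments$genome_id) &&
      !all(assignments$genome_id == status$genome_id))
    stop("assignments contain rows for other genomes")
  forms <- if (nrow(assignments)) assignments$form else character(0)
  n_iv <- sum(forms == "IV")
  n_iii_excl <- if (domain == "archaea" && !status$step1_prk)
    sum(forms == "III") else 0L
  counted <- length(forms) - n_iv - n_iii_excl
  data.frame(genome_id = status$genome_id,
             rubisco_copies_considered = length(forms),
             excluded_form_iv = n_iv,
             excluded_prk_lacking_form_iii = n_iii_excl,
             eligible = counted >= 1L && status$complete,
             stringsAsFactors = FALSE)
}

#' Domain (bacteria/archaea) from a genome's taxonomy
#'
#' Falls back to `"bacteria"` with a message when the domain is not recorded:
#' the archaeal form III exclusion is applied conservatively, only on
#' positive evidence of Archaea.
#'
#' @param genome a `genome_record`.
#' @return `"bacteria"` or `"archaea"`.
#' @export
domain_of <- function(genome) {
  d <- tolower(genome$taxonomy$domain %||% NA_character_)
  if (is.na(d)) {
    message("genome ", genome$genome_id,
            ": domain unknown, treating as bacteria")
    return("bacteria")
  }
  if (d %in% c("archaea", "archaeon")) "archaea" else "bacteria"
}
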