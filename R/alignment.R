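# Pairwise global alignment core. All identity/coverage numbers in the
# package funnel through here so every stage uses one definition:
#   identity = matches / alignment columns (dual-gap columns excluded)
#   coverage = fraction of the *seed* (subject) residues aligned to a residue
# 'X' is a valid residue but never counts as a match.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

.pkg_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_env$BLOSUM62
}

#' Check a protein sequence against the amino-acid alphabet
#'
#' Valid sequences are non-empty, uppercase strings over the 20 standard
#' residues plus `X` (unknown), with no gap characters.
#'
#' @param seq character scalar.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_protein <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) < 1L)
    return(FALSE)
  !grepl(paste0("[^", paste(c(AA_ALPHABET, "X"), collapse = ""), "]"), seq)
}

.id_cov_from_aligned <- function(p, s) {
  # p, s: equal-length character strings with '-' gaps (pattern = query,
  # subject = seed). Pairwise global alignments contain no dual-gap columns,
  # but exclude them anyway so the same rule applies to MSA rows.
  pv <- strsplit(p, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- !(pv == "-" & sv == "-")
  pv <- pv[keep]; sv <- sv[keep]
  ncols <- length(pv)
  matches <- sum(pv == sv & pv != "-" & pv != "X")
  aligned_seed <- sum(sv != "-" & pv != "-")
  seed_len <- sum(sv != "-")
  c(identity = if (ncols) matches / ncols else 0,
    coverage = if (seed_len) aligned_seed / seed_len else 0)
}

#' Align one query protein against a set of seed sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap opening 11 and gap
#' extension 1 (the conventional protein-search scoring).
#'
#' @param query character scalar, the protein sequence.
#' @param seeds named character vector of seed sequences.
#' @return data.frame with one row per seed: `label`, `score`, `identity`,
#'   `coverage`.
#' @export
align_to_seeds <- function(query, seeds) {
  stopifnot(is_valid_protein(query), length(seeds) >= 1L,
            !is.null(names(seeds)))
  subj <- Biostrings::AAString(query)
  pat <- Biostrings::AAStringSet(unname(seeds))
  aln <- Biostrings::pairwiseAlignment(
    pat, subj, substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = "global")
  pstr <- as.character(Biostrings::pattern(aln))   # seeds, aligned
  sstr <- as.character(Biostrings::subject(aln))   # query, aligned
  idcov <- t(vapply(seq_along(seeds),
                    function(i) .id_cov_from_aligned(sstr[i], pstr[i]),
                    c(identity = 0, coverage = 0)))
  data.frame(label = names(seeds),
             score = Biostrings::score(aln),
             identity = idcov[, "identity"],
             coverage = idcov[, "coverage"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global-alignment identity between two protein sequences
#'
#' @param a,b character scalars.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  res <- align_to_seeds(a, c(seed = b))
  res$identity[1]
}

## ---- center-star multiple alignment ----------------------------------------

.pairwise_aligned_strings <- function(query, center) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(center),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  list(q = strsplit(as.character(Biostrings::pattern(aln)), "")[[1]],
       c = strsplit(as.character(Biostrings::subject(aln)), "")[[1]])
}

#' Multiple sequence alignment by the center-star method
#'
#' Picks the sequence with the highest summed pairwise identity to the others
#' as the center (ties broken by lexicographically smallest name), aligns
#' every other sequence to it pairwise, and merges the pairwise alignments on
#' the center's coordinates ("once a gap, always a gap"). Adequate for the
#' closely related gene families handled here; not a substitute for iterative
#' refinement aligners on distant or heavily indeled sets.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @return named character vector of equal-length aligned rows.
#' @export
align_center_star <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)),
            length(seqs) >= 2L)
  ids <- names(seqs)
  n <- length(seqs)
  if (n == 2L) {
    pa <- .pairwise_aligned_strings(seqs[[2]], seqs[[1]])
    out <- c(paste(pa$c, collapse = ""), paste(pa$q, collapse = ""))
    return(stats::setNames(out, ids))
  }
  total_id <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pid <- pairwise_identity(seqs[[i]], seqs[[j]])
    total_id[i] <- total_id[i] + pid
    total_id[j] <- total_id[j] + pid
  }
  center <- order(-total_id, ids)[1]
  cseq <- seqs[[center]]
  clen <- nchar(cseq)
  others <- setdiff(seq_len(n), center)
  pals <- lapply(others, function(i) .pairwise_aligned_strings(seqs[[i]], cseq))
  # per pair: insertions relative to the center at slots 0..clen (before
  # center residue k+1)
  ins_of <- function(pa) {
    slots <- integer(clen + 1L)
    pos <- 0L
    for (k in seq_along(pa$c)) {
      if (pa$c[k] == "-") slots[pos + 1L] <- slots[pos + 1L] + 1L
      else pos <- pos + 1L
    }
    slots
  }
  ins <- lapply(pals, ins_of)
  maxins <- Reduce(pmax, ins)
  expand_center <- function() {
    v <- strsplit(cseq, "")[[1]]
    out <- character(0)
    for (p in 0:clen) {
      out <- c(out, rep("-", maxins[p + 1L]))
      if (p < clen) out <- c(out, v[p + 1L])
    }
    paste(out, collapse = "")
  }
  expand_other <- function(pa, slots) {
    out <- character(0)
    k <- 1L
    for (p in 0:clen) {
      pad <- maxins[p + 1L] - slots[p + 1L]
      chunk <- character(0)
      while (k <= length(pa$c) && pa$c[k] == "-") {
        chunk <- c(chunk, pa$q[k]); k <- k + 1L
      }
      out <- c(out, chunk, rep("-", pad))
      if (p < clen) { out <- c(out, pa$q[k]); k <- k + 1L }
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  rows[center] <- expand_center()
  for (j in seq_along(others))
    rows[others[j]] <- expand_other(pals[[j]], ins[[j]])
  stopifnot(length(unique(nchar(rows))) == 1L)
  stats::setNames(rows, ids)
}

#' Pairwise identity matrix from aligned rows
#'
#' Computes, for every pair of rows of an alignment, the match fraction over
#' columns where at least one of the two rows has a residue (pair-specific
#' dual-gap columns are excluded); `X` never matches.
#'
#' @param rows named character vector of equal-length aligned rows.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
alignment_identity_matrix <- function(rows) {
  n <- length(rows)
  m <- matrix(1, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <-
      .id_cov_from_aligned(rows[[i]], rows[[j]])[["identity"]]
  }
  m
}
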