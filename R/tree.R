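# Neighbor-joining distance tree over RbcL sequences: the desk-scale
# grouping view (distances from the trimmed mutual alignment). For
# publication-grade phylogenetics export the trimmed alignment with
# write_alignment_fasta() and run a maximum-likelihood tool.

#' Build a neighbor-joining tree from sequences
#'
#' Queries (and optionally panel references) are aligned together by
#' center-star MSA, columns are trimmed at `gap_threshold`, pairwise
#' distances are 1 - identity on the trimmed rows, and the tree is built by
#' standard neighbor joining (`ape::nj`; the 3-taxon case uses the
#' closed-form star resolution). Negative NJ branch-length estimates are
#' clamped to zero with a message.
#'
#' @param seqs named character vector of query sequences.
#' @param panel optional `reference_panel` whose entries are added as leaves
#'   (prefixed ids must not clash with query names).
#' @param gap_threshold column trim threshold (default 0.8).
#' @return an unrooted `ape::phylo` tree with leaf set equal to the input
#'   ids.
#' @export
build_nj_tree <- function(seqs, panel = NULL, gap_threshold = 0.8) {
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "reference_panel"))
    seqs <- c(seqs, stats::setNames(panel$sequence, panel$ref_id))
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  if (length(seqs) < 3L) stop("need at least 3 sequences for a tree")
  rows <- align_center_star(seqs)
  tr <- trim_alignment(rows, gap_threshold)
  d <- 1 - alignment_identity_matrix(tr$rows)
  nj_tree(d)
}

#' Neighbor joining from a distance matrix
#'
#' @param d symmetric numeric distance matrix with dimnames.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (n == 3L) {
    # closed-form three-taxon star: v_i = (d_ij + d_ik - d_jk) / 2
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tree <- list(edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L),
                               ncol = 2, byrow = TRUE),
                 edge.length = v, tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
  } else {
    tree <- ape::nj(stats::as.dist(d))
  }
  if (any(tree$edge.length < 0)) {
    message("clamping ", sum(tree$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
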