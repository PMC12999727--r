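# Greedy incremental identity clustering (the classic longest-first scheme
# used to pick representative sequences before tree building).

#' Cluster sequences greedily at an identity threshold
#'
#' Sequences are processed longest first (ties broken by lexicographically
#' smallest id). Each sequence joins the first existing cluster (in cluster
#' creation order) whose representative it matches at global identity >=
#' `threshold`; otherwise it founds a new cluster and becomes its
#' representative. Deterministic given the input set.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param threshold identity threshold in (0, 1]; default 0.80.
#' @return a `cluster_set`: list with `threshold` and `clusters`, each
#'   cluster a list of `representative_id` and `member_ids` (representative
#'   included).
#' @export
cluster_sequences <- function(seqs, threshold = 0.80) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)),
            threshold > 0, threshold <= 1)
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  reps <- character(0)
  members <- list()
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(seqs[[id]], seqs[[reps[k]]]) >= threshold) {
        members[[k]] <- c(members[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  structure(list(threshold = threshold,
                 clusters = Map(function(r, m)
                   list(representative_id = r, member_ids = m),
                   reps, members)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters at threshold",
      x$threshold, "\n")
  invisible(x)
}

#' Cluster membership as a data.frame
#'
#' @param x a `cluster_set`.
#' @return data.frame with `member_id`, `representative_id`.
#' @export
cluster_members <- function(x) {
  do.call(rbind, lapply(x$clusters, function(cl)
    data.frame(member_id = cl$member_ids,
               representative_id = cl$representative_id,
               stringsAsFactors = FALSE)))
}
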