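# Marker catalog: definitions of every marker gene the screen looks for,
# each with >=2 seed sequences and identity/coverage thresholds.

MARKER_CATEGORIES <- c("cbb", "hydrogenase", "oxidase", "sulfur_ox",
                       "sulfur_red", "nitrate_red", "photosystem",
                       "rubisco_small")

# markers the screen cannot run without: the four CBB module steps (with the
# three GAPDH alternatives), the small subunit, electron-donor/acceptor
# markers, and the photosystem pair
MANDATORY_MARKERS <- c(
  "K00855", "K01601", "K00927", "K05298", "K00150", "K00134", "rbcS",
  "soxA", "soxB", "soxX", "soxY", "soxZ", "sqr", "narG", "narH",
  "coxA", "coxB", "cyoA", "cyoB", "cyoC", "cyoD",
  "ccoN", "ccoO", "cydA", "cydB", "pufL", "pufM", "dsrA", "dsrB",
  paste0("hydrogenase:NiFe:", c("1","2a","2b","2c","2d","2e","4h","4i")),
  paste0("hydrogenase:FeFe:", c("A2","A3")))

GAP_ALTERNATIVES <- c("K05298", "K00150", "K00134")
CBB_STEP_MARKERS <- list(step1_prk = "K00855", step2_rbcl = "K01601",
                         step3_pgk = "K00927", step4_gap = GAP_ALTERNATIVES)

#' Load a marker catalog from YAML
#'
#' The catalog file holds one entry per marker: `marker_id`, `category`,
#' optional `gene` note, `min_identity` / `min_coverage` thresholds in
#' (0, 1], and a non-empty list of labelled `seeds`. The bundled default
#' (`marker_catalog_synthetic.yaml`) carries synthetic seed families; see
#' [default_catalog()].
#'
#' @param path path to a YAML catalog file.
#' @param require_mandatory check that every marker the pipeline's rules
#'   reference is present (default `TRUE`).
#' @return a `marker_catalog` object: list with `markers` (named list of
#'   definitions) and `seed_index` (one row per seed, for fast search).
#' @export
load_catalog <- function(path, require_mandatory = TRUE) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$markers) || length(raw$markers) == 0L)
    stop("catalog is empty: ", path)
  ids <- vapply(raw$markers, `[[`, "", "marker_id")
  if (anyDuplicated(ids))
    stop("duplicate marker_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  markers <- list()
  for (m in raw$markers) {
    stopifnot(is.character(m$marker_id), nzchar(m$marker_id))
    if (!m$category %in% MARKER_CATEGORIES)
      stop("unknown category '", m$category, "' for marker ", m$marker_id)
    for (th in c("min_identity", "min_coverage")) {
      v <- m[[th]]
      if (!is.numeric(v) || v <= 0 || v > 1)
        stop(th, " for marker ", m$marker_id, " must be in (0, 1]")
    }
    if (length(m$seeds) == 0L)
      stop("marker ", m$marker_id, " has no seed sequences")
    labels <- vapply(m$seeds, `[[`, "", "label")
    seqs <- toupper(vapply(m$seeds, `[[`, "", "sequence"))
    if (anyDuplicated(labels))
      stop("duplicate seed labels for marker ", m$marker_id)
    ok <- vapply(seqs, is_valid_protein, logical(1))
    if (!all(ok))
      stop("invalid seed sequence(s) for marker ", m$marker_id, ": ",
           paste(labels[!ok], collapse = ", "))
    markers[[m$marker_id]] <- list(
      marker_id = m$marker_id, category = m$category,
      gene = m$gene %||% NA_character_,
      min_identity = m$min_identity, min_coverage = m$min_coverage,
      seeds = stats::setNames(seqs, labels))
  }
  if (require_mandatory) {
    miss <- setdiff(MANDATORY_MARKERS, names(markers))
    if (length(miss))
      stop("catalog is missing mandatory marker(s): ",
           paste(miss, collapse = ", "))
  }
  idx <- do.call(rbind, lapply(markers, function(m)
    data.frame(marker_id = m$marker_id, category = m$category,
               label = names(m$seeds), sequence = unname(m$seeds),
               min_identity = m$min_identity, min_coverage = m$min_coverage,
               stringsAsFactors = FALSE)))
  rownames(idx) <- NULL
  structure(list(markers = markers, seed_index = idx),
            class = "marker_catalog")
}

#' Bundled default marker catalog (synthetic seeds)
#'
#' @return a `marker_catalog`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "marker_catalog_synthetic.yaml",
                           package = "cbbscan", mustWork = TRUE))
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("marker_catalog:", length(x$markers), "markers,",
      nrow(x$seed_index), "seeds\n")
  print(table(vapply(x$markers, `[[`, "", "category")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
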