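# Independent oracles and fixture builders. Everything here is coded without
# reference to the package's own implementations (identity comes from a plain
# dynamic-programming aligner, rules from direct boolean expressions), so
# agreement tests are genuinely dual-route.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

.blosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# substitute a fraction of positions, never to the same residue
substitute_fraction <- function(seq, frac) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  for (i in idx) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

# Brute-force global affine-gap aligner (Needleman-Wunsch with Gotoh's three
# matrices) returning the aligned strings and the identity as matches over
# alignment columns; 'X' never counts as a match. Gap of length L costs
# open + L * ext, matching the package's scoring convention.
nw_oracle <- function(a, b, open = 11, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  # pointer matrices: which state (1=M, 2=Ix, 3=Iy) each cell came from
  pM <- matrix(0L, n + 1, m + 1)
  pIx <- matrix(0L, n + 1, m + 1)
  pIy <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { Ix[i, 1] <- -open - (i - 1) * ext; pIx[i, 1] <- 2L }
  for (j in 2:(m + 1)) { Iy[1, j] <- -open - (j - 1) * ext; pIy[1, j] <- 3L }
  pIx[2, 1] <- 1L; pIy[1, 2] <- 1L
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- .blosum[av[i - 1], bv[j - 1]]
    prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
    pM[i, j] <- which.max(prev)
    M[i, j] <- prev[pM[i, j]] + s
    if (M[i - 1, j] - open - ext >= Ix[i - 1, j] - ext) {
      Ix[i, j] <- M[i - 1, j] - open - ext; pIx[i, j] <- 1L
    } else { Ix[i, j] <- Ix[i - 1, j] - ext; pIx[i, j] <- 2L }
    if (M[i, j - 1] - open - ext >= Iy[i, j - 1] - ext) {
      Iy[i, j] <- M[i, j - 1] - open - ext; pIy[i, j] <- 1L
    } else { Iy[i, j] <- Iy[i, j - 1] - ext; pIy[i, j] <- 3L }
  }
  i <- n + 1; j <- m + 1
  fin <- c(M[i, j], Ix[i, j], Iy[i, j])
  state <- which.max(fin)
  score <- fin[state]
  ai <- character(0); bi <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ai <- c(av[i - 1], ai); bi <- c(bv[j - 1], bi)
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ai <- c(av[i - 1], ai); bi <- c("-", bi)
      state <- pIx[i, j]; i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1], bi)
      state <- pIy[i, j]; j <- j - 1
    }
  }
  ncols <- length(ai)
  matches <- sum(ai == bi & ai != "-" & ai != "X")
  list(identity = matches / ncols, score = score,
       a = paste(ai, collapse = ""), b = paste(bi, collapse = ""))
}

# Independent greedy clustering: longest-first (ties by id), first-fit
# against representatives in creation order.
brute_cluster <- function(seqs, threshold, identity_fun) {
  ids <- names(seqs)[order(-nchar(seqs), names(seqs))]
  reps <- character(0)
  assign <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (identity_fun(seqs[[id]], seqs[[r]]) >= threshold) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    assign[id] <- hit
  }
  assign
}

# Direct boolean evaluation of the CBB completeness criterion
brute_cbb_complete <- function(present) {
  all(c("K00855", "K01601", "K00927") %in% present) &&
    any(c("K05298", "K00150", "K00134") %in% present)
}

# Direct boolean evaluation of the trait rules over a marker-presence set
brute_traits <- function(present, any_uptake_hydrogenase = FALSE) {
  has <- function(...) all(c(...) %in% present)
  sox4 <- has("soxA", "soxX", "soxY", "soxZ")
  list(
    h2_uptake = any_uptake_hydrogenase,
    sulfur_oxidation =
      if (sox4 && has("soxB")) "complete_sox"
      else if (sox4) "partial_sox_lacking_soxB"
      else if (has("sqr")) "sqr_only" else "none",
    oxygen_aerobic_lowaff =
      (has("coxA") && has("coxB")) ||
      (has("cyoA") && has("cyoB") && has("cyoC") && has("cyoD")),
    oxygen_microaerophilic_highaff =
      (has("ccoN") && has("ccoO")) || (has("cydA") && has("cydB")),
    nitrate_reduction = has("narG") && has("narH"),
    sulfur_reduction = has("dsrA") && has("dsrB"),
    photosystem_ii = has("pufL") && has("pufM"))
}

# hits data.frame from a plain marker-id vector
hits_from_markers <- function(markers, genome_id = "g") {
  if (length(markers) == 0L)
    return(data.frame(genome_id = character(), protein_id = character(),
                      marker_id = character(), stringsAsFactors = FALSE))
  data.frame(genome_id = genome_id,
             protein_id = sprintf("p%02d", seq_along(markers)),
             marker_id = markers, stringsAsFactors = FALSE)
}

no_hydro <- data.frame(protein_id = character(), family = character(),
                       group = character(), is_uptake = logical(),
                       stringsAsFactors = FALSE)
no_assign <- data.frame(genome_id = character(), form = character(),
                        stringsAsFactors = FALSE)

# additive 5-taxon tree ((a:2,b:3):1,(c:4,d:1):2,e:6) and its path-length
# distance matrix, computed by hand
additive_5taxon <- function() {
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  blen <- c(a = 2, b = 3, c = 4, d = 1, e = 6, ab = 1, cd = 2)
  path <- function(x, y) {
    # leaves a,b hang off node AB; c,d off node CD; e off the root joining
    # AB, CD, e
    up <- list(a = c("a", "ab"), b = c("b", "ab"), c = c("c", "cd"),
               d = c("d", "cd"), e = "e")
    sum(blen[setdiff(union(up[[x]], up[[y]]), intersect(up[[x]], up[[y]]))])
  }
  for (x in letters[1:5]) for (y in letters[1:5])
    if (x != y) d[x, y] <- path(x, y)
  d
}

# expected unrooted topology of the additive matrix, as a newick string
additive_5taxon_tree <- function() ape::read.tree(text =
  "((a:2,b:3):1,(c:4,d:1):2,e:6);")

tiny_catalog_path <- function(markers_yaml) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(markers_yaml, f)
  f
}
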