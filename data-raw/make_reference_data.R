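# Builds the bundled SYNTHETIC reference data committed under inst/extdata/:
#   - marker_catalog_synthetic.yaml : seed-sequence catalog for all marker genes
#   - rbcl_panel_synthetic.fasta    : labelled RbcL form reference panel
#
# The seed families are synthetic: real characterized proteins cannot be
# bundled, so each marker gets a private random ancestor and >=2 seeds derived
# from it, and the RbcL panel is a two-level family (root -> form ancestors ->
# per-form references) whose identity structure mimics deep form clades
# (within-form ~85%, between-form ~35% identity). Regenerate with:
#   Rscript data-raw/make_reference_data.R
# Deterministic: fixed seed below.

set.seed(20260117)

AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
# rough background frequencies (Robinson-Robinson style), so sequences do not
# look uniform-random to the substitution matrix
BG <- c(0.079,0.051,0.045,0.054,0.019,0.043,0.063,0.074,0.022,0.051,
        0.091,0.057,0.022,0.039,0.052,0.068,0.059,0.014,0.032,0.066)

rand_seq <- function(n) paste(sample(AA, n, replace = TRUE, prob = BG), collapse = "")

mutate_frac <- function(seq, frac) {
  v <- strsplit(seq, "")[[1]]
  k <- round(frac * length(v))
  idx <- sample(length(v), k)
  for (i in idx) v[i] <- sample(setdiff(AA, v[i]), 1)
  paste(v, collapse = "")
}

## ---- RbcL form panel --------------------------------------------------------
forms <- c("IA","IB","IC","ID","IE","I_THERMUS","I_PRIME","I_DOUBLE_PRIME",
           "I_ALPHA","I_ANAERO","II","III","IV")
RBCL_LEN <- 300
root <- rand_seq(RBCL_LEN)
panel <- list()
for (f in forms) {
  anc <- mutate_frac(root, 0.45)           # ~55% identity to root
  for (i in 1:2) {
    id <- sprintf("%s_ref%d", f, i)
    panel[[id]] <- list(form = f, seq = mutate_frac(anc, 0.08))
  }
}

panel_lines <- unlist(lapply(names(panel), function(id) {
  e <- panel[[id]]
  c(sprintf(">%s form=%s provenance=synthetic_panel_entry", id, e$form), e$seq)
}))
writeLines(panel_lines, "inst/extdata/rbcl_panel_synthetic.fasta")

## ---- marker catalog ---------------------------------------------------------
marker <- function(marker_id, category, gene = NULL, n_seeds = 2, len = NULL) {
  list(marker_id = marker_id, category = category, gene = gene,
       n_seeds = n_seeds, len = if (is.null(len)) sample(240:300, 1) else len)
}

defs <- list(
  marker("K00855", "cbb", "prkB"),
  marker("K00927", "cbb", "pgk"),
  marker("K05298", "cbb", "gapA_GAPA"),
  marker("K00150", "cbb", "gap2_gapB"),
  marker("K00134", "cbb", "gapA_GAPDH"),
  marker("rbcS",   "rubisco_small", "rbcS", len = 120),
  marker("soxA", "sulfur_ox"), marker("soxB", "sulfur_ox"),
  marker("soxX", "sulfur_ox"), marker("soxY", "sulfur_ox"),
  marker("soxZ", "sulfur_ox"), marker("sqr",  "sulfur_ox"),
  marker("dsrA", "sulfur_red"), marker("dsrB", "sulfur_red"),
  marker("narG", "nitrate_red"), marker("narH", "nitrate_red"),
  marker("coxA", "oxidase"), marker("coxB", "oxidase"),
  marker("cyoA", "oxidase"), marker("cyoB", "oxidase"),
  marker("cyoC", "oxidase"), marker("cyoD", "oxidase"),
  marker("ccoN", "oxidase"), marker("ccoO", "oxidase"),
  marker("cydA", "oxidase"), marker("cydB", "oxidase"),
  marker("pufL", "photosystem"), marker("pufM", "photosystem")
)
nife_groups <- c("1","2a","2b","2c","2d","2e","3b","3d","4a","4h","4i")
fefe_groups <- c("A1","A2","A3")
for (g in nife_groups)
  defs <- c(defs, list(marker(paste0("hydrogenase:NiFe:", g), "hydrogenase")))
for (g in fefe_groups)
  defs <- c(defs, list(marker(paste0("hydrogenase:FeFe:", g), "hydrogenase")))

cat_entries <- lapply(defs, function(d) {
  anc <- rand_seq(d$len)
  seeds <- lapply(seq_len(d$n_seeds), function(i) {
    list(label = sprintf("%s_s%d", gsub(":", "_", d$marker_id), i),
         provenance = "synthetic seed family (fixed-seed generator, data-raw)",
         sequence = mutate_frac(anc, 0.10))
  })
  out <- list(marker_id = d$marker_id, category = d$category,
              min_identity = 0.40, min_coverage = 0.70, seeds = seeds)
  if (!is.null(d$gene)) out$gene <- d$gene
  out
})

# K01601 (rbcL) seeds: first panel entry of every form, so any divergent rbcL
# copy is still caught by the generic CBB step-2 marker
rbcl_seeds <- lapply(forms, function(f) {
  id <- sprintf("%s_ref1", f)
  list(label = paste0("K01601_", id),
       provenance = "synthetic panel entry (shared with rbcl_panel_synthetic.fasta)",
       sequence = panel[[id]]$seq)
})
cat_entries <- c(
  list(list(marker_id = "K01601", category = "cbb", gene = "rbcL_cbbL",
            min_identity = 0.40, min_coverage = 0.70, seeds = rbcl_seeds)),
  cat_entries)

yaml::write_yaml(
  list(catalog_name = "cbbscan synthetic default catalog",
       note = paste("Seed sequences are SYNTHETIC stand-ins generated by",
                    "data-raw/make_reference_data.R; replace with curated",
                    "proteins for use on real genomes."),
       markers = cat_entries),
  "inst/extdata/marker_catalog_synthetic.yaml")

cat("panel entries:", length(panel), " catalog markers:", length(cat_entries), "\n")
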