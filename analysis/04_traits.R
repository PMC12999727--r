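#!/usr/bin/env Rscript
# Step 4 - trait inference and growth-mode prediction.
# Applies the marker-presence rules (uptake hydrogenases, sox states,
# terminal-oxidase classes, narGH, dsrAB, pufLM), gates on CBB eligibility
# (form IV / archaeal PRK-lacking form III exclusions) and emits the donor x
# acceptor growth-mode predictions.

suppressPackageStartupMessages(library(cbbscan))

cat_ <- default_catalog()
files <- list.files("results/synthetic", pattern = "\\.faa$",
                    full.names = TRUE)
genomes <- unlist(lapply(files, read_genome_fasta), recursive = FALSE)
hits <- read.delim("results/marker_hits.tsv", stringsAsFactors = FALSE)
cbb <- read.delim("results/cbb_status.tsv", stringsAsFactors = FALSE)
asn <- read.delim("results/rbcl_assignments.tsv", stringsAsFactors = FALSE)
md <- read_strain_metadata("results/synthetic/metadata.tsv")
# FASTA carries no taxonomy; recover each genome's domain from the metadata
for (gid in names(genomes))
  genomes[[gid]]$taxonomy$domain <-
    md$domain[match(gid, md$genome_id)]

profiles <- list(); verdicts <- list(); modes <- list(); evidence <- list()
for (gid in names(genomes)) {
  h <- hits[hits$genome_id == gid, ]
  a <- asn[asn$genome_id == gid, , drop = FALSE]
  hydro <- classify_hydrogenases(h, cat_)
  pr <- infer_traits(h, hydro, a, gid)
  v <- evaluate_eligibility(cbb[cbb$genome_id == gid, ], a,
                            domain = domain_of(genomes[[gid]]))
  profiles[[gid]] <- pr
  verdicts[[gid]] <- v
  modes[[gid]] <- predict_growth_modes(pr, v)
  evidence[[gid]] <- trait_evidence(h, pr)
}
prdf <- profiles_to_df(profiles)
vdf <- do.call(rbind, verdicts)
mdf <- do.call(rbind, modes)

write.table(prdf, "results/trait_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(vdf, "results/eligibility.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mdf, "results/growth_modes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(evidence, "results/trait_evidence.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat("eligible CO2-fixation candidates:", sum(vdf$eligible), "of",
    nrow(vdf), "\n")
cat("growth-mode predictions:", nrow(mdf), "rows;",
    sum(mdf$mode == "photoautotrophy"), "phototrophy calls\n")
cat("H2-uptake genomes:", sum(prdf$h2_uptake), "; nitrate reducers:",
    sum(prdf$nitrate_reduction), "\n")
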