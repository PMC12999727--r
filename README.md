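# cbbscan

Genome-based screening of Calvin–Benson–Bassham (CBB) CO2-fixation
potential in prokaryotes.

Culture collections hold thousands of sequenced strains whose capacity for
autotrophic growth has never been tested. `cbbscan` is for microbiologists
who want to triage such collections from protein FASTA alone: flag genomes
that carry a complete CBB gene module, classify each RubisCO large-subunit
(RbcL) copy into its phylogenetic form, predict plausible electron
donors/acceptors from respiratory marker genes, and aggregate the calls into
the taxon-level and isolation-environment summary tables the field uses.

## What it computes

1. **CBB completeness** — a genome is a candidate CO2 fixer when all four
   module steps are present: PRK (K00855), RbcL (K01601), PGK (K00927) and
   one of the GAPDH alternatives (K05298 / K00150 / K00134). Form IV
   (RubisCO-like) copies and archaeal PRK-lacking form III copies never
   count toward eligibility.
2. **Marker detection** — global-alignment search (BLOSUM62, gap 11/1)
   of every protein against seed sequences, thresholds identity ≥ 0.40 and
   seed coverage ≥ 0.70.
3. **RbcL form calls** — nearest reference in a labelled panel (forms
   IA–IE, Thermus clade, I′, I″, I-α, I-Anaero, II, III, IV), requiring
   identity ≥ 0.45 and an inter-form margin ≥ 0.02; anything less is
   `UNASSIGNED`. Greedy 80%-identity clustering, gap-threshold (0.8)
   alignment trimming and a neighbor-joining tree support the grouping view.
4. **Trait rules** — H2 uptake (NiFe groups 1, 2a–2e, 4h, 4i; FeFe A2/A3),
   sulfur oxidation states (soxABXYZ complete / lacking-soxB / sqr-only),
   low-affinity (coxAB, cyoABCD) vs high-affinity (ccoNO, cydAB) terminal
   oxidases, nitrate reduction (narG+narH), sulfur reduction (dsrA+dsrB),
   photosystem II (pufL+pufM), and the donor × acceptor growth-mode
   cross-product for eligible genomes.
5. **Reporting** — strain-count matrices per (phylum, order) with enforced
   column conservation, and per-form isolation-environment breakdowns.

A synthetic proteome simulator with known ground truth
(`generate_proteomes()`, `recovery_experiment()`) makes the whole chain
benchmarkable offline. **The bundled marker catalog and RbcL panel are
synthetic seed families** (see `data-raw/`); swap in curated sequences via
`load_catalog()` / `read_reference_panel()` for real screens.

## Worked example

```r
library(cbbscan)

# simulate a small cohort with known truth, then screen it
spec <- random_synthetic_spec(n_genomes = 3, rng_seed = 7)
sim  <- generate_proteomes(spec)
scan <- scan_genomes(sim$genomes)

scan$cbb
#>   genome_id step1_prk step2_rbcl step3_pgk step4_gap complete
#> 1    syn001      TRUE      FALSE      TRUE     FALSE    FALSE
#> 2    syn002      TRUE       TRUE     FALSE      TRUE    FALSE
#> 3    syn003     FALSE       TRUE      TRUE      TRUE    FALSE

scan$assignments[, c("genome_id", "protein_id", "form",
                     "identity_to_nearest", "margin")]
#>   genome_id protein_id           form identity_to_nearest    margin
#> 1    syn002 p011_rbcl1 I_DOUBLE_PRIME                0.85 0.5697452
#> 2    syn003 p011_rbcl1             ID                0.85 0.5817881
```

`syn002`'s single RbcL copy sits at 85% identity to an I″ reference with a
margin of 0.57 over every other form — a confident form call — while its
missing PGK gene keeps `complete` (and therefore any growth-mode
prediction) false. Trait columns live in `scan$profiles_df`; growth-mode
predictions, gated on eligibility, in `scan$modes`.

The `analysis/` directory runs the same chain as a five-step workflow
(simulate → annotate → classify forms → infer traits → report), writing its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_annotate.R && \
Rscript analysis/03_classify_forms.R && Rscript analysis/04_traits.R && \
Rscript analysis/05_report.R
```

## Layout

```
R/                  implementation (markers, CBB rules, RbcL phylogeny,
                    trait engine, reporting, simulator)
inst/extdata/       synthetic marker catalog + RbcL panel, transcribed
                    published count table
analysis/           numbered workflow drivers (write to results/)
scripts/acceptance.R  headline-number recomputation
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, rules, parameters, limits)
data-raw/           generators for the bundled reference data
```
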