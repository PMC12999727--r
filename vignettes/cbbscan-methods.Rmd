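---
title: "Methods: genome-based screening of CBB-cycle CO2-fixation potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-based screening of CBB-cycle CO2-fixation potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbbscan)
```

# The screening problem

Most microbial CO2 fixation runs through the Calvin–Benson–Bassham (CBB)
cycle, whose gatekeeper enzyme is RubisCO. Whether a sequenced strain *could*
grow autotrophically is, to first order, a question about gene content: does
the genome encode the CBB module, which phylogenetic form of the RubisCO
large subunit (RbcL) does it carry, and which electron donors and acceptors
do its respiratory and photosynthetic marker genes support? `cbbscan`
implements that screen as a chain of small, testable decisions over protein
FASTA input, with a simulator that generates inputs whose correct answers
are known.

# The decision chain

## CBB completeness

A genome is a CBB candidate when all four module steps are detected:

* step 1 — phosphoribulokinase (PRK, `K00855`),
* step 2 — RubisCO large subunit (`K01601`),
* step 3 — phosphoglycerate kinase (`K00927`),
* step 4 — a glyceraldehyde-3-phosphate dehydrogenase, any of `K05298`,
  `K00150`, `K00134`.

Marker presence anywhere in the genome suffices; the criterion does not
require the four steps to sit in one operon or on distinct genes. This is
deliberately permissive — the screen flags *potential*, and the literature
step downstream decides what has been demonstrated.

Two RubisCO configurations never count toward eligibility even when the
module is complete: form IV copies (RubisCO-like proteins that do not fix
CO2), and form III copies in archaeal genomes lacking PRK, which mark the
pentose bisphosphate pathway rather than a CBB cycle. The archaeal exclusion
is applied only on positive evidence of Archaea in the taxonomy; genomes of
unknown domain are treated as bacteria and the fallback is logged.

## Marker detection

The published screen this package follows used profile-HMM annotation
against curated databases. `cbbscan` instead searches each protein against
bundled *seed sequences* with Needleman–Wunsch global alignment (BLOSUM62,
gap opening 11, extension 1 — conventional protein-search scoring). A marker
is assigned when the best seed reaches `min_identity` 0.40 and
`min_coverage` 0.70 (coverage = fraction of the seed aligned to residues).
These are conventional ortholog-screen values; no numeric thresholds are
inherited from elsewhere. Identity is defined everywhere in the package as
matches over alignment columns (dual-gap columns excluded), with `X` never
counting as a match. Per protein, at most one marker per category is kept;
ties go to the higher score, then the lexicographically smaller seed label,
so results are deterministic and invariant to protein order.

**The bundled catalog and panel are synthetic.** Real characterized
proteins cannot be redistributed with the package, so the default catalog
(`marker_catalog_synthetic.yaml`) and RbcL panel
(`rbcl_panel_synthetic.fasta`) are fixed-seed generated families
(`data-raw/make_reference_data.R`) that reproduce the identity structure the
classifiers rely on: two seeds per marker at roughly 80% mutual identity,
unrelated across markers; RbcL forms as clades at roughly 35% between-form
and 85% within-form identity. Every function accepts a user catalog/panel,
and real screens should supply curated sequences through `load_catalog()`
and `read_reference_panel()`.

## RbcL form classification

Each protein hitting `K01601` is classified by nearest reference against
the labelled panel (13 forms: IA–IE, the Thermus clade, I′, I″, I-α,
I-Anaero, II, III, IV). The call requires

* identity to the nearest reference ≥ `identity_floor` (0.45), and
* a margin ≥ `margin_floor` (0.02) over the best reference of any *other*
  form.

Anything else — including exact inter-form ties and queries under 100
residues — returns `UNASSIGNED`. The floors were chosen once, before any
benchmarking, on the principle that forms are deep clades and an unassigned
copy is strictly preferable to a wrong form; the synthetic benchmarks then
verify that this regime yields no wrong-form calls even at 60% identity.
"III-like" sequences are mapped to label `III`; the package does not carry a
separate enum value for them.

rbcS co-occurrence is evaluated per rbcL copy: *present* means any rbcS hit
in the genome; *colocalized* means an rbcS hit within 5 loci of the copy.
Locus indices are 0-based ordinal positions in annotation order — the
package never sees nucleotide coordinates or strands, so 5 loci is an
operon-scale proximity proxy, not a base-pair distance.

## Clustering, trimming, trees

Representative selection before tree building uses greedy incremental
clustering at 80% global identity: sequences longest-first (ties by id),
each joining the first representative it matches at or above the threshold.
This is the classic greedy-incremental scheme; note that published
clustering tools define identity over their own (local) alignments, whereas
here identity is global — the package documents this choice rather than
emulating any specific tool.

Alignments are built by center-star MSA (center = highest summed pairwise
identity, ties by id) and trimmed by the gap-threshold rule: keep exactly
the columns whose non-gap fraction is ≥ 0.8. The tree over trimmed rows
uses distances `1 − identity` and standard neighbor joining (`ape::nj`;
3-taxon inputs use the closed-form star resolution; negative branch-length
estimates are clamped to zero with a message). This NJ tree is a desk-scale
grouping view: it is **not** a substitute for maximum-likelihood inference
with profile mixture models and bootstrap support. `write_alignment_fasta()`
exports the trimmed alignment for exactly that hand-off.

## Trait rules

All rules are pure marker-presence logic (see `?infer_traits`): uptake
hydrogenases are NiFe groups 1, 2a–2e, 4h, 4i and FeFe groups A2, A3 (the
group is carried by the group-labelled seed that matched); the sox ladder
distinguishes `complete_sox` (soxABXYZ), `partial_sox_lacking_soxB`, and
`sqr_only`; oxygen classes are subunit-complete complexes — low-affinity
"aerobic" = coxA+coxB or cyoABCD, high-affinity "microaerophilic" =
ccoN+ccoO or cydA+cydB (the bd-type oxidase is grouped with the
high-affinity class); nitrate reduction = narG and narH, with no adjacency
requirement; photosystem II = pufL and pufM. Sulfur-species *reduction* has
no main-text marker enumeration in the source material, so the package uses
dsrA+dsrB, overridable through the catalog — an assumption, recorded here.
Ferrous-iron oxidation appears in the field's tables but has no marker gene
set given, and is excluded.

Growth-mode prediction emits the donor × acceptor cross-product (donors: H2,
sulfur species from *any* oxidation state including `sqr_only`; acceptors:
the two oxygen classes, nitrate, sulfur species) only for eligible genomes.
A phototrophy row is added when pufL and pufM are both present, always
flagged `CBB-not-necessarily-autotrophic`: aerobic anoxygenic phototrophs
carry CBB genes that may serve redox balancing rather than autotrophy, and
when no donor is detected the note says so explicitly.

## Reporting

`summarize_strains()` produces the strain-count matrix — rows per (phylum,
order) with phylum totals and a grand total; columns for strain counts, the
six tabulated forms (IA, IB, IC, IE, I_THERMUS, II), donors, acceptors and
photosystem — and *asserts column conservation on every produced table*:
each phylum total must equal its order sums and the grand total the phylum
sums. The bundled transcription of the published table satisfies all of
these identities; published narrative counts that disagree with the table
(a 143 vs 144 strain total; a form IC environment breakdown summing to 96
against a stated 97) are surfaced by this check rather than silently
reconciled. Blank cells in the TSV output render zero counts as empty
strings, matching the published dialect; internally they are zeros.

Environment breakdowns count the closed categories (marine, terrestrial,
rhizosphere/plant, engineered, organism-hosted, food, unknown) within a form
stratum, with derived tallies for terrestrial-including-rhizosphere and
plant-associated strains, since the field reasons with both groupings.
Representative selection (`select_representatives()`) keeps one strain per
genus with demonstrated autotrophic growth — the lexicographically smallest
label among the demonstrated ones — and all strains of genera lacking
evidence.

# The simulator and what the benchmarks mean

`generate_proteomes()` emits, per genome: one mutated gene per true marker,
RbcL copies mutated from the requested forms' references, rbcS at a
controlled locus offset, partial-complex distractors (narG without narH,
pufL without pufM, a non-uptake NiFe-3b hydrogenase) that must not flip any
trait, and residue-shuffled decoys. Substitutions are uniform over the 19
alternative residues with no rate matrix and (by default) no indels, so
realized identity is controlled to ±0.02; an optional indel mode with
geometric lengths exists for robustness checks. Defaults — 30 genomes, 85%
identity, 8 decoys, trait prevalences around 0.3–0.5 — are fixed study
conditions chosen to exercise every rule branch at divergence levels typical
of cross-genus ortholog detection, and are not tuned per run.

Because the mutation model is non-phylogenetic and the references synthetic,
passing benchmarks demonstrate that the *decision logic* is correct and the
thresholds are coherent (no wrong-form calls down to 60% identity, decoys
never hit, leave-one-out CBB flips). They do **not** demonstrate
recall/precision on real proteomes, which depends on the curation quality of
a real catalog and panel, on domain architecture, and on alignment behavior
over true indel patterns. Problem sizes in the shipped analyses — 30-genome
cohorts, 50 mutants per form, 150-decoy batches, 20-sequence clustering
oracles — were chosen as the smallest sets that exercise every branch with
stable rates.

# Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; generation is
  byte-identical per seed, and the session RNG state is restored afterwards.
* Ties: seed assignment by score then label; clustering order by length then
  id; form ties return `UNASSIGNED`; NJ agglomeration follows `ape`'s
  deterministic order.
* Degenerate inputs: empty hit sets are valid (all-false CBB status);
  empty record lists give all-zero tables; all-gap trims and sub-3-taxon
  trees are errors with actionable messages; unknown imported marker ids
  warn-and-drop by default and can be promoted to errors.
* `trim_alignment()` reports kept columns as 1-based indices, the R
  convention.

# Known limitations

* Synthetic references: shipped seeds/panel are stand-ins; real screens
  must supply curated sequences.
* No ML phylogenetics, bootstrap or placement-instability analysis; the NJ
  tree is for orientation only.
* Protein input only: no gene calling, no nucleotide models, no operon
  strand logic.
* The literature-evidence layer is a metadata table the user supplies; the
  package does not mine publications.
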