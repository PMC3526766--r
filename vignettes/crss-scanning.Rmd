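---
title: "Scanning germline VH genes for the 3' cryptic RSS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning germline VH genes for the 3' cryptic RSS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsscan)
```

## The biological question

During V(D)J recombination, RAG-1/RAG-2 cut at recombination signal
sequences (RSSs): a conserved heptamer (consensus CACAGTG), a 12- or 23-nt
spacer, and an A-rich nonamer. VH replacement is a secondary, RAG-mediated
rearrangement in which an upstream germline VH invades an already
rearranged VHDJH exon. It is made possible by a *cryptic* RSS — a
heptamer-like motif with no nonamer — embedded near the 3' end of the VH
coding sequence (the 3'cRSS, canonically `TACTGTG`). The recombination
leaves behind a short stretch of the replaced VH 3' of the cut: the
*footprint*, which often donates charged residues to CDR3.

The motif is not free-standing sequence: it overlaps codons 103–105. The
`GT` of its essential `GTG` core is the last two nucleotides of the `TGT`
codon for the structurally invariant 2nd-CYS (Cys104, IMGT unique
numbering), and the final `G` is the first nucleotide of codon 105 —
usually an alanine `GCN` codon. This package measures, across germline VH
repertoires, (i) how often that anchored heptamer is canonical, GTG-type,
or neither; (ii) the charged amino-acid content of the footprint in three
reading frames against a 14/64 (~22%) random-codon baseline and a DH-gene
comparison; and (iii) how those frequencies distribute over cross-species
clade groups of VH families.

## The procedure

1. **Read and filter** (`read_repertoire`, `filter_functional_allele01`).
   Genes arrive as FASTA plus a sidecar annotation TSV (species, family,
   functionality). Only functional genes enter the denominators, and when
   a gene has several alleles only the `*01` allele is kept. A name with
   no `*` suffix is always kept — the naming conventions of non-IMGT
   species carry no allele information.
2. **Anchor Cys104** (`anchor_from_gapped`, `anchor_heuristic`). With an
   IMGT-gapped V-REGION the anchor is arithmetic: aligned nucleotides
   310–312 are codon 104; counting non-gap nucleotides upstream gives the
   ungapped codon index. Without gapping, a heuristic translates the
   natural frame and takes the 3'-most Cys codon within the final 12
   codons, confident only in a conserved (Y/F)-Y-C FR3-like context. The
   heuristic is the package's stand-in for species that lack IMGT
   numbering, and its calls are flagged as such (`method = "HEURISTIC"`).
3. **Extract and classify the heptamer** (`extract_heptamer`,
   `classify_heptamer`). The heptamer is codons 103–104 plus the first
   nucleotide of codon 105 — nothing else is scanned. `CANONICAL` means
   `TACTGTG` or `CACTGTG`; `GTG_TYPE` means positions 5–7 equal `GTG`
   (the canonical motifs are a sub-case, and summary tables count them in
   both columns, so within a row `n_canonical <= n_gtg` and
   `n_gtg + n_other = N`). CAC/GTG-like motifs elsewhere in the gene are
   deliberately out of scope: the anchored heptamer is the object of
   study, and a whole-gene motif scan would measure something else.
4. **Extract and score the footprint** (`extract_footprint`,
   `translate_frames`, `pool_charge`). The footprint is everything 3' of
   the heptamer, typically 7 nt in tetrapods and 9 nt in teleosts. Frame
   offsets are pinned by the residue counts those lengths must produce
   (1, 2, 2 and 2, 3, 2): frame I continues the V reading frame, so its
   first two footprint nucleotides merely complete codon 105 and are not
   scored (offset 2); frame II starts at offset 0; frame III at offset 1.
   Only codons wholly inside the footprint count. Charged = {D, E, K, R,
   H} (His counted as charged and positive), giving the 14/64 baseline;
   positive-only and negative-only censuses are 10 and 4.
5. **DH comparison** (`dh_best_frame_charged`). For each functional DH
   gene the frame with the highest charged fraction is chosen and the
   per-species value is the mean of those maxima. This is an upper bound
   by construction and is labelled as such.
6. **Grouping** (`load_group_scheme`, `group_frequencies`). Clade groups
   are a declarative (species, family) → group mapping consumed from
   YAML. The published grouping is a printed table; re-running Bayesian
   tree inference is tool invocation, not package content, so the mapping
   is data. A deterministic neighbor-joining guide tree
   (`nj_guide_tree`: pairwise p-distance with pairwise deletion of gap/N
   sites, lexicographic taxon order, classical NJ via ape) is available
   for exploration but never feeds the frequency computation.

## Aggregation choices

Charge frequencies pool residues across genes by default
(`frequency = sum charged / sum residues` within species × frame), because
the in-text ratios this analysis style reports (e.g. 108/115
positive/charged) are residue tallies. Per-gene-mean aggregation
(`aggregation = "mean"`) is available; the two differ whenever footprint
lengths vary between genes. Stop codons translate to `*` and ambiguous
codons to `X`; both stay in denominators as non-charged residues — a
conservative choice (it can only deflate charged frequencies) that is easy
to revisit because scoring is centralized.

Percentages render with one decimal, round-half-up, zero cells as `-`, so
93/107 prints `86.9 (93/107)` and 16/17 prints `94.1 (16/17)`.

## The synthetic repertoire generator

Real repertoires come from curated databases that this package does not
download; instead `generate_repertoire` builds seeded repertoires with the
statistical structure the analysis assumes, plus a truth ledger, so every
stage is testable end to end.

Classes are planted at the *codon* level — scaffold through the codon-102
analog, then codon 103, the Cys104 codon, and codon 105 chosen to realize
the drawn class — so the anchor must be found, not given. Structural
facts follow from the motif's codon decomposition: GTG-core classes force
`TGT` at Cys104 and a G-initial codon 105; an OTHER gene retains `GT` at
heptamer positions 5–6 exactly when Cys104 kept `TGT` (drawn with
`p_cys_TGT`), in which case its codon 105 must *not* start with G. The
scaffold contains no stop and no Cys, ends in Tyr (so the heuristic
anchor's context rule is exercised), and codon-105 candidates exclude
Cys codons, keeping the planted Cys104 the 3'-most Cys through codon 105.

Generator defaults are the package's model of a tetrapod-style functional
repertoire and are fixed once:

* class mix `p_class` with total GTG fraction 0.869 and canonical fraction
  0.645 — the shape of a mouse-sized repertoire's totals row;
* `p_cys_TGT = 0.95`, `p_res105_ala = 0.82` (cf. 88/107 Ala in mouse);
* `footprint_len = 7` (use 9 for teleost-style sets);
* `footprint_base_weights = c(A = .55, C = .05, G = .35, T = .05)`. The
  footprint's first two nucleotides are the tail of codon 105 (forced by
  the heptamer's geometry), so the weights govern positions 3..L. They
  were chosen analytically so that an iid draw yields a frame-I charged
  frequency of about 0.66 — reproducing the A/G-richness and the >60%
  frame-I charge observed across real repertoires.

For calibration experiments, `footprint_charged_codon_p = p` switches the
footprint to being drawn as frame-II codons that are charged with
probability p (uniform over the 14 charged codons, else uniform over the
47 non-stop others); codon 105's tail follows the draw and the realized
residue-105 codon is recorded. This makes pooled frame-II recovery of p an
exact binomial experiment.

What the generator does **not** emulate: phylogenetic correlation between
genes, indel/substitution evolution along a tree, realistic framework
sequence content, or V(D)J rearrangement itself. Passing tests on
synthetic data therefore demonstrate correctness of the *measurement*
machinery under known truth — not that any biological claim holds in a
given real repertoire.

## Numerical and degenerate-input choices

* Coordinates: nucleotide intervals 0-based half-open; codon index c
  covers nucleotides [3c, 3c+3). `cys104_codon_index` is 0-based (103 for
  a gap-free V-REGION).
* Anchoring never reads past bounds; truncated or gap-containing codon
  104, or non-codon-multiple gapping, yields an absent, unconfident
  anchor rather than a guess.
* `INCOMPLETE` heptamer calls are excluded from every percentage
  denominator; empty footprints are legal and contribute zero residues.
* NJ tie-breaks: taxa are sorted lexicographically before agglomeration;
  numerically negative branch lengths are clamped to zero. On additive
  matrices the reconstruction is exact, which is what the tests assert.
* RNG: one seed, drawn through a locally saved-and-restored stream in a
  fixed draw order, so equal seed + config means byte-identical output and
  the caller's RNG state is untouched.

## Problem sizes used in validation

The shipped tests and the acceptance script size their simulations at
10,000 genes for the motif-scan oracle comparison, 107 genes (mouse-shaped
family sizes) for ledger-exactness, 2,000 genes per charged-fraction level
p ∈ {0.2, 0.5, 0.8} for frame-II parameter recovery (3σ binomial bands on
4,000 pooled residues), and 4–6 taxa for NJ exactness. These sizes make
the stochastic checks sharp while keeping a full run comfortably
desk-scale.

## A worked example

```{r example}
cfg <- crss_sim_config(seed = 42, n_families = 3,
                       genes_per_family = c(12, 8, 5), dh_count = 6)
gen <- generate_repertoire(cfg)
res <- run_scan(gen$repertoire)
res$family_summary[, c("family", "canonical", "gtg", "other")]

fp <- run_footprint(gen$repertoire, scan = res)
fp$frame_summary[, c("frame", "n_charged", "n_total", "frequency")]
fp$baseline$pct

identical(res$calls$klass, gen$ledger$klass)
```

## Known limitations

* The heuristic anchor assumes the sequence is in frame from its first
  nucleotide; out-of-frame inputs will anchor wrongly (confidence flags
  mitigate, not solve, this).
* Published repertoire tables cannot be reproduced exactly without the
  original database snapshots; this package reproduces the *procedure*
  and validates it against synthetic ledgers and analytically forced
  quantities.
* The DH best-frame statistic deliberately overestimates DH charge
  contribution; treat it as the upper bound it is labelled as.
* Nonamer/spacer scoring, whole-gene cryptic-motif scans, and RSS
  information-content models are out of scope.
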