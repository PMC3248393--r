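---
title: "Comparing ligand-binding sites by microenvironment alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ligand-binding sites by microenvironment alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketalign)
```

## The model

`pocketalign` treats a ligand-binding pocket as a *bag of
microenvironments*: local spherical regions around residue functional
centers, compared pairwise by physicochemical content with no constraint on
their relative 3D arrangement beyond co-occurrence in the pocket. The
underlying assumption is that molecular recognition is driven by
interactions between ligand fragments and individual microenvironments, and
that flexible ligands can present the same fragments to geometrically
rearranged pockets. The cost of this assumption is that the method cannot
distinguish two pockets containing the same microenvironments in
functionally incompatible arrangements; the benefit is robustness to
conformational change in both pocket and ligand.

The pipeline has five stages, each with an explicit contract:

1. **Pocket extraction.** A pocket is every protein residue with at least
   one atom at distance ≤ 6 Å (closed bound — "within" is read
   inclusively) from any atom of the bound ligand. Ligands are hetero
   residues that are not water, common ions, or crystallization additives,
   with strictly more than 5 heavy atoms; both the exclusion list and the
   threshold are arguments of `select_ligands()`.
2. **Functional centers.** Each residue type maps to one center — the
   centroid of a side-chain functional-group atom set — except tryptophan
   and tyrosine, which contribute a polar center (W1: indole NE1; Y1:
   hydroxyl OH) and an aromatic center (W2/Y2: six-membered-ring
   centroid), for 22 types over 20 residue types. The table is replaceable
   via `read_functional_centers()`; the shipped rules are this package's
   own choices (charged-group centroid for D/E/R/K/H, amide group for N/Q,
   hydroxyl oxygen for S/T, ring centroid for F, side-chain centroid for
   nonpolar residues, CA for glycine) and are deliberately conservative:
   scoring depends on the 22-type scheme, not on the exact atom sets.
3. **Featurization.** 80 properties × 6 shells = 480 cells per
   microenvironment (details below).
4. **Background.** Per-cell standard deviations over a reference
   microenvironment population, plus a normal fit of raw Tc for each of
   the 72 permissible pair types.
5. **Scoring and alignment.** Adjusted Tanimoto → background-normalized
   S(Tc) → single-pass mutual-best matching under a cutoff → summed
   binding-site similarity score and its lower-tail p-value.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| contact cutoff | 6.0 | Å | pocket membership (closed bound) |
| total radius | 7.5 | Å | microenvironment extent |
| shells | 6 × 1.25 | Å | half-open `[k·w, (k+1)·w)` bins |
| properties | 80 | — | pluggable schema, shell-major layout |
| heavy-atom minimum | 5 | atoms | ligand filter (strictly exceeded) |
| similar-property rule | 1 STD | — | cell similarity in Tc |
| nonzero tolerance | 1e-12 | — | a cell is "present" if |value| exceeds it |
| S(Tc) cutoff | −0.3 | — | alignment eligibility |
| minimum Tc samples | 30 | pairs | per pair-type normal fit |
| pair subsample cap | 50 000 | pairs | per pair type, seeded |
| p-value cutoff | 0.01 | — | significance flag in reports |

The defaults are the method's standard operating point; all are exposed as
function arguments (and through `run_config()` for the command layer) so
sensitivity analyses can vary them.

## The property schema

Prior microenvironment-profiling work in this lineage uses a fixed
published catalogue of 80 properties. That catalogue is not
redistributable here, so the package defines its own: element counts (C/N/O/S/P/other), per-residue
and residue-class counts, backbone/side-chain atom roles, hydrogen-bond
donor and acceptor counts, aromatic-ring and formally charged atoms, common
side-chain atom names, summed atomic descriptors (mass, van der Waals
volume, electronegativity, crude partial charge, Kyte–Doolittle
hydrophobicity), B-factor and occupancy statistics, secondary-structure
class counts (zero unless an annotation is supplied — no DSSP-like
dependency is bundled), and residue-size classes — exactly 80, enumerated
by `default_schema()`. The scoring and alignment contract depends only on
the vector geometry (cell count, shell-major order, count/sum/fraction
kinds), so users holding a different catalogue can swap it in with
`read_schema()` provided background and query vectors share one schema.
Vectors produced here are therefore *not* comparable to vectors computed
under any other catalogue.

Hetero atoms are excluded from featurization by default so that vectors
describe the protein environment rather than the bound ligand itself
(`include_hetero = TRUE` overrides).

## Background and normalization

Comparison is restricted to pairs of types in the same physicochemical
group — positive (R H K), negative (D E), polar (S T Q N W1 Y1), nonpolar
(A C G I L M P V), aromatic (W2 Y2 F) — giving
6 + 3 + 21 + 36 + 6 = 72 permissible pair types; cross-group lookups fail
loudly rather than returning a default.

Per-cell STDs use the *population* formula (the reference set is treated
as the population defining "similar"); the per-pair-type normal fits use
the sample mean and SD, which at the intended sample sizes (hundreds to
tens of thousands of pairs) differ negligibly from maximum-likelihood
estimates. Tc₀ is defined as the mode of the fitted density, which for a
normal equals its mean; a cumulative distribution function has no mode, so
this is the only self-consistent reading of "mode of the fitted CDF".
`S(Tc) = ln(SF(Tc)/SF(Tc₀))` then satisfies every stated constraint of the
normalized score: zero at Tc₀, negative and strictly decreasing beyond,
and changing most rapidly in the upper tail. The log base is configurable
(`base` argument); the default is the natural log.

Structure-level reference-set filters (X-ray resolution better than 2.0 Å,
pairwise sequence identity below 40 %) are manifest responsibilities: the
pockets handed to `build_background()` are taken as the reference set, and
the package does not recompute sequence identity or parse PDB-wide
metadata.

## Numerical choices

- **Shell binning** is half-open with an exclusive outer boundary: an atom
  at exactly 7.5 Å does not contribute. This makes binning unambiguous.
- **Nonzero cells** are those with magnitude above 1e-12, so sums that
  cancel to rounding noise do not count as present.
- **Zero-STD cells** (constant across the reference set) require exact
  equality to count as similar; the one-STD rule would otherwise make them
  trivially dissimilar or undefined.
- **Similar-property count c** is restricted to cells nonzero in *both*
  vectors. This is the only reading of presence/absence similarity that
  guarantees c ≤ min(a, b) and hence Tc ≤ 1 with the a + b − c
  denominator.
- **Tie-breaking** in mutual-best matching orders candidates by S
  ascending, then raw Tc descending, then lexicographic partner name, so
  alignments are deterministic. Matching is single-pass (the strict
  mutual-best definition); a greedy iterative variant is deliberately not
  the default as it can chain matches that are not mutually best.
- **Survival-function ratio saturation.** S is computed on the log scale
  (`pnorm(..., log.p = TRUE)`), which is accurate in both tails, so the
  upper tail never underflows to −Inf for realistic backgrounds. In the
  deep *lower* tail S approaches its supremum ln 2, and the true decrement
  per grid step (∝ exp(−z²/2)) falls below the resolution of the final
  double-precision subtraction; S is then numerically flat although
  mathematically strictly decreasing. Tests assert strict decrease
  wherever the decrement is representable (always the case at and above
  the mode, where alignment decisions happen) and non-strict monotonicity
  globally.
- **Altlocs** keep the highest-occupancy conformer (ties prefer blank then
  'A'); multi-MODEL files keep the first model. Degenerate inputs error
  early: empty vectors in Tc, too few samples or zero variance in fits,
  infeasible hypergeometric arguments.

## Evaluation machinery

AUC is the Mann–Whitney rank statistic — the probability that a random
positive pair scores more negatively than a random negative pair, ties
counting one half — which is exactly the area under the ROC curve swept by
thresholding scores. Sensitivity at a specificity level is the best
sensitivity among thresholds achieving at least that specificity.
Ranking-separation significance uses the upper-tail hypergeometric
probability (`stats::phyper`).

Kinase-pair filtering keeps pairs from different EC sub-subgroups (first
four EC fields) with structural-alignment identity ≤ 30 % ("not higher
than 30 %" is read inclusively). An incomplete EC such as `2.7.1.-`
compares unequal to any complete sub-subgroup; two identical incomplete
ECs are conservatively treated as equal and the pair dropped, since their
distinctness cannot be established.

Assay labeling: Ambit-style panel rows qualify a compound on a kinase when
Kd < 1 µM and the off-target/primary ratio is < 100, the primary target
being the compound's minimum-Kd target unless an explicit `primary` column
marks one (panel data do not record the design target). CHEMBL-style rows
first drop confidence < 7 — rows with *missing* confidence are dropped
too, since an unknown confidence cannot pass a ≥ 7 filter — then qualify
on Kd < 1 µM, IC50 < 1 µM, or inhibition > 90 % at 1 µM. Concentrations
are normalized to µM; rows with unparseable units are rejected with a
warning. Staurosporine, a notoriously non-selective inhibitor, is
blacklisted by default. A pair is positive when at least one shared
compound qualifies on both kinases, unknown when either kinase has no
assay rows, negative otherwise.

## What the synthetic generators emulate — and what they do not

`make_toy_structure()` builds PDB text with a small ring-shaped ligand and
residues whose *minimum* distance to the ligand is planted by root-solving
along a random placement ray, then quantized to the PDB coordinate
precision of 0.001 Å; the achieved distance is recorded exactly, so pocket
membership is known ground truth. `sample_microenvironment_set()` draws
sparse positive vectors and can engineer "sibling" pairs sharing a target
fraction f of similar cells, giving expected Tc = f/(2 − f).
`make_benchmark_scores()` draws positive and negative scores from shifted
normals with closed-form AUC Φ(δ/(σ√2)). All generators are pure functions
of their arguments and a seed; per-generator sub-seeds are derived from
the run seed by stable name hashing, so adding a generator never perturbs
another's stream.

These fixtures exercise every contract — distance rules, vector geometry,
score normalization, matching, ROC machinery — but they are not proteins:
toy structures have no realistic stereochemistry, secondary structure, or
rotamers, and synthetic vectors have no correlation structure between
properties. Passing tests therefore demonstrate algorithmic correctness,
not retrieval performance on real structures; measuring the latter
requires curated structure collections and a vetted property catalogue,
both outside this package's scope.

## Problem sizes used in the test suite

The suite runs at desk scale by design: backgrounds are built from tens of
sites with a few hundred microenvironments; alignment is verified against
an exhaustive mutual-best oracle on 1 000 random pocket pairs of up to six
microenvironments; Tanimoto is checked against a per-cell scan on 10 000
random 480-cell pairs; normal-fit recovery uses 10 000 draws; AUC checks
use 2 000 + 2 000 scores; the hypergeometric tail is compared with a
direct summation oracle over the complete argument grid up to N = 60
(exact in double-precision rational arithmetic wherever C(N, n) < 2⁵³,
log-space summation beyond). These sizes give comfortable statistical
margins for every asserted tolerance while keeping a full run under a
minute.

## Known limitations

- No geometric verification of alignments: two sites sharing
  microenvironment content in incompatible arrangements score as similar.
- The default property schema is this package's own; absolute Tc values
  are schema-dependent and comparable only within one schema + background.
- Backgrounds require enough cross-site pairs per pair type; rare types
  (e.g. W1 with small reference sets) are flagged missing, and alignments
  touching them fail loudly rather than guessing.
- Secondary-structure properties are zero without an external annotation.
- mmCIF input, hydrogen placement, biological-assembly generation and
  apo-pocket detection are out of scope.
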