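---
title: "Three-stage structural prediction of CD4 T-cell epitopes"
author: "Tripitope package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-stage structural prediction of CD4 T-cell epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Tripitope)
```

## The problem

Most computational CD4 T-cell epitope predictors score only
peptide–MHCII binding affinity, which over-predicts epitopes: a peptide
must also be excised from its parent antigen by endosomal proteases,
and the presented peptide–MHCII (pMHCII) complex must be recognized by
a T-cell receptor (TCR) from the responding repertoire. Tripitope
models all three stages for a given antigen sequence, MHCII allele
structure, and TCR model set, and integrates them into a single
ranking of candidate 12-mer epitope cores.

## Stage 1: antigen cleavage

Endosomal processing is modeled with the minimal cathepsin system:
cathepsin S and cathepsin B act as endopeptidases on the whole
antigen, and cathepsin H is a mono-aminopeptidase that trims single
residues from fragment N-termini. Each protease is described by a
specificity matrix over a window of Schechter–Berger positions around
the scissile bond (cut between P1 and P1′): counts of the residues
observed at each window position in a set of cleavage events are
converted to pseudocount-smoothed probabilities and then to natural-log
odds against a background residue distribution,

$$\mathrm{cleavage\_score}(i) \;=\; \sum_{p \in \text{window}}
\ln \frac{\Pr(r_{i+o_p} \mid p)}{q(r_{i+o_p})},$$

the sum of the log of the normalized probabilities across the window
centered on bond $i$. A bond is a *confident* cleavage site when its
score exceeds the threshold (default 3.0). Candidate 12-mers that
contain a confident bond strictly inside their span are removed from
the ranking; the filter is optional (for auto-antigens it is often run
both ways).

Parameter defaults, with rationale:

| parameter | default | notes |
|---|---|---|
| window, cathepsin S / B | P4–P4′ | matches the octapeptide event sets these enzymes are profiled with |
| window, cathepsin H | P1–P4′ | aminopeptidase events only constrain P1 and the prime side |
| threshold | 3.0 (nat log-odds) | the method's operating point; configurable |
| pseudocount | 1 (add-one) | finite log-odds for small event sets |
| background | uniform 1/20 | a table of natural residue frequencies may be supplied |
| aminopeptidase trims per fragment start | 1 (max 4) | H is a mono-aminopeptidase; trims never spawn new endopeptidase evaluations |

Three choices here were genuinely open and are resolved as follows.
The threshold is kept at the *literal* value 3.0 in summed natural-log
units, although a "three-fold over chance" reading would correspond to
ln 3 ≈ 1.1; the printed operating point is authoritative and the gloss
is treated as informal. Cathepsin B is scored over the full P4–P4′
window (its octapeptide training window) rather than the shorter
P4–P2′ range sometimes used for display. The cleavage filter removes a
candidate only for *strictly internal* confident bonds — a cut at a
candidate's boundary excises rather than destroys it. Window positions
that fall outside the antigen termini contribute 0 to the score
(neutral padding), which keeps near-terminal bonds scoreable;
norleucine in substrate peptides (a methionine surrogate in profiling
libraries) is mapped to Met on input.

## Stage 2: peptide–MHCII presentation

Every overlapping 12-mer of the antigen is a candidate epitope core
(the 12-mer starts two positions before the traditional 9-mer groove
register; `register_note = 2` records this). Each candidate is
threaded onto a pMHCII template with a **fixed backbone**: the MHC
chains and the template peptide's 12-residue core backbone (N, Cα, C,
O) are kept bit-identical, residue identities are replaced by the
candidate sequence, and side chains are rebuilt. The default
`"reduced"` placement gives every non-glycine residue an
ideal-geometry Cβ stub (Cα–Cβ = 1.53 Å), which is exactly the
representation the default residue-level scoring consumes; a `"copy"`
mode retains template side chains for unchanged residues. A rotamer
library is deliberately not bundled — full repacking belongs to
external tools, and the coarse potential does not resolve beyond Cβ.
Peptide flanks beyond the 12-mer core are not modeled.

The peptide–MHC interface of the threaded model is scored with a
distance-dependent statistical potential (below), giving `pmhc_score`
(lower = better).

## Stage 3: TCR recognition

For each surviving candidate, ternary pMHCII–TCR models are assembled
on a library of ternary templates: the pMHCII model is superposed on
the template through MHC Cα atoms and each TCR model through TCR Cα
atoms (Kabsch least-squares superposition), so the MHC–TCR orientation
of each assembly reproduces its template. With $m$ TCR models (loop
variability) and $t$ templates (orientation variability) there are
$m \times t$ assemblies per candidate — the production-scale grid is
10 × 500 = 5000 — and `tcr_pmhc_score` is the best (minimum)
TCR–pMHC interface score over the grid, with deterministic tie-breaks
by template then model order. TCR-β-only models are accepted.

Template-library coverage is quantified with the MHC-anchored TCR
RMSD: superpose two complexes on MHC Cα only, then take the Cα RMSD
over the TCR chains without refitting (`tcrRMSD`,
`closestTemplate`). All MHC-role Cα atoms anchor the superposition
(restricting to groove-domain Cα is a selection argument away).

## The statistical potential

Interface potentials are derived from cross-interface heavy-atom pair
counts binned by distance (half-open 0.5 Å bins over 0–15 Å by
default). For observed counts $o$ and reference counts $r$,

$$s(t_1, t_2, b) = -\ln\!\left(
\frac{(o_{t_1 t_2 b} + p)\,/\,(\Sigma o + P)}
     {(r_{t_1 t_2 b} + p)\,/\,(\Sigma r + P)}\right),
\qquad P = p \times \#\text{cells},$$

so identical tensors give the exact zero table and enriched cells
score negative (favorable). Scoring sums the table over pairs within
the interface cutoff (6 Å default). Two atom-typing schemes are
provided: residue-level (20 types, the default — adequate for
backbone + Cβ models) and a finer per-residue backbone/side-chain
scheme. The potential is distance-only: the orientation-dependent
terms of published atomic potentials are not reproduced (their
parametrization is not public), so trained tables here are
recipe-compatible, not value-compatible, with published ones.

The pMHC potential is trained with the two-stage bootstrap
`trainPMHCPotential`: models of affinity-labeled peptide–MHCII
complexes are built first, then the problem-specific table is derived
with binder-cohort counts as the observed state and nonbinder-cohort
counts as the reference state. The alternative reference state
(distance-shuffled pairs) is available through `derivePotential`
directly.

## Integration and consensus

The final score of a candidate is
`final_score = pmhc_score + tcr_pmhc_score`; survivors of the optional
cleavage filter are ranked by ascending final score (ties broken by
start offset). Z-scores use the mean and *sample* (n−1) standard
deviation of the final scores of **all** candidates — the pre-filter
population — so scores are comparable across antigens and TCRs.
External per-peptide affinity predictions (e.g. a NetMHCIIpan-style
table) are oriented so lower = better (nM affinities are
log-transformed first), Z-scored the same way, and added; whether such
tables report nM or rank-percentile is configurable through the
`type` argument, with log-nM as the default. Across a panel of TCRs,
`consensusAcrossTCRs` intersects the top-k sets (k = 100 by default)
and also reports the near-consensus (all-but-one) set — the
repertoire-level filter that reduces thousands of overlapping 12-mers
to a handful of candidate epitopes.

## What the synthetic generators emulate

All tests run on synthetic data generated in code; nothing is
downloaded.

* `makePlantedMatrix` / `makeCleavageDataset` emulate a protease
  profiling experiment: substrates of exactly the window length,
  sampled position-wise from a planted matrix (with an optional
  background-only decoy fraction). Planted probabilities are floored
  at 0.004 so planted log-odds stay within ±~3 nats — the range that
  is identifiable from a few hundred events under add-one smoothing;
  count-derived matrices have the same property, and cells far outside
  it would be unlearnable artifacts of the simulation, not of the
  method.
* `makeComplexSet` builds idealized mini-complexes: a 12-residue
  extended peptide flanked by two MHC chains whose anchor-facing
  positions carry Asp, and two short TCR chains docked above the
  peptide. Binder peptides carry Lys at the three anchor positions
  (realizing short-range Lys–Asp contacts); nonbinders are shuffles of
  binder peptides. Two deliberate design choices make the planted
  signal identifiable: the anchors sit at peptide positions 3/5/10,
  whose pairwise spacings (2, 5, 7) are distinct, so no register shift
  of a candidate aligns more than one anchor and the planted register
  is unique; and the non-anchor positions of every binder are a
  permutation of one fixed filler multiset, so binder and nonbinder
  cohorts have *identical* residue composition and the trained
  potential reflects positional contact structure rather than
  composition sampling noise. Ternary templates are generated
  noise-free at known TCR displacements, so their pairwise
  MHC-anchored TCR RMSDs equal the constructed displacements exactly.
* `makePlantedEpitopeScenario` plants one consensus-binder 12-mer in a
  ~100-residue antigen along with two cathepsin-S dipeptide cleavage
  motifs outside the epitope, and trains the potential from a fresh
  cohort — a complete, seeded end-to-end input bundle.

These generators are pure functions of their seed. They emulate the
*shape* of the real inputs (window structure of cleavage events, chain
roles and interface geometry of complexes, planted favorable contacts)
but none of the physics: no real groove chemistry, no side-chain
packing, no docking decoys. Passing tests therefore demonstrate the
correctness of the machinery — tallying, scoring, superposition,
assembly, ranking algebra, and recoverability of planted signal — not
predictive accuracy on real antigens, which depends on the quality of
the structural templates and trained potentials supplied.

## Numerical choices

* Distance bins and the interface cutoff are half-open (`[lo, hi)`); a
  pair at exactly the ceiling is excluded.
* Superposition uses the SVD form of the Kabsch solution with the
  determinant correction, so the rotation is always proper; fewer than
  3 pairs or a collinear selection is an error, not a silent result.
* Z-scoring a constant vector returns zeros with a warning.
* All rankings break ties by ascending candidate start; the best-of-grid
  search breaks ties by template order then model order. The pipeline
  is deterministic end to end.
* Alternate-location atoms: the first altloc is kept, the rest dropped
  with a warning. Chain roles are always assigned explicitly — no
  automatic MHC/TCR detection.

## Problem sizes used by the test-suite

The suite exercises: 1000 random (matrix, antigen, site) triples for
score/oracle equivalence; 500-event parameter recovery; 20
superposition pairs × 100 random perturbations; 100
discrimination trials; a 10 × 50 best-of-grid check; and 50 seeded
end-to-end planted-epitope runs on ~100-residue antigens with 2 TCR
models × 3 ternary templates. These sizes were chosen to estimate each
rate or bound tightly while keeping the whole suite comfortably
runnable on a laptop core; the production-scale 10 × 500 grid differs
only in loop extent.

## Limitations

* The potential is distance-only and, by default, residue-typed;
  trained tables are not numerically comparable to published atomic
  potentials, so published benchmark ranks are not expected to
  reproduce from this package without the original templates, models
  and potentials.
* Threading is rigid: no backbone relaxation, no register search
  within the groove beyond candidate enumeration, no flank modeling,
  and no CDR3 loop remodeling in the ternary context.
* The cleavage model is sequence-only (no structure, no kinetics or
  enzyme concentrations) and the aminopeptidase is restricted to
  N-terminal single-residue trims.
* Ternary orientations are limited to the supplied template library; a
  radically non-canonical TCR docking mode absent from the library
  cannot be predicted.
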