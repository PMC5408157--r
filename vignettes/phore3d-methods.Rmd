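---
title: "phore3d: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phore3d: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phore3d` is a ligand-based workflow for predicting hERG K⁺ channel binding
affinity: a common pharmacophore is derived from potent blockers, all
compounds are aligned to it, an atom-based 3D-QSAR model is fitted by
partial least squares on grid-occupancy descriptors, and the model is
validated by enrichment statistics on an active/decoy screen. This
vignette explains the model, each tunable parameter, the synthetic
benchmark, and the numerical and design decisions a maintainer should know
about. No empirical claim is made here beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The model and its assumptions

The core assumption is the pharmacophore hypothesis: molecules that block
the channel share a 3D arrangement of interaction features — for hERG
typically two aromatic rings, a hydrogen-bond acceptor, a hydrophobic
center and a basic (positively ionizable) nitrogen (label `AHPRR`) — and
affinity differences among blockers are explained by which additional
volume elements their atoms occupy once they are aligned on that common
frame. Both steps are approximations: the alignment is rigid per conformer
(flexibility enters only through the conformer ensemble), and the
regression is linear in binary occupancy bits.

**Feature perception.** Sites are assigned by explicit structural rules
(acceptors on O/N with a free lone pair, donors on N/O/S–H, P on charged or
basic sp³ nitrogens, N on charged/acidic centers, hydrophobic group
centroids, aromatic ring centroids with normals). The rules are shipped as
an editable CSV (`inst/extdata/feature_rules.csv`) so a user can tighten or
disable any rule; they are implemented as graph predicates rather than as a
SMARTS engine because no installed R cheminformatics stack exposes SMARTS
matches with atom indices. The rule table is the contract; the predicates
are its implementation.

**Conformers.** The retention contract is the scientific content: keep
conformers within an energy window of 21 kJ/mol of the minimum and prune
any geometry within 0.5 Å heavy-atom RMSD (after optimal superposition) of
an already-kept, lower-energy one — greedily, in ascending energy order,
which is the common convention and makes pruning idempotent and
order-independent. Raw geometries come from a seeded torsion-sampling
engine (full 60° grids for up to ~3 rotatable bonds, seeded random torsions
beyond) scored by a united-atom 12-6 steric term plus a 3-fold torsional
barrier. This engine is deliberately simple and bitwise-deterministic per
seed; it is recorded in ensemble metadata (`engine` field) and can be
replaced by any embedder that honors the same contract. Hydrogens are
excluded from the RMSD (heavy atoms only), which the redundancy rule does
not specify but which is the conservative reading.

**Hypothesis search.** Every k-subset (default k = 5) of every conformer's
sites becomes a *variant*: its sorted kind label (e.g. `AHPRR`) plus a
canonical inter-site distance vector — the lexicographically smallest
upper-triangle distance vector over all site orderings consistent with the
sorted kinds, which resolves the ambiguity of duplicated kinds (the two
rings) deterministically. Variants of one label are partitioned by a
recursive tree: the axis with the largest value range is split at the
midpoint of its largest empty gap, until every axis range is at most
`bin_size`; a leaf is therefore a data-centred box of edge ≤ `bin_size`.
Gap splitting (rather than bisection at the box midpoint) was chosen
because it never cuts a tight cluster that fits in one box — with a single
rigid conformer per molecule, midpoint bisection slices the common-geometry
cluster on some of the 10 distance axes with near certainty, whereas an
adaptive box keeps it intact. A leaf whose variants cover at least a
`must_match` fraction of the input molecules is emitted as a hypothesis,
using its medoid variant (minimum summed distance-vector distance, ties
broken by molecule id, conformer, site tuple) as the geometry. Candidates
are scored as

`score = w_align·(1 − mean match RMSD / 1.2 Å) + w_vec·mean |direction cosine| over A/R sites + w_vol·mean pairwise heavy-atom overlap`

with unit weights. Ring-normal signs are ignored; sites without directions
contribute a cosine of 1 (tolerant default); the volume term is a
symmetrized within-contact-distance atom fraction over at most 20 aligned
actives (the term is quadratic in molecules and saturates quickly).
The exact scoring function used by commercial software is unpublished;
this surrogate rewards the same three properties (tight alignment,
consistent feature directions, shared volume) and is documented rather
than authoritative.

**Matching and alignment.** A ligand matches a hypothesis if some
kind-consistent correspondence of at least `min_sites` sites superposes
with every site pair within the per-site tolerance (default 2.0 Å). The
best match maximizes matched sites, then minimizes RMSD, then conformer
energy — all ties broken deterministically. Superposition is the
closed-form SVD solution with the determinant correction (no reflections);
an independent quaternion implementation serves as the test oracle.
Collinear site sets are rejected as degenerate (second singular value
< 10⁻⁶).

**Atom-based QSAR.** Aligned heavy atoms are classed as D/H/N/P/W/X
(donor, hydrophobic, negative, positive, electron-withdrawing,
miscellaneous) and stamped onto a cubic grid (default spacing 0.5 Å,
margin 2 Å): bit (cube, class) is set iff an atom of that class lies
within its van der Waals radius of the cube center. The grid origin is
snapped down to a multiple of the spacing so matrices are bit-identical
across runs and ligand orderings. Columns occupied by fewer than
`min_occupancy = 2` ligands are dropped (a singleton column is pure
memorization for a binary descriptor). PLS1 (NIPALS) is fitted on the
mean-centered matrix — no unit-variance scaling, since the columns are
same-scale binary indicators — with models exposed for every factor count
up to 7; the cap guards against over-fitting. Cross-validation is
leave-n-out realized as seeded k-fold (default 10 folds, so n = ⌈rows/10⌉)
with `Q² = 1 − Σ(y_held − ŷ)² / Σ(y_held − ȳ_train)²` aggregated over
folds. The statistics panel per factor count k over n training compounds:
r² = 1 − RSS/TSS, RMSE = √(RSS/n), SD = √(RSS/(n−k−1)),
F = (r²/k)/((1−r²)/(n−k−1)) with P its upper-tail probability at
(k, n−k−1) degrees of freedom, and the Pearson product-moment r between
observed and predicted.

**Screening.** Each database molecule is matched, aligned, encoded and
predicted; molecules failing the match receive a floor prediction (the
training-set minimum pKi) and rank below every matched molecule, internally
by id. Ranking ties among matched molecules also break by id, so the hit
list is reproducible; the ROC instead gives ties half credit (Mann–Whitney
AUC), making the headline AUC tie-robust. EF, GH, %YA and %RA are computed
at full precision; two-decimal presentation is a display concern. Valid
contingencies additionally satisfy Ht − Ha ≤ D − A (hit-list inactives
cannot exceed database inactives); within that domain GH is provably in
[0, 1], and the preconditions enforce it.

## Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| energy window | 21 | kJ/mol | conformer retention window |
| RMSD cutoff | 0.5 | Å | conformer redundancy |
| max conformers | 200 | — | desk-scale runtime bound |
| potent threshold | 50 | nM | hypothesis-building subset |
| moderate/inactive boundary | 5 | µM | ties flag inactive (safer) |
| n_features (k) | 5 | — | AHPRR-size hypotheses |
| bin_size | 1.0 | Å | partition box edge |
| site tolerance | 2.0 | Å | per-site match radius |
| min_sites (screen) | 4 | — | partial matches allowed |
| grid spacing | 0.5 | Å | occupancy resolution |
| grid margin | 2.0 | Å | bounding-box inflation |
| min occupancy | 2 | ligands | column pruning |
| PLS factors | ≤ 7 | — | over-fitting guard |
| CV folds | 10 | — | leave-n-out realization |
| train fraction | 0.6 | — | 60/40 split, seed recorded |
| hit cutoff | 1% of D | — | purchasable-list size |

## The synthetic benchmark

`synthetic_spec()` defines the study conditions: 200 actives, 2,000
decoys, site jitter σ = 0.3 Å, 3 distractor sites per molecule, activity
intercept 6.3 pKi with eight substituent coefficients spanning −1.0 to
+1.2, noise σ = 0.3 pKi, and Ki clipped to 3.3 nM–54 µM (the span of a
realistic hERG panel, about 4.2 log units). Each active is a rigid classed
point-set molecule: the five planted AHPRR sites jittered per coordinate,
an anchor atom per site, a random half of the planted substituent atoms
(whose presence determines activity through the linear model), distractor
sites, and a random rigid pose. Decoys clone an active's atom count, class
composition and bounding-box extent but resample the site geometry,
rejecting (up to 25 redraws) any candidate that presents the *complete*
planted pharmacophore at tolerance + 0.5 Å — the margin makes the no-match
property robust to the difference between the planted geometry and a
hypothesis recovered from jittered actives. Partial (≤ 4-site)
arrangements are deliberately allowed: fragments of a pharmacophore occur
by chance in real property-matched decoys too, and the validation screen
accordingly requires the complete match (`min_sites = 5`), mirroring the
observation that inactives fail to fulfil *all* features of a
pharmacophore rather than most of them.

Two benchmark calibrations are the package's own: the hypothesis-search
bin is widened from the generic 1.0 Å default to `6·√2·σ_jitter` (2.5 Å at
σ = 0.3) because with one rigid conformer per molecule each inter-site
distance jitters with standard deviation √2·σ, and a box must hold ~3
standard deviations on all ten distance axes for most molecules to
co-locate; and `must_match` is relaxed to 0.4 because adaptive box
placement can still shave a boundary tail off the planted cluster — the
planted hypothesis is then identified by score, not by coverage alone.
Both numbers follow from the generator's stated jitter, not from tuning
against outcomes.

What the generator does *not* emulate: conformational flexibility (point
sets are rigid; a small family of real molecules exercises the conformer
and perception code instead), chemically consistent valence around planted
sites, correlated substituent effects, assay noise structure beyond
i.i.d. Gaussian pKi error, and the 2D-dissimilarity criterion of real
decoy services. Passing the recovery tests therefore demonstrates that the
geometry, regression and ranking machinery is correct under the stated
noise — not that the model generalizes to any particular real compound
series.

Problem sizes used by the test suite and acceptance script: recovery runs
use 200 actives (120 train / 80 test) and screen 100 unseen actives
against 2,000 decoys across seeds 1–5; oracle-equivalence fixtures use at
most 4 molecules × 6 sites × 3 conformers; the GH bound is swept
exhaustively over all valid contingencies with D ≤ 200. These sizes give
stable statistics while keeping a full run in minutes on one CPU.

## Numerical choices and degenerate inputs

- Distance-vector comparisons and medoid ties use strict deterministic
  tie-breaking (lexicographic by molecule id, conformer, site tuple);
  variants equal to a split point go to the lower box.
- Superposition excludes reflections (determinant correction); degenerate
  (collinear) site sets raise an error rather than returning an arbitrary
  frame.
- `prune_ensemble` on an empty ensemble returns it unchanged; PLS
  extraction stops with a warning when the residual covariance vanishes
  (rank exhaustion), and constant responses are rejected.
- Boundary Ki values: exactly 50 nM is potent (the potent class is defined
  inclusively); exactly 5 µM is inactive — the ambiguous boundary goes to
  the class that flags the compound, the safer choice for an anti-target.
- The 60/40 split is unstratified by default (stratification is an
  option); the seed is stored in the split object and every pipeline
  artifact embeds the config hash.
- Pipeline caching is keyed on content hashes (md5 of inputs plus the
  config), never on timestamps.

## Known limitations

- Feature perception covers the common functional groups; exotic
  tautomers, charged phosphates/sulfonates and organometallics fall back
  to conservative classes (X) with a warning.
- The conformer engine's strain energy is qualitative; relative energies
  are honored only through the retention contract, and no Boltzmann
  weighting is applied.
- Hypothesis search enumerates k-subsets per conformer; molecules with
  very many perceived sites (> ~15) make the combinatorics noticeable.
- Predictions outside the occupancy space spanned by training ligands
  revert toward the intercept; the floor policy for unmatched molecules is
  a ranking convention, not an affinity estimate.
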