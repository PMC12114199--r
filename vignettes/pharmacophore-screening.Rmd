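---
title: "Pharmacophore screening and decoy-aware validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore screening and decoy-aware validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
```

## The model

A pharmacophore model is a set of typed tolerance spheres in 3D: each
feature has a kind (hydrogen-bond donor HBD, acceptor HBA, hydrophobic
contact HC, or aromatic ring AI), a center, a radius, and optionally a
unit direction with a cone half-angle. Exclusion volumes (Xvols) are
additional spheres approximating receptor bulk: a conformer whose heavy
atoms reach strictly inside any of them cannot be a hit, no matter how
well its features align. Residue anchors such as `"Glu957"` are carried
as annotation only; they document which binding-site residue a feature
addresses and never influence matching.

A conformer satisfies a model when an injective, kind-compatible
assignment of model features to perceived ligand features exists such
that, after the least-squares rigid superposition of the assigned ligand
features onto the model centers,

1. every matched feature's residual distance is at most its tolerance
   radius,
2. every direction pair (when both sides carry one) subtends at most the
   cone half-angle — ring normals are compared as axes, since a normal
   has no preferred sign, and
3. no heavy atom lies strictly inside an exclusion volume.

Conformational flexibility is handled entirely by the conformer
ensemble: matching itself is rigid, and a molecule is screened by taking
its best conformer. A compound is a hit for a kinase when *any* model of
that kinase matches *any* conformer (union-of-models semantics); this is
the reading under which a single overall hit count can stand for a set
of eight to ten models per target.

### The correspondence search

The matcher enumerates assignments depth-first over model features,
pruning any partial assignment in which some pair violates
$|d_\text{model}(i,j) - d_\text{ligand}(a,b)| \le r_i + r_j$. This prune
is a *necessary* condition for acceptance (triangle inequality), so it
never discards an acceptable assignment; the test suite certifies the
pruned search against exhaustive enumeration with an independent
quaternion-based rigid fit on hundreds of random instances. The rigid
fit itself is the Kabsch SVD solution restricted to proper rotations, so
chirality is never inverted.

Among acceptable assignments the matcher maximizes the fit score

$$\text{score} = \frac{1}{|M|} \sum_{i \in M} \left(1 -
\frac{\text{residual}_i}{r_i}\right) \in [0, 1],$$

with ties broken by the lexicographically smallest correspondence so
results are deterministic. The score definition is this package's own:
the screening decision is binary and any monotone score would do; this
one is bounded, interpretable, and equals 1 exactly for a perfect
superposition. When nothing is acceptable, the best-scoring *failed*
assignment is still reported (with `matched = FALSE`); this is what lets
non-hits be ranked in ROC curves.

Three matched features are the minimum for a well-posed rigid fit, so
smaller assignments are rejected outright. With exactly three collinear
features the superposition has a one-parameter rotational ambiguity
about the feature axis; the matcher accepts only if the checks pass for
both ends of that family (the fitted solution and its half-turn about
the axis). By default all model features are required
(`max_omitted = 0`); partial matching is available per model but is not
used by any shipped workflow.

## Feature perception

Perception works on the annotated molecular graph of one conformer:

* **HBD** on each N or O carrying at least one hydrogen (explicit or
  implicit), one feature per donor heavy atom at the heavy-atom
  position; the direction is the mean explicit-hydrogen vector and is
  omitted when hydrogens are implicit.
* **HBA** on each N or O with an available lone pair, excluding amide
  nitrogens, nitro oxygens, pyrrole-type aromatic nitrogens and
  positively charged atoms; the direction is the lone-pair bisector
  approximation (opposite the mean bond vector).
* **AI** at the centroid of each 5- or 6-membered aromatic ring with the
  least-squares plane normal. Aromaticity uses a Hückel-style count on
  the ring (every atom contributes a double bond or a hetero lone pair,
  total $4n+2$), which covers benzenoid and the common heteroaromatic
  rings.
* **HC** at the centroid of each maximal connected cluster of at least
  three low-polarity atoms (C, S, F, Cl, Br, I, none bonded to N or O).

The rule table (`default_perception_rules()`) documents each rule with
an equivalent SMARTS pattern; the patterns are validated against probe
molecules in the test suite. Directions are always emitted when defined
but are optional at match time — a model feature without a direction
imposes no angular constraint, and a ligand feature without one is
never direction-checked.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| feature tolerance radius | 1.5 Å | sphere within which a ligand feature may fall |
| exclusion volume radius | 1.0 Å | forbidden sphere around receptor bulk points |
| cone half-angle | 34° | maximal angle between model and ligand directions |
| `max_omitted` | 0 | model features allowed to go unmatched |
| conformers (training / screening) | 200 / 400 | ensemble caps per compound |
| EF threshold | 4 | models below it are discarded |

The geometric tolerances mirror common pharmacophore-tool defaults; the
reference workflow fine-tuned tolerances per feature without publishing
values, so here they are configuration (per feature in the model JSON,
with `screen_params()` supplying defaults), not a fidelity claim. The
activity thresholds are fixed by the curation rules: active means
IC50 ≤ 1000 nM; inactive requires IC50 > 40,000 nM for JAK1 or
> 50,000 nM for JAK2/JAK3/TYK2; the intermediate band is excluded.
Repeated measurements for one compound are reconciled by their geometric
mean before thresholding — the reference datasets were curated manually,
and a deterministic rule replaces that judgment. A relative tolerance of
$10^{-9}$ keeps exact boundary values on the boundary despite log/exp
round-off.

## Validation statistics

With TP retrieved actives, FP retrieved inactives-plus-decoys, and a
database of $n_{AC}$ actives, $n_{IA}$ inactives and $n_{DC}$ decoys
(total $N$):

* sensitivity $= TP / n_{AC}$
* yield of actives $\text{YoA} = TP / (TP + FP)$
* enrichment factor $\text{EF} = \text{YoA} / (n_{AC} / N)$
* accuracy $= (TP + TN) / N$

The accuracy formula is printed ambiguously in the reference
(`(TP/TN)/N`); $(TP+TN)/N$ is the only reading consistent with all four
published accuracy values, and is what this package computes. No single
specificity formula reproduces all four published specificities, so two
explicit variants are reported — $TN/(n_{IA}+n_{DC})$ and
$1 - FP_{IA}/n_{IA}$ — and specificity is deliberately not part of the
reproduction checks. Likewise the published JAK3 sensitivity (0.86)
differs from $116/129 = 0.90$ recomputed from the same table's counts;
the recomputed value is reported, the printed one is documented here,
and neither is patched. ROC curves sweep a threshold over descending
fit scores with tied scores entering together; AUC is the trapezoid
area, identical to the Mann–Whitney statistic with ties counted 1/2.
How compounds were ranked for the reference ROC curves is not stated;
this package ranks by best fit score across a target's models, scoring
non-matching compounds by their best failed attempt.

## The synthetic benchmark generator

`make_planted_benchmark()` produces feature-set-level libraries: a
planted active is the model's own feature layout re-expressed in a
random rigid frame with isotropic Gaussian positional jitter (and
directions jittered by a small random rotation, 5° s.d.); a decoy
violates at least one constraint by construction — a kind permutation,
one feature displaced beyond twice its radius, or uniform random points
in the model's bounding box — and is *verified* to fail the matcher at
generation time (bounded retries; a model no decoy can fail is reported
as unfalsifiable). Dummy heavy atoms sit on the feature positions so
the exclusion-volume check stays live. Everything is derived from one
seed via stable stage hashing, so libraries are byte-identical across
runs.

This isolates matching and validation from chemistry: a planted
benchmark exercises correspondence search, superposition, tolerance and
clash logic, and the entire metrics stack, but says nothing about
feature *perception* on real molecules — that path is covered
separately by small embedded-molecule fixtures (benzene, phenol,
pyridine, pyrrole, amides, triazine herbicides) in the tests and the
`analysis/04` workflow. Passing planted benchmarks therefore shows the
screening machinery is correct, not that any particular model is
predictive for real chemistry.

Benchmark sizes in the shipped workflows are 20 actives + 180 decoys
per model (matching an inverse prevalence of 10, so a perfect screen
shows EF = 10 exactly) and 200 actives per jitter level in the noise
sweep; these sizes give stable statistics while keeping the whole
analysis reproducible in well under a minute per model.

## Conformers and chemistry input

3D embedding uses RDKit's ETKDG distance geometry (through the bundled
Python helper) with explicit hydrogens, MMFF cleanup, RMSD-based
duplicate pruning (0.5 Å default) and a fixed random seed — identical
seeds give bitwise-identical ensembles, which downstream screening
relies on for reproducibility. The pruning threshold and force-field
polish are configuration, not a claim of equivalence to any commercial
ensemble generator. SDF records are read and written through ChemmineR
(V2000 written, V3000 accepted on read); consecutive records sharing a
title and connectivity are regrouped into one molecule with a conformer
ensemble, and a record whose coordinates are all zero contributes no
conformer. Structure keys are InChIKeys (canonical SMILES as fallback)
computed via Open Babel, so they are invariant under atom reordering
and retain stereochemistry.

## The exemplar models

The coordinates of the optimized reference models are not published.
The repository ships eight *synthetic* exemplar models (one
structure-based and one ligand-based per kinase,
`jak_exemplar_models.synthetic.json`) whose feature and exclusion-volume
census follows the published figure captions — e.g. the JAK1
structure-based exemplar has one anchored HBD, one anchored HBA, two
HCs and 66 Xvols. Their geometry was authored for this package
(`data-raw/author_models.R`, seeded): features are mutually separated
by ≥ 2.5 Å inside a 5 Å sphere, and Xvols sit on a shell ≥ 2.6 Å from
every feature center so that a zero-jitter planted active can never
clash. Their role is to exercise the schema and pipeline end to end,
not to replicate any published model's output.

## Numerical choices and degenerate inputs

* Strict inequality for clash (a point exactly on an Xvol surface does
  not clash) and for the EF filter (EF < 4 drops, EF = 4 is retained),
  both following the stated rules.
* Acceptance comparisons carry a $10^{-9}$ absolute slack so exact
  boundary geometry is accepted regardless of round-off.
* Ties between equally scoring assignments, conformers, and models are
  broken by lowest index / lexicographic order — all outputs are
  deterministic.
* Empty feature sets, models with fewer than three matchable features,
  zero-hit screens (YoA/EF undefined, flagged rather than patched),
  empty decoy lists, single-class ROC inputs, and single-atom molecules
  (which the SDF layer handles via a narrow bondless-record fallback)
  are all exercised in the tests.

## Known limitations

* Ligand-based model building requires pre-aligned feature sets; the
  flexible 3D alignment a modeling suite performs before merging is out
  of scope (a seed-model match can supply the common frame).
* Residue bonding points are annotation only; no geometric semantics
  are attached to them.
* Aromaticity perception is rule-based Hückel counting, adequate for
  drug-like rings but not for exotic ring systems.
* The perception rule table is a standard default, not a re-derivation
  of any commercial tool's internals; feature counts on unusual
  functional groups may differ from specific modeling suites.
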