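---
title: "Multi-parameter scoring for de novo molecular design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parameter scoring for de novo molecular design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the scientific model behind `genscore`, the
parameters that matter, the numerical choices the implementation makes,
and what the bundled synthetic data can and cannot demonstrate.

## The problem

A goal-directed generative model for drug design emits batches of SMILES
and learns from a scalar reward per molecule. The reward must combine
heterogeneous evidence — physicochemical windows, similarity to known
actives, structural-alert avoidance, domain-of-applicability checks —
into a single desirability in [0, 1], and it must do so identically every
time the same molecule appears, fast enough to sit inside an optimisation
loop of hundreds of steps. `genscore` implements that oracle, plus the
post-hoc metrics used to judge what a run actually produced.

## The pipeline

Each batch passes through a fixed sequence:

1. **Parsing and canonicalization.** Every input is parsed with
   OpenBabel; malformed SMILES are values (`valid = FALSE`, score 0),
   never errors, because a generative model will emit them routinely.
   The canonical isomeric SMILES is the molecule's identity everywhere
   downstream. Canonicalization is idempotent — the test suite asserts
   `canonical(canonical(x)) == canonical(x)` over generated libraries.
2. **Uniqueness and caching.** Intra-batch duplicates are scored once and
   all copies receive the value. Molecules seen in earlier batches are
   served from the run cache without re-invoking scorers: scorer call
   count equals the number of distinct valid molecules in a run, an
   invariant the tests check with a counting scorer. What is cached is
   the raw and transformed values and the aggregate; diversity penalties
   are deliberately *not* cached, because a repeat is by definition
   non-diverse — the memory must see it again (the Unique and Occurrence
   filter kinds rely on exactly this).
3. **Scoring.** Each configured scorer maps one valid molecule to named
   raw values. A scorer exception fails that molecule (score 0, logged
   warning), never the batch: a long optimisation must survive single
   pathological molecules.
4. **Transformation.** Raw values become desirabilities in [0, 1] (next
   section), with per-parameter running state for the max–min kind.
5. **Aggregation, filters, diversity.** The desirabilities aggregate to
   one score; parameters declared as filters multiply it; the diversity
   filter penalises over-exploited chemotypes using its cross-batch
   memory. Output order always matches input order.

## Transformations and their parameters

* `step_threshold` — hard window; with `direction = "range"` it is
  `1[low <= x <= high]`, with maximize/minimize a one-sided cut at
  `threshold`. Used for property windows such as TPSA below 70 Å²,
  H-bond donors below 2, logP between 2 and 4, MW below 400 Da — the
  classic CNS-permeability-style profile used throughout the examples.
* `linear_threshold` — a ramp of width `buffer` (> 0, same units as the
  raw score) ending at `threshold`: credit degrades linearly instead of
  vanishing at the boundary. Midpoint of the ramp scores exactly 0.5.
* `gaussian_threshold` — `exp(-(x-mu)^2 / (2 sigma^2))`; for maximize
  (minimize) it returns 1 past `mu` in the preferred direction, so it is
  a soft one-sided target. `sigma` is the tolerance in raw units.
* `normalise` — running max–min over all values seen so far in the run,
  inverted for minimize. This is the "moving goal post" used when the
  raw scale is unknown a priori (e.g. an arbitrary model output). Before
  any range exists — first observation, or a constant stream — it
  returns 0.5: a neutral desirability is the only defensible value when
  no comparison is possible yet. Because the range state updates with
  every *newly scored* molecule in input order, a replayed run
  reproduces its transformed values exactly.
* Non-finite raw values score 0 with a warning; values within 1e-9 of
  the interval ends are clamped (floating-point guard only, never a
  semantic correction).

## Aggregations

Weighted sums normalise the weights internally, so configurations may
use any positive scale (a weight of 2 against three weights of 1 yields
2/5 of the mass). The auto-weighted kinds use per-molecule weights
`w_i = (1 - s_i) + 0.01`, i.e. mass concentrates on the least-satisfied
objectives; the 0.01 floor keeps fully satisfied objectives from
vanishing entirely. This formula is this package's concrete reading of
"auto-weighting" — the idea is standard, the constant is ours, and it is
unit-tested so any change is visible. Pareto aggregation is batch-wise:
molecules are non-dominated-sorted within the newly scored part of the
batch and the front rank maps linearly onto [0, 1]
(`1 - (rank-1)/n_fronts`), ties within a front sharing a value; a scalar
is required because the pipeline contract returns one number per
molecule. The sort is the dominance-count peeling algorithm, checked
against a brute-force pairwise oracle on random batches.

## Diversity filters

The memory clusters high-scoring molecules and penalises arrivals to
saturated clusters. Design points:

* **Hard zero on overflow.** For the scaffold and similarity kinds a
  molecule whose cluster already holds `nbmax` members scores 0 — a
  memory-assisted reinforcement scheme where exploitation beyond the
  bucket earns nothing. `Occurrence` is the one graded kind: score
  scales by `max(0, 1 - max(0, seen - tolerance)/buffer)`.
* **The `minscore` gate (default 0.5) applies to everything.** Molecules
  below it neither enter memory nor get penalised; the filter manages
  *successful* chemotypes only. Penalising sub-threshold molecules would
  only add noise to an already-zero-ish reward.
* **Determinism.** Similarity kinds join the nearest centroid with
  Tanimoto at or above `minsimilarity` (default 0.6, ECFP4 for compound
  and ECFP4/atom-pair over the Murcko scaffold for the scaffold kinds);
  equal similarities join the earliest-created cluster. Replaying a
  record stream from a fresh memory reproduces outputs exactly.
* Acyclic molecules share the `""` scaffold cluster under the scaffold
  kinds — a deliberate pooling, since "no scaffold" is itself a
  chemotype that can be exploited.

## Chemistry substrate and numerical choices

Parsing, canonical SMILES, ECFP/MACCS/path fingerprints, SMARTS matching
and the logP/TPSA/HBD/HBA/MW descriptors are delegated to OpenBabel
(via ChemmineR/ChemmineOB). Scaffolds, ring systems, rotatable-bond
paths, SSSR and the atom-pair, torsion, pharmacophore-pair and
feature-class fingerprints are computed natively on the molecular graph:

* **Murcko scaffolds** prune non-ring atoms of degree ≤ 1 iteratively,
  then re-attach exocyclic multiply-bonded atoms (a ring ketone keeps
  its carbonyl oxygen). The generic (topological) scaffold additionally
  rewrites every atom to carbon and every bond to single. Both are
  emitted as canonical SMILES via an SDF round trip, so scaffold
  identity is string identity.
* **SSSR** is built greedily from ring perception capped at ring size
  12, keeping cycles that are independent over GF(2) edge space. The cap
  bounds enumeration on fused aromatics; molecules in the intended
  drug-like size range are unaffected.
* **Rotatable bonds** are acyclic single bonds between two non-terminal
  heavy atoms, excluding amide C–N and bonds into triple-bond termini —
  the standard rotor definition, expressed on the graph. The
  consecutive-rotor descriptor is the longest simple path in the rotor
  subgraph (DFS; rotor subgraphs are near-trees, so enumeration is
  cheap), validated against an exhaustive path oracle.
* **Hashed fingerprints** (atom pair, torsion, 2-point pharmacophore,
  feature-class) use a deterministic 31-bit string hash; they are
  internally consistent and stable across platforms but not
  bit-compatible with any other toolkit's implementation, which the
  package never claims. Counted variants (atom pair, torsion) use the
  min/max generalisation of Tanimoto and binarize for all other
  coefficients.
* **Synthetic accessibility** is a native complexity-based estimate on
  the conventional 1–10 scale (size, ring fusion, macrocycles,
  quaternary carbons, spiro atoms, heteroatom load). It deliberately
  omits the fragment-frequency term of corpus-driven SA scores, which
  requires a multi-million-entry database; within this package it serves
  as the monotone complexity penalty inside penalised logP and as a
  property axis in the Wasserstein metrics. Penalised logP is
  `logP - SA - (# SSSR rings larger than 6)`, with no training-set
  z-normalisation — the raw difference is returned and documented as
  such.
* **QED** uses the published asymmetric-double-sigmoid desirability
  parameters; its inputs come from OpenBabel and its alert count from
  the shipped alert list, so absolute values differ slightly from
  implementations on other toolkits while preserving the ordering
  behaviour that matters for scoring.
* **Alert lists** (`inst/extdata`) are compact curated catalogues of
  widely agreed reactive/unstable motifs and assay-interference classes,
  written for this package; they are subsets, not the full published
  catalogues, and the file headers say so.

## Metrics: conventions that needed a decision

* **Internal diversity** excludes self-pairs, making a single-molecule
  set score exactly 0; the self-inclusive convention used by some
  distribution-learning suites is available behind
  `include_self_pairs = TRUE`.
* **SEDiv and Solow–Polasky sample the valid stream with duplicates**
  (seeded shuffle, cap `sample_n`, default 1000). A set of k copies of
  one molecule must score 1/k — deduplicating first would hide exactly
  the redundancy the metric exists to expose.
* **Solow–Polasky** is reported normalised as D/n in (0, 1] so values
  compare across set sizes; `theta` defaults to 1 on the
  `1 - Tanimoto` distance, and a 1e-10 ridge regularises duplicated
  fingerprints.
* **Analogue threshold** defaults to 0.4 Tanimoto; coverage is
  normalised by the reference side (what fraction of the reference has a
  generated analogue), the natural reading of "coverage".
* **Wasserstein distances** are exact 1-D earth-mover integrals over
  merged quantile breakpoints, in the property's own units.
* Metrics that require trained networks or external catalogues (Fréchet
  ChemNet distance, purchasability, natural-product likeness) are
  reported as `NA` markers rather than omitted, keeping report schemas
  stable.

## The synthetic data, and what the tests do and do not show

`make_library()` enumerates decorated scaffold templates (alkanes,
substituted benzenes, piperazines, morpholines, fused bicyclics) with a
seeded internal LCG, so libraries are reproducible and independent of
the caller's RNG state. The stated fraction of entries is corrupted with
unmatched ring-bond/bracket tokens — corruptions chosen to be
unparseable by construction, so "invalid" is exact, not probabilistic.
The default test conditions use 10% invalid entries, matching the
realistic failure rate of an imperfect SMILES generator, streams of
500–1000 molecules through the pipeline, and metric samples of a few
hundred molecules; the methods scale linearly (pipeline) or
quadratically (pairwise metrics) beyond that.

The demo optimizer is resampling-based: batches are drawn from a fixed
pool with weights `exp(score / temperature)`, so it exercises the full
iterative loop — caching, running normalisation, diversity memory,
budget accounting — through the same three-call interface a generative
model would use (construct, score batches, finalize). It is *not* a
generative model: it cannot leave its pool, so passing tests demonstrate
the scoring side of the loop, not chemical novelty. Likewise the fixture
library spans a deliberately narrow, clean chemistry; real de novo
output is weirder (charged species, macrocycles, tautomer artefacts),
and the pipeline's guarantees there are the structural ones (validity
handling, determinism, bounds), not calibration of any particular
scorer.

## Known limitations

* Fingerprints are not bit-compatible with other toolkits; similarity
  values are comparable within the package only.
* The SA estimate ranks complexity, not literal synthesizability; it has
  no knowledge of reagent availability or precedent.
* 3D methods (docking, shape alignment, conformer generation) and
  scorers requiring external services, licenses or trained weights are
  out of scope by design; the `property_model` and `custom` scorer kinds
  are the extension points where such models would plug in.
* McConnaughey similarity follows its standard definition with range
  [-1, 1]; it is the one shipped coefficient that is not a [0, 1]
  desirability and should not be used directly as a score without a
  transform.
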