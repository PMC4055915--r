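---
title: "Predicting folding-initiation segments from sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting folding-initiation segments from sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldinit)
```

# The problem

Small proteins of a common topology — the ferredoxin-like fold
(βαββαβ, two helices packed on a four-stranded antiparallel sheet) is the
motivating family — can nevertheless start folding from different parts of
their chain. Experimentally this shows up in Φ-value analysis: residues
structured in the transition state carry Φ near 1. `foldinit` asks how much
of that information can be recovered from the amino-acid sequence alone,
using only a table of *inter-residue average distance statistics* compiled
from solved structures.

Three sequence-only analyses are combined:

1. **Average Distance Map (ADM)**: a predicted contact map; its dense
   diagonal blocks ("compact regions") are candidate folding-initiation
   segments, scored by an η value.
2. **F-value analysis**: a coarse-grained Cα chain is sampled by Metropolis
   Monte Carlo under a Gaussian distance potential derived from the same
   statistics; range-normalized contact frequencies are summed into a
   per-residue F profile whose peaks mark putative hydrophobic-cluster
   centers. (F here is a simulation statistic — distinct from experimental
   Φ.)
3. **Conservation profiling**: conserved hydrophobic residues (>99 %
   across a homologue alignment, interchanges within
   {A, M, W, L, F, V, I, Y} tolerated) and the native contacts between
   them, defined by a solvent-accessibility burial criterion, provide an
   evolutionary cross-check of the predicted segments.

# Distance statistics

For every residue pair i < j of every input chain, the Cα–Cα distance is
keyed by the two residue types and the *separation range* M of
k = j − i: k = 1–8 → M = 1, 9–20 → M = 2, 21–30 → M = 3, and width-10 bins
beyond. Per key the mean r̄ and the *population* standard deviation σ are
stored (`build_statistics()`); the potential below treats σ as a
distribution parameter, which is why the population convention is used and
why one-sample keys (σ = 0) are floored downstream.

Lookup is total: a never-observed (pair, M) key backs off to the mean over
all observed pairs of the same M (each observed distance counted once); a
never-observed range backs off to the nearest observed M. Totality matters
because an ADM must be constructible for any query sequence.

# ADM construction and region extraction

`build_adm()` fills the map with r̄ looked up per pair and thresholds it at
a configurable cutoff (default 13 Å): pairs with small expected distance
are predicted contacts. For an interval [a, b],

* density(a, b) = predicted contacts among pairs inside [a, b] / number of
  such pairs,
* η(a, b) = density(a, b) − density(1, N).

η is therefore zero for the whole sequence and positive for intervals
denser than background — the published behaviour ("many contacts within
the region" ⇒ high η) with a fully specified, testable formula. The exact
η numerics of the original method are not recoverable from the primary
literature accessible here, so Table-1-level numerical agreement is out of
scope (see *Limitations*); defaults (cutoff 13 Å, η threshold 0.03,
minimum length 10) are config-exposed stand-ins chosen so the weakest
published region score (≈0.036) would clear the threshold while candidates
on featureless random maps do not.

**Boundary scan.** Candidates come from a recursive split of the diagonal:
for the current interval, every admissible split point p is scored by
η(a, p) + η(p+1, b) and the best p (smallest on ties, for determinism)
is examined. The interval is split — and its children recorded and
recursed into — only when the contact density *between* the two parts
falls below the whole-map density, i.e. when the parts interact less than
background. This substructure criterion is the one design point where
implementation experience overruled the initial design ("recurse while a
child's η exceeds the threshold"): inside a homogeneous dense block every
sub-interval has the same η, so threshold-based recursion shatters the
block into minimum-length tiles; the cross-density criterion stops exactly
at block boundaries and recovers planted two-block structure to the
residue.

Candidates covering the whole sequence are discarded; survivors above the
η threshold are resolved greedily (higher η wins, overlaps dropped). A
kept region covering ≥70 % of the sequence triggers one re-scan restricted
to its interior, whose sub-regions are reported alongside it. The maximal-η
region is `primary`, the rest `auxiliary`; `dominance` is N or C by the
half of the sequence containing the region midpoint.

# The Monte-Carlo F-value analysis

**Model.** N beads, fixed virtual bonds of 3.8 Å (trans Cα–Cα). A move at
joint i rotates the whole downstream segment rigidly: a *bend* about an
axis perpendicular to bonds (i−1, i) and (i, i+1) (changing the bond angle
at i), then a *torsion* about the bond itself, each by an independent
uniform angle in ±10°. One sweep visits joints 1 … N−1 in order. Rigid
rotation preserves bond lengths to machine precision (asserted to 1e-6 Å
over 1000 sweeps) and leaves downstream-internal distances unchanged, so
the energy difference of a move involves only joint-crossing pairs — this
is what makes the O(N³)-per-sweep cost tractable in compiled code. The
first joint has no previous bond; a fixed perpendicular of the first bond
serves as its bend axis (also the fallback for collinear bonds).

**Potential.** Equating the Boltzmann weight of a pair distance with the
Gaussian density of its statistics key gives, per pair with |i−j| ≥ 2,

E(r) ∝ (r − r̄)² / (2σ²) + const.

The constant is conformation-independent and cancels from every ΔE
(asserted by test), and the dimensionless quadratic is taken as the energy
in fixed units with kT the Metropolis temperature: taken literally, an
energy *defined* in units of kT would cancel the temperature from every
acceptance ratio and leave nothing to calibrate. σ is floored at 0.1 Å so
one-sample keys cannot produce near-infinite forces. No steric term is
added: the potential is meant to reproduce the distance statistics, not
to model excluded volume.

**Calibration.** kT is set so the acceptance ratio is 0.5, by bisection on
log kT. Each bisection step measures the mean acceptance of 20 pilot
chains over the last quarter of 400 sweeps. Two estimator choices matter
and were fixed from measurement, not from test outcomes: (i) the *late*
pilot window — acceptance drifts upward by ≈0.02 as a chain relaxes from a
random start, so an early window systematically over-sets kT relative to
what long production sampling realizes; (ii) a stop tolerance of 0.01 —
at ±0.02 the calibrated kT varied by 15–20 % between seeds because the
acceptance-versus-log kT slope is shallow (≈0.15 per ln-unit), while at
±0.01 the seed-to-seed spread is under 10 %.

**Sampling.** Per run: random initial bond angles (uniform 60–160°) and
dihedrals (uniform ±180°), kT calibration, then n_steps sweeps with the
first 10 % discarded; after every remaining sweep the contact indicator
(Cα–Cα ≤ 8 Å, |i−j| ≥ 2) is accumulated. Frequencies g(i,j) are averaged
over n_runs independent runs (published scale: 60000 sweeps × 100 runs;
tests and the acceptance report use the stated desk scales, e.g. 5000 × 10,
which this package's checks are calibrated against). The 8 Å cutoff,
burn-in fraction, amplitudes and initial-angle ranges are unstated in the
source method and are config-exposed conventions here.

**Normalization and profile.** Within each separation range M, Q is g
centred on the range mean and divided by the range's population SD
(zero-variance ranges give Q = 0), so Q sums to zero per range;
F_i = Σ_j Q(i,j) then sums to zero globally. Peaks of F are strict local
maxima over a ±2 window; because chain ends are unrealistically flexible
in this model, peaks within 5 residues of either terminus are discarded.
Peak lists are compared by greedy nearest matching within ±3 residues.

# SASA contacts and conservation

`shrake_rupley()` samples each atom's expanded sphere (vdW + 1.4 Å probe)
with a deterministic golden-spiral lattice (default 960 points; no RNG, so
results are exactly reproducible). Radii are C 1.70, N 1.55, O 1.52,
S 1.80 Å — the carbon value is forced by the analytic two-carbon burial
reference 2π(1.7+1.4)·1.4 = 27.27 Å², which fixes the contact threshold
at 27 Å². A hydrophobic residue pair is in native contact when removing
either partner's atoms raises the other's side-chain SASA by ≥ the
threshold (the directional definition is asymmetric; taking the max makes
the contact set symmetric, which downstream profiling requires). Whether
the original baseline removed only the partner or all neighbours is not
stated; the pairwise-removal reading is used. Glycine has no side-chain
heavy atoms and is never in contact.

Conservation uses the column-fraction rule on a user-supplied alignment: a
site with no gap in any record, whose reference residue is hydrophobic,
is conserved when the fraction of records carrying any hydrophobic residue
is strictly greater than 0.99. The source method estimated conservation
through a phylogeny (NJ tree + maximum-likelihood substitution counting);
that tool chain is out of scope here, and the fraction variant is a
documented substitute realizing the same downstream >99 % rule. Per-residue
counts of contacts between conserved hydrophobic residues are smoothed
with a discrete Gaussian (bandwidth 2 residues by default — unstated in
the source, chosen to suppress adjacent-residue noise while resolving
peaks ≥ 7 residues apart). Smoothing uses *reflecting boundaries*: kernel
mass falling off a chain end is folded back inside, which conserves total
mass exactly and maps a constant profile to itself — the two properties
the tests pin down (a mass-renormalized edge kernel satisfies the first
but ripples on constant input).

# Family analyses

Per aligned homologue, regions predicted on its ungapped sequence are
mapped to alignment sites (`regions_to_assignment()`). The ADM similarity
of two records drops every site gapped in either and returns the
percentage of remaining sites agreeing on region membership; it is
symmetric, bounded in [0, 100], and documented as unsuitable for
alignments with large gaps (the synthetic generator caps its gap rate at
0.1 accordingly). On top of it sit the per-site inclusion histogram, the
average-similarity-versus-identity-lower-limit curve (identity computed
over mutually non-gapped sites, grid 30–100 % by 5), and a neighbor-joining
tree of d = 1 − s/100 (via `ape`).

# The synthetic world

The generators plant the statistical properties the analyses assume, and
return their ground truth so tests never re-derive it:

* `make_compact_chain()`: self-avoiding (≥3.0 Å) fixed-bond chains grown
  in a confining sphere calibrated so Rg ≈ 2.2 n^{1/3} Å — the globular
  scaling a structure set used for distance statistics should obey.
  Sequences are hydrophobic-rich (60 %).
* `make_two_domain_family()`: two compact blobs per chain, separated by
  15 Å of clearance (safely beyond the 13 Å ADM cutoff), with disjoint
  block alphabets, so statistics built from the family encode dense
  intra-block/sparse cross-block structure and region extraction on a
  probe sequence has an exact planted boundary to recover.
* `make_msa()`: an ungapped reference with planted regions
  (boundary-jittered per record) and planted conserved sites carrying an
  *exact* number of hydrophobic records (interchange applied); non-planted
  sites are guaranteed below the >99 % rule, gaps (≤0.1) avoid planted
  sites and regions. A target of 1.0 must be flagged, 0.9/0.95 must not.
* `make_sasa_fixture()`: two-carbon pairs at 10 Å (no burial) and 3.4 Å
  (the 27.27 Å² cap reference) and a fully enclosed atom (SASA ≈ 0).

What a green test does *not* establish: real structure sets are not
hydrophobic-rich SAWs, real domains share alphabets and touch each other,
real alignments have phylogenetic correlation. The synthetic world tests
the machinery (recovery of planted truth, exactness of the bookkeeping),
not the biological accuracy of the predictions.

# Numerical choices and degenerate inputs

* Diagonal and |i−j| < 2 entries of maps/matrices are NA, never 0.
* Peak detection uses a 1e-9 relative margin so summation-order ripple on
  flat profiles cannot create spurious strict maxima.
* Zero-variance normalization ranges give Q = 0 (convention, tested).
* Ties in the boundary scan resolve to the smallest split point;
  overlapping candidates of equal η keep the earlier-starting one.
* Sequences with >50 % unknown residues are rejected for ADM analysis;
  unknown residues elsewhere fall back to range statistics.
* An alignment site gapped in *any* record is ineligible for conservation.

# Limitations

* The exact η formulation, contact cutoff and region-length parameters of
  the original ADM method are not in the accessible text; published η
  values (0.036–0.197) and region boundaries for specific PDB entries are
  therefore not reproduced numerically, and no test asserts them. The
  qualitative layout (two terminal compact regions per protein) requires
  PDB downloads plus the original 42-protein statistics set and is left as
  an optional integration exercise; family-similarity contrasts
  additionally depend on a BLAST-derived corpus.
* Conservation is column-fraction, not phylogeny-weighted.
* The Monte-Carlo model has no excluded volume and a single move class;
  it targets the distance-statistics ensemble, not folding kinetics.
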