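---
title: "Ensemble allostery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble allostery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloscan)
```

# Scope and model

`alloscan` supports a two-sided workflow for studying conformational state
equilibria of kinase domains with structure predictors. The front-end
perturbs the predictor's input — alanine masking of the query sequence plus
shallow MSA subsampling settings — to diversify predicted ensembles; the
back-end quantifies what an ensemble contains: which states it samples, in
what proportions, how residues move together, and which residues sit at the
communication bottlenecks of the resulting interaction network.

All back-end analyses operate on Cα coordinates of a multi-model ensemble
over one shared residue numbering. This is deliberate: every statistic we
compute — RMSD, TM-score, coordinate PCA, displacement correlations,
Cα-contact networks — is defined on Cα traces, so side chains contribute
nothing to the results and are not modeled.

# Front-end: masking and job planning

## Per-position masking model

For each eligible position the masker draws a probability
$p_i \sim U(p_{\min}, p_{\max})$ (defaults 0.05–0.15) and substitutes the
residue with alanine with probability $p_i$. Two readings of "mask 5–15% of
residues" exist: fixing a per-sequence rate first, or drawing per-position
probabilities. We adopt the per-position form because it is the more
explicit description of the algorithm we implement; users should note the
realized per-variant rates then have a wider spread than under a fixed-rate
scheme (the mean is identical, $(p_{\min}+p_{\max})/2 = 10\%$). Positions
that are already alanine count as eligible draws whose substitution is a
no-op; recording them keeps the realized rate well defined regardless of
the input's alanine content.

Each variant uses an independent sub-seed derived deterministically from
the set-level seed and the variant index, so any variant can be regenerated
in isolation. Ten variants per run is the default; the useful range in
practice is roughly 10–50.

## Job-plan arithmetic

With recycling enabled, one predictor model emits one structure per recycle
plus a final refined structure: `num_recycles + 2` structures. The planner
therefore enumerates exactly
`n_models * num_seed * (num_recycles + 2)` outputs per input sequence — 70
with the defaults (5 models, 1 seed, 12 recycles). The default MSA
subsampling depth `max_seqs:extra_seqs = 16:32` is the shallow setting that
maximizes ensemble diversity at an acceptable misfolding rate. The planner
emits manifests for an external runner and never invokes a predictor: GPU
inference is outside this package's scope, and the hand-off contract (FASTA
plus JSON manifest, predictions dropped back as multi-model PDB) keeps the
boundary explicit.

# Back-end conventions

## Reference conformations and RMSD

The reference conformation of every ensemble is its **first model**; RMSD,
TM-score and state classification all follow this convention, and the
proximity mapping uses the same model for coordinates. Whole-chain RMSD
fits on all shared Cα atoms. Region-restricted RMSD (e.g. the activation
loop, ABL residues 398–421) fits on the whole chain and *reports* on the
region — local deviations after a global fit — matching how loop
rearrangements are conventionally quantified. Both the fit and report
selections are configurable. Two interval conventions for the activation
loop circulate (395–421 and 398–421); the package defaults to 398–421 and
accepts any interval.

Classification assigns a model to the nearest reference state only when
that RMSD is below 1.5 Å (configurable); otherwise the model is
`unassigned`, and population fractions are reported over assigned plus
unassigned so they always sum to 1. Exact ties (within $10^{-9}$ Å) are
broken by the order of the reference list, with a message.

## TM-score

$\mathrm{TM} = \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2}$ with
$d_0 = 1.24\,(L-15)^{1/3} - 1.8$ floored at 0.5 Å, maximized over rigid
superpositions by the standard fragment-seeded iteration: fits seeded from
sliding windows of length $L$, $L/2$ and $L/4$ are refined by re-fitting on
residues currently within $\max(d_0, 3)$ Å until the selection stabilizes
(at most 20 rounds), and the best score over all seeds is kept. The
normalization length is the reference chain length; inputs must cover the
same residues of the same protein — no sequence alignment is performed.

## PCA on common components

Before any covariance computation, all models are iteratively superposed
onto the evolving mean structure (at most 10 rounds or until the mean moves
less than $10^{-4}$ Å), removing rigid-body motion; a final pass fits every
model onto the converged mean so that projections reproduce the fit
exactly. The covariance of the flattened coordinates is eigendecomposed;
eigenvector signs are fixed so each component's largest-magnitude
coordinate is positive, making score plots reproducible across platforms.
Fitting the components on a merged wild-type reference ensemble and
projecting every other ensemble onto them places experimental and predicted
ensembles in one coordinate frame, which is what makes their coverages
directly comparable. When confidence values are present, models with mean
pLDDT below 70 are excluded from the fit by default — low-confidence models
are partially misfolded and would inflate the variance with noise. Two
components are reported by default; `state_overlap()` quantifies cloud
overlap as the fraction of one group's scores inside the other's 95%
Gaussian ellipse.

## Correlations

The dynamic cross-correlation is the normalized form
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
\sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}$, which
guarantees $C_{ii} = 1$; an unnormalized rendering (without the square
root) sometimes appears in print but does not yield a correlation.
Zero-variance residues would make the quotient undefined; their
off-diagonal entries are set to 0 with a warning.

The generalized correlation is
$R = \sqrt{1 - e^{-2I/3}}$ with $I$ the mutual information between the two
residues' 3-D displacement vectors (dimensionality $d = 3$ in the
exponent). The default estimator is analytic-Gaussian — $I$ from the
determinants of the $3\times3$ and $6\times6$ displacement covariance
blocks — chosen because it is stable at the ensemble sizes this workflow
produces (around 70 models). A Kraskov k-NN estimator ($k = 4$) is
available for larger ensembles; it is nonparametric but needs at least 30
models and scales as $O(N^2 M^2)$. For jointly Gaussian displacements with
equal per-dimension correlation $\rho$, the closed form gives
$R = |\rho|$, which the test suite uses as its oracle; sample estimates
also satisfy $R \ge |C_{ij}|$ — the generalized correlation captures the
linear correlation at minimum.

Both correlation functions superpose the models first (same scheme as PCA)
by default. Synthetic ensembles are generated in a common frame, so tests
of exact limits ($C_{ij} = \pm 1$) disable the superposition: a rigid-body
fit re-expresses coordinates and would blur constructed exact
correlations.

## Contacts and the interaction network

An edge joins residues whose Cα–Cα distance stays within the cutoff in at
least 75% of models. The 5 Å default follows the side-chain contact
convention; for Cα-only traces 7–8 Å is more appropriate (the pipeline
demo uses 7.5 Å) because Cα atoms of side-chain-contacting residues sit
farther apart. Chain neighbors ($|i-j| \le 1$) are excluded: their contact
is covalent, and the network models non-covalent communication. Edge
weights are $w_{ij} = -\log R_{ij}$; $R \ge 1 - 10^{-12}$ is clamped
(weight floor $10^{-12}$, keeping weights strictly positive) and $R = 0$
edges are dropped with a warning since they carry no information flow.

Shortest paths use Floyd–Warshall with exact co-optimal path counting
(length ties resolved within $10^{-9}$; all co-optimal paths counted, no
tie-breaking), implemented in C++ — the algorithmic core the rest of the
network analysis consumes. Betweenness excludes path endpoints and sums
over pairs within each connected component; Z-scores are computed over all
nodes, and a flat profile (zero variance) yields all-zero Z-scores, a
warning, and no hotspots rather than an error. Hotspots are residues with
$Z \ge 2$.

Communities come from Girvan–Newman removal of the maximum
edge-betweenness edge (weighted paths, recomputed after every removal),
returning the partition that maximizes Newman modularity along the
dendrogram, evaluated on the unweighted edge set. Bridgeness uses a
Rao–Stirling-style diversity sum over foreign communities,
$G_i = \sum_{J \ne I} \delta_{iJ}\, l_{IJ}$, where $\delta_{iJ}$ indicates
at least one edge from node $i$ into community $J$ (an indicator, not an
edge count — multiplicity is already carried by $l_{IJ}$) and
$l_{IJ}$ is the inverse of the number of $I$–$J$ links. Nodes with only
internal edges score exactly 0.

# The synthetic-data generators

The generators define the conditions under which the pipeline is tested.

* **Reference states.** A helix-like parametric Cα backbone (radius 2.3 Å,
  rise 1.5 Å, 100°/residue — the canonical 3.8 Å Cα spacing) of 287
  residues numbered 245–531, so the activation-loop interval 398–421 and
  the αC-helix interval 291–311 fall inside the chain. The three states
  differ only by a rigid translation of the loop segment: `I1` 4 Å along
  x, `I2` ~8 Å along (0, 4, 7) — magnitudes comparable to an
  open-to-closed activation-loop swing. Each state's ensemble holds 20
  models (the size of the experimental reference ensembles this workflow
  is built around) with isotropic Gaussian noise per coordinate.
* **Noise level.** The default `noise_sd = 0.3` Å makes a mixture model's
  RMSD to its own state's reference conformation ≈ 0.9 Å — comfortably
  inside the 1.5 Å assignment rule, as befits models that are "members" of
  a state — while the between-state separations (1.2–2.3 Å whole-chain)
  keep the states distinct. A noise level of 0.5 Å would place same-state
  RMSD exactly at the 1.5 Å boundary (three independent noise draws stack
  as $\sqrt{9\sigma^2}$), i.e. the fixture would no longer represent
  ensembles whose members are recognizably close to their state.
* **Mixtures.** Model slots draw state labels i.i.d. from the requested
  populations (the headline scenario is 82/10/8), then a uniformly chosen
  model of that state plus fresh noise; the true labels are returned so
  classification can be scored. The default draw of 70 models mirrors one
  prediction run.
* **Confidence tracks.** Loop residues draw pLDDT-like values from 65–85
  (mobile loops show moderately reduced confidence), core residues from
  80–100, and designated low models from 40–65 — guaranteeing a model mean
  below 70 so confidence-filter tests can count removals exactly.
* **Planted networks.** Communities are compact grid clusters (all
  intra-community Cα pairs under 5 Å, clusters 7 Å apart at their closest
  faces) joined only through bridge residues placed between consecutive
  clusters within ~3.8 Å of the facing grid layers. Displacements follow a
  block correlation structure (within-community, between-community, and
  bridge levels), verified positive semi-definite before sampling —
  violations are rejected with the offending block named. By construction
  every inter-community shortest path crosses the bridge, so the bridge
  must emerge as the top betweenness hotspot downstream; this is the
  package's strongest self-test.

What the generators do **not** emulate: real backbone geometry beyond Cα
spacing, side chains, secondary-structure-specific contact patterns,
anisotropic or correlated experimental noise, and predictor failure modes
other than a low-confidence track. Passing tests therefore demonstrate the
correctness of the computations and the recoverability of planted signal —
not that any predictor's real ensembles have these statistics.

# Numerical choices and degenerate inputs

* Superposition is the SVD form of the Kabsch fit with the determinant
  correction, so reflections are excluded; fewer than 3 points or a
  collinear selection is an error.
* PDB coordinates carry 3 decimals and B-factors 2; round-trip tests
  assert at exactly these precisions. B-factor columns outside [0, 100]
  are not interpretable as pLDDT and are dropped with a warning rather
  than clamped.
* Merging requires identical residue sets, or a common intersection
  covering at least 90% of every input (performed with a warning);
  anything less is an error naming the mismatch. Correspondence is by
  residue id, never by sequence alignment — all ensembles in scope share
  one numbering frame.
* Kernel densities use Scott's-rule bandwidth $\sigma n^{-1/5}$; a
  zero-variance sample degenerates to a delta-like spike with a warning.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; sub-seeds are derived arithmetically (never from
  global state), and all derived seeds stay below $2^{31}$.

# Problem sizes

The test suite and demo pipeline run at sizes chosen for the signal they
must exhibit: full 287-residue chains wherever the kinase numbering frame
matters (classification, mutation mapping), 1000-model mixtures for
population recovery (binomial bands at 3 SD), 500-model ensembles for
correlation recovery (±0.1 at $\rho = 0.5$), ≤ 8-node graphs for exhaustive
path-enumeration oracles, and a 100-residue chain for the end-to-end demo
so that community detection — the most expensive stage, at one shortest-path
recomputation per removed edge — completes in seconds.

# Known limitations

* Girvan–Newman with full recomputation scales poorly beyond a few hundred
  edges; for larger networks, betweenness and bridgeness remain fast (the
  C++ kernel is $O(N^3)$) but community detection becomes the bottleneck.
* The analytic-Gaussian mutual information is exact only for Gaussian
  displacements; strongly non-Gaussian motion (multi-modal loops) is
  better served by the k-NN estimator and more models.
* TM-score optimization is a heuristic; it matches the direct formula on
  its own fit and is invariant under rigid motion, but global optimality
  is not certified.
* The front-end plans predictor jobs; it cannot validate that an external
  runner honored the subsampling settings. The manifest echoes them so
  provenance survives the round trip.
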