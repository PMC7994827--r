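---
title: "Flexibility, coupling and hinge-shift design with hingeshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility, coupling and hinge-shift design with hingeshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingeshift)
```

## The model

`hingeshift` treats a protein as an elastic network of residues: one node
per residue at its C$\alpha$, harmonic springs between every pair within a
distance cutoff. Near equilibrium, linear response theory gives the
displacement field caused by a small force $\mathbf{F}$ applied at one
site as $\Delta\mathbf{R} = \mathbf{H}^{-1}\mathbf{F}$, with $\mathbf{H}$
the $3N\times3N$ network Hessian. Because $\mathbf{H}^{-1}$ (through its
six-zero-mode pseudo-inverse) is, up to a constant, the equilibrium
positional covariance $\mathbf{G}$, the same response can be read from a
covariance matrix estimated from a coordinate ensemble —
$\Delta\mathbf{R} = \mathbf{G}\mathbf{F}$. This is what makes the analysis
applicable both in *ENM mode* (a single structure, harmonic approximation)
and in *trajectory mode* (an ensemble carrying whatever anharmonicity and
chemistry the sampling engine produced).

Perturbation response scanning (PRS) applies unit forces at every residue
in turn and records the magnitude of the response everywhere, averaged
over force directions. The entry $(i,j)$ of the response matrix is
$|\Delta R^j|_i = \sqrt{\langle(\Delta R)^2\rangle}$, the root mean square
response at $i$ over unit forces at $j$. For a force uniform on the unit
sphere the average has a closed form: with $\mathbf{B}$ the $3\times3$
block of $\mathbf{G}$ coupling residues $i$ and $j$,
$E\,|\mathbf{B}\hat f|^2 = \mathrm{tr}(\mathbf{B}^{\mathsf T}\mathbf{B})/3$.
`response_matrix()` uses this deterministic form by default; the
`monte_carlo` mode draws explicit random kicks and is kept as an
independent cross-check (the two agree to well under 1% at $M = 10^5$
kicks per site in the test suite) and as the literal implementation of
random-force averaging.

Two indices condense the response matrix:

* **DFI**, $\mathrm{DFI}_i = \sum_j |\Delta R^j|_i \,/\,
  \sum_{i,j} |\Delta R^j|_i$, the fraction of the total response carried
  by residue $i$. It sums to 1 by construction. Percentile-ranked within
  one protein it becomes %DFI; residues with %DFI below the hinge
  threshold are *hinges*, the rigid nodes that coordinate collective
  motion.
* **DCI**, the response of $i$ to a designated functional set relative to
  its response to all sites; the pairwise form
  $\mathrm{DCI}_i^j = |\Delta R^j|_i / (\sum_j |\Delta R^j|_i / N)$
  scores individual partners and is compared via percentile rank (%DCI).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 13 Å | ENM contact cutoff; large enough that C$\alpha$ networks of folded proteins are connected and free of spurious zero modes |
| `gamma` | 1 | spring constant; DFI/DCI are ratios, so a uniform rescaling cancels exactly (tested to 1e-9) |
| `hinge_threshold` | 0.2 | %DFI below which a residue is a hinge |
| `dci_threshold` | 0.8 | %DCI at or above which two residues count as coupled |
| `darc_band` | (0.3, 0.5) | open %DFI band defining mid-flexibility DARC candidates |
| `min_active_distance` | 8 Å | minimum C$\alpha$–C$\alpha$ distance from the active site for a DARC spot (strictly greater) |
| window sizes / lag / burn-in | 25–100 / 25 / 100 ns | trajectory-mode windowing; profiles for production use come from 50 ns windows |
| `zero_tol` | 1e-10 | relative eigenvalue tolerance separating rigid-body modes from internal modes |

The coupling rule in this literature is usually stated loosely, as a %DCI
of roughly 0.8; software needs an executable rule, so the package hardens
it to $\ge 0.8$ on
percentile-ranked pairwise DCI and exposes the threshold. Percentile ties
take the maximal (count-at-or-below) rank, which is conservative for hinge
calls: a tied group only counts as hinges if the whole group is rigid
enough. Pairwise %DCI is ranked within each perturbed site (column-wise
over $\mathrm{DCI}_i^j$) by default, i.e. "which responders does
perturbing site $j$ reach most strongly"; whole-matrix ranking is
available via `dci_scope = "all"`.

## Hinge classification and the mutation sets

Given flexibility profiles of an ancestor A and a descendant B and a
pairwise global alignment (Needleman–Wunsch, BLOSUM62, gap open 10 /
extend 0.5 — or a user-supplied mapping table, since alignments of
divergent pairs deserve manual control), each aligned pair is classified
as a *common hinge* (hinge in both), *non-common* (hinge in exactly one)
or neither, and flagged as sequentially conserved or not. The four classes
partition the aligned positions.

The selection rules follow the design logic of hinge-shift engineering:

* **Set X** targets the hinge shifts themselves: non-conserved positions
  that are hinges in exactly one protein — covering both hinge-gain and
  hinge-loss — and that are coupled (%DCI $\ge$ 0.8, evaluated in the
  descendant's coupling matrix) to at least one other non-common hinge.
* **Set Y** targets compensation: non-conserved *common* hinges coupled to
  non-conserved non-common hinges, evaluated in the ancestor's matrix
  since the design perturbs the ancestor. A `manual_include` hook lets the
  designer force an eligible common hinge into the set (e.g. to balance
  the spatial distribution of substitutions); ineligible manual positions
  are rejected loudly, never silently.
* **Set Z** targets allostery: DARC spots, mid-flexibility residues
  (open band 0.3 < %DFI < 0.5, hence never hinges themselves) that are
  distal from the active site (> 8 Å minimum C$\alpha$ distance) yet
  coupled to *conserved* non-common hinges — the hinges one cannot reach
  by direct substitution because the amino acid is identical in both
  proteins.

Evidence (coupling partners, %DCI values, active-site distances) is
recorded per selected position, and `design_report()` enforces that the
three sets are disjoint.

Where the coupling matrices feed each rule was a genuinely open design
point; the package uses the descendant's matrix for X (the rule asks which
descendant hinges communicate) and the ancestor's for Y and Z (the design
perturbs the ancestor), and says so in the report metadata.

## Trajectory mode and convergence

Ensemble covariances are estimated on overlapping windows: after
discarding a burn-in, windows of a given length start every `lag` ns; all
frames of a window are Kabsch-superposed (proper rotations only) onto the
window's first frame using backbone heavy atoms, and the population
covariance of the C$\alpha$ coordinates is taken about the *window mean* —
the fit frame only fixes the rotational gauge, while fluctuations are
defined about equilibrium. Window arithmetic is exact: times must be whole
frame counts (a mismatch is an error, never a silent round), and the
window count is $\lfloor (T - \text{burn} - W)/\text{lag} \rfloor + 1$.

Convergence is decided by computing one mean DFI profile per window size
and requiring every pairwise Pearson correlation to reach a threshold
(default 0.9). Converged sampling only guarantees that the profiles share
their qualitative features across window sizes; a numeric rule is
required for software, so the correlation threshold is the package's own
quantification and is exposed in the config. A constant profile (zero variance) makes the
correlation undefined and is reported as not converged with a diagnostic.

Two properties of this diagnostic are worth knowing, and the synthetic
fixtures demonstrate both. A *basin hop* — the mean structure jumping
partway through the trajectory — is caught decisively: windows straddling
the hop absorb the displacement into apparent variance, and window sizes
mix straddling and pure windows in different proportions, so the mean
profiles disagree. The non-stationary test fixture hops a 3-residue lid by
12 Å halfway through (a deliberately strong positive control on a
10-residue toy, where estimation noise is itself a few percent) and fails
convergence at the 0.9 threshold. A pure *covariance switch* with an
unchanged mean, by contrast, is only weakly visible: every window size
averages pure windows from both regimes to nearly the same mixture
profile. The test suite asserts only that the switch lowers the minimum
correlation relative to the stationary case; users should not expect this
diagnostic to flag subtle covariance drift.

## Profile clustering

Percentile-ranked profiles of $m$ proteins are stored as columns of an
$n \times m$ matrix over the positions aligned across *all* proteins.
`svd_reduce()` computes $X = U\Sigma V^{\mathsf T}$ and embeds the
proteins as $X^* = V^*\Sigma^*$ over the $r$ leading components
(default 2). `center = TRUE` (default) subtracts the per-position mean
first — the standard PCA biplot; `center = FALSE` decomposes the raw
matrix, reproducing the uncentered formulation exactly. Both are exposed
because PCA biplots and uncentered SVD recipes coexist in this
literature; neither mode is claimed as canonical. With
full rank and no centering the embedding is an isometry of the raw
columns (tested to 1e-9), so distances never depend on the decomposition,
only on the truncation. Component signs are fixed (largest-magnitude
loading positive) so embeddings are bit-reproducible. Dendrograms use
average linkage — the linkage was unstated in the source analysis, and
average linkage is the common choice for profile distance matrices — and
export to Newick via `ape`.

## Synthetic fixtures: what they do and do not show

All tests run on generated fixtures: an ideal $\alpha$-helix (rise 1.5 Å,
100°/residue, radius 2.3 Å, giving the canonical ~3.8 Å C$\alpha$
spacing), a jittered chain, and a two-domain topology with a wide-pitch
helical linker (a straight linker would carry spurious zero modes —
beads whose contacts are collinear or coplanar have free perpendicular
displacements). "Mutants" are emulated by scaling the spring constants of
all contacts of selected positions; this is the minimal perturbation with
an exact ground-truth covariance. Gaussian ensembles drawn from a known
$\mathbf{G}$ (through its symmetric square root, optionally composed with
random rigid motions) let every trajectory-mode stage be checked against
the generating truth: at $10^4$ frames the recovered DFI profile sits
within a few percent L1 of `dfi(G_true)`, rigid motions included
(`scripts/acceptance.R` reports the value measured for a given seed).

The hinge-shift pair (`hinge_shift_pair()`) stiffens a moderately flexible
block adjacent to one hinge core (positions 12–14 of a 40-residue helix,
×10) and softens the other hinge core (30–33, ×0.1). Because %DFI is a
rank, gaining hinge status requires changing *relative* response — a
single stiffened site embedded in a collectively moving region barely
moves in rank, which is itself a faithful feature of elastic networks.
The chosen configuration follows the design narrative the method itself
uses (moderate-flexibility sites rigidify; strong hinges soften in
compensation) and robustly flips all perturbed positions across the 0.2
threshold.

What passing these tests shows: the estimators, rules and bookkeeping are
implemented correctly and are self-consistent down to independent oracles.
What they do not show: anything about force-field realism, side-chain
chemistry, solvent, or whether an ENM covariance matches an MD covariance
for a given real protein — trajectory mode exists precisely so that users
can supply ensembles with better physics.

## Numerical choices and degenerate inputs

* Rigid-body modes are removed by eigenvalue threshold
  ($10^{-10}\lambda_{\max}$); more than six near-zero modes means a
  disconnected or geometrically degenerate network and is an error that
  suggests a larger cutoff, never a silent projection.
* Kabsch superposition disallows reflections (determinant +1) and rejects
  collinear fit sets; planar sets are accepted — the determinant
  constraint makes the planar optimum unique, and rejecting rank-2 sets
  would refuse legitimate inputs.
* Altlocs resolve to highest occupancy then first listed; insertion codes
  are distinct residues; HETATM records are ignored (the model is
  C$\alpha$/backbone coarse-grained); residues without a C$\alpha$ are
  skipped with a warning.
* All randomness (Monte-Carlo kicks, ensemble sampling, chain jitter)
  flows through one seeded entry point and restores the caller's RNG
  state.
* Problem sizes in the tests — 10–40-residue fixtures, $10^4$-frame
  ensembles, $10^5$ Monte-Carlo kicks — were chosen as the smallest scales
  at which each property is cleanly measurable; each assertion states its
  tolerance next to the scale it was measured at.

## Known limitations

* ENM mode shares the limits of harmonic, C$\alpha$-level models: no
  chemistry, no anharmonicity, and mutation effects only through spring
  scaling. Production analyses of real proteins should use trajectory
  mode with externally generated ensembles.
* The convergence diagnostic is insensitive to covariance switches that
  preserve the mean (see above).
* The selection rules operate on percentile ranks, so they are
  scale-free but also blind to absolute flexibility differences between
  proteins.
* mmCIF and binary trajectory formats are out of scope; multi-model PDB
  is the ensemble interchange format.
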