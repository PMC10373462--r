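---
title: "Methods: trajectory statistics for cryptochrome mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory statistics for cryptochrome mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crytraj)
```

## Scope and model

`crytraj` judges whether single point mutations (W→F along the
tryptophan tetrad, Y319F) perturb the structure and dynamics of avian
cryptochrome 4a in molecular-dynamics trajectories. The battery is:
global backbone RMSD as a stability gate; correlation times of site
center-of-mass (CoM) motion; block-subsampled per-residue RMSF;
hydrogen-bond occupancies; inter-site distances; water exposure; and
relative aromatic plane angles. The conservation module adds the
cross-species view: per-site amino-acid composition on a protein or
codon alignment.

All of these are estimators on a common data model: a fixed topology
(atom names, elements, author residue numbers, masses from a built-in
element table) plus an ordered stack of coordinate frames in Å with a
frame spacing in ns. PDB files carry no time axis, so the spacing is
always supplied by the caller or config. Residue numbers are taken
verbatim from the input and never renumbered; atom indices are 1-based,
as is idiomatic in R.

## Units, defaults, and what they mean

| Parameter | Default | Meaning |
|---|---|---|
| `frame_spacing` | 0.1 ns | time between stored frames |
| neighborhood radius | 10 Å | residues pooled with a site for CoM motion |
| `n_blocks` | 20 | trajectory blocks for error bars (500 ns → 25 ns blocks) |
| H-bond distance | 3.0 Å | donor–acceptor heavy-atom separation |
| H-bond angle | 20° | max deviation of D–H···A from linear |
| water radius | 5.0 Å | shell for water-exposure counts |
| `max_lag` | 10% of series | longest autocorrelation lag retained |

The block count of 20 reflects the usual compromise for 500 ns
productions: blocks of 25 ns are an order of magnitude longer than the
site correlation times (1–10 ns), so per-block statistics are treated as
independent draws; `suggest_block_scheme()` warns whenever a block is
shorter than 2 τ_c.

## Superposition and RMSD

RMSD is computed over backbone atoms (N, CA, C, O) by default. Whether
frames should be rigid-body superposed before Eq-style RMSD is a genuine
convention choice: without superposition the series includes diffusive
tumbling of the whole protein, which says nothing about internal
stability. The default is therefore `align = TRUE` (Kabsch
superposition on the same selection, SVD with a determinant guard so
reflections are never returned); `align = FALSE` is available for the
literal fixed-axes reading. The reference is the first frame by default,
configurable; for RMSF an explicit `reference_coords` matrix can stand
in for the minimized pre-production structure when it is not part of the
trajectory — the reference convention visibly shifts the plateau (a
stationary process fluctuating with per-coordinate sd σ sits at σ√3
about its own mean but at σ√6 relative to a random reference frame).

## Correlation times

The motion signal for a site is the length of the CoM vector of the
site's backbone atoms together with the backbone atoms of all amino-acid
residues within 10 Å. Two conventions are deliberate here:

- **Frozen neighborhood.** The 10 Å membership is evaluated once at the
  reference frame and kept fixed, so the series is a function of one
  atom set and the autocorrelation is well defined. A dynamic set would
  inject membership-switching noise into the very signal being
  analyzed.
- **Origin.** Coordinates are first expressed relative to the
  whole-backbone CoM of the same frame, removing rigid drift;
  `origin = "raw"` restores box coordinates.

The autocorrelation uses the unbiased 1/(T−h) lag normalization of the
mean-centered series, divided by the lag-0 autocovariance — the form
under which C(0) = 1 holds identically and an alternating series gives
exactly −1 at lag 1. Constant series raise an error rather than
returning NaN. Lags are truncated at 10% of the series length by
default; beyond that the estimator variance dominates.

Fitting uses a sum of three exponentials with hard constraints: weights
live on the simplex via a stick-breaking parameterization (so Σ Aᵢ = 1
holds exactly, not approximately), and decay times are positive and
bounded by the fitted lag window through a scaled-logistic
parameterization — a decay slower than the observed window is not
resolvable from it, and leaving τ unbounded lets a vanishing weight on
an enormous τ absorb long-lag noise and corrupt τ_c. For the same
reason the fit window adapts: the curve is cut at 10× the lag where it
first drops below 1/e (`fit_window = "full"` disables this). Multi-start
Levenberg–Marquardt from a deterministic log-spaced grid of decay-time
pairs makes the fit reproducible without randomness; the reported r² is
the coefficient of determination over the fitted lags. The cumulative
correlation time is the weight-averaged decay time τ_c = Σ Aᵢ τᵢ.

On the synthetic study conditions (four-residue units, 50,000 frames at
0.1 ns, σ = 0.5 Å, τ ∈ {1, 2, 5, 10} ns) this recovers τ_c with a
median relative error of about 5%.

## RMSF, distributions, and Gaussian fits

Per residue and block, RMSF is the root of the mean squared displacement
of the residue's backbone atoms from the reference, averaged over block
frames; the profile reports mean and sd across blocks plus the pooled
all-frame value, which by construction satisfies the identity
pooled² = mean over blocks of (per-block RMSF²) when blocks tile the
trajectory evenly (trailing frames are dropped with a warning).

"The residues around a site" is ambiguous between sequence neighbors
and the spatial 10 Å set, so both ship: `sequence_10` takes the ±5
sequence window minus the site itself (topped up from the other side at
chain ends, so 10 residues are kept where the chain allows), and
`radius_10A` takes the frozen spatial neighborhood. Outputs record which
mode produced them.

Distribution fits (RMSF samples, distance densities) are least-squares
Gaussian fits to binned densities: Freedman–Diaconis binning with a
fixed 30-bin fallback, deterministic moment-based initialization (median
split for two components), weights on the simplex, and a floor on fitted
sds to keep degenerate point masses from collapsing the optimizer. Two
components are retained only when they improve r² by ≥ 0.05 — double
Gaussians are the exception, used when a second mode is visible, not the
rule.

## Hydrogen bonds

Donor/acceptor chemistry is data, not code: a TSV resource lists heavy
atoms and their attached hydrogens per residue type, with `*` rows for
the backbone amide and carbonyl of any standard residue and an editable
cofactor block (FAD), so new chemistry requires no code change. The
default criterion reads "within 3 Å" as the donor–acceptor heavy-atom
distance and "deviation ≤ 20°" as the D–H···A angle measured at the
hydrogen; both conventions vary between scripts in the wild, so
`distance_mode = "hydrogen"` and `angle_vertex = "donor"` (where the
ideal angle is 0° rather than 180°) are exposed as flags. Intra-residue
pairs are excluded, as are heavy-atom pairs closer than 1.8 Å — the
covalent-adjacency guard; no bond perception is attempted beyond it.
Water–water bonds are skipped unless requested. Occupancy tables list
only pairs observed at least once (a never-seen pair is absent, not 0%),
and per-residue averages count both donor and acceptor roles.

## Geometry

Inter-site distances default to side-chain heavy-atom CoMs — the
electron-transfer-relevant moieties — walked along the transfer chain:
d1 FAD–W395, d2 W395–W372, d3 W372–W318, d4 W318–W369, d5 W318–Y319,
d6 FAD–W369. These endpoint definitions are interpretive defaults, fully
overridable, and every report prints the definitions used. Plane angles
use three side-chain atoms per residue (Trp CG/CD2/CE2, Phe and Tyr
CG/CE1/CE2, FAD N5/N10/C4A), take the angle between plane normals and
fold it into [0°, 90°] since planes are unoriented; collinear triplets
exclude the frame with a warning and a count. Water counting applies the
any-atom rule — a water molecule counts once per frame if any of its
atoms is inside the radius.

## Conservation

Composition is tabulated over sequences with a non-missing state at the
column: gaps, X, ambiguity codes and (for codon alignments) non-ACGT or
incomplete codons leave the denominator and are tallied separately,
and stop codons are treated as missing. A column is conserved when
exactly one state is observed; codon-level conservation implies
amino-acid conservation, never the reverse. A ≥50% sequence-presence
filter is available but off by default. dN/dS estimation is out of
scope — the module prepares per-site tables, it does not test for
selection.

## Synthetic data: what it emulates, and what it does not

The generators stand in for undeposited 500 ns trajectories. Each is a
pure function of its arguments including the seed (RNG state is scoped,
so callers' streams are untouched), and each returns a manifest that
fully determines the expected analysis result: the OU generator records
the per-residue displacement series, the H-bond scene the exact
satisfying frame set, the water shell the per-frame counts, the ring
pair the per-frame folded angle, the toy alignment the realized state
matrix.

Residue motion is a stationary Ornstein–Uhlenbeck process per residue —
exact discretization, not Euler, so the target autocorrelation
exp(−Δt/τ) and stationary sd σ hold at any frame spacing. Defaults
mirror the study conditions: 0.1 ns spacing, correlation times of order
1–10 ns, sub-Å amplitudes. What the generators do not emulate: force
fields, solvent boxes, anharmonicity, coupling between residues,
conformational transitions, or FAD photophysics. Passing the recovery
tests therefore demonstrates that the estimators are correct on
processes with known statistics — not that any particular biological
conclusion transfers to real trajectories.

Tolerances in the recovery tests come from the generating model
(binomial 3σ bands for occupancies and alignment fractions, Monte-Carlo
moments for RMSF), computed in the test code rather than hard-coded.

## Problem sizes

The test suite and acceptance script run on deliberately modest sizes:
50,000-frame single-site trajectories for correlation-time recovery
(20 of them), 10,000 frames for RMSF and Gaussian recovery, 1,000-frame
H-bond and ring scenes, and a 322-sequence toy alignment. These sizes
put estimator noise well below the tested tolerances while keeping a
full run in tens of seconds.

## Pipeline conventions

`run_pipeline()` executes stages in dependency order (correlation times
feed the block-scheme check) with stage isolation: a failing stage is
recorded with its message and the remaining stages still run; the run
errors only when every variant fails. The comparison table mirrors the
wild-type-versus-mutant framing — per metric, both values and their
difference — and deliberately applies no hypothesis test: the
field's practice here is overlap of block-sd error bars, and the table
carries the block provenance needed to read it that way. Reruns under
the same config are deterministic.

## Known limitations

- PDB and DCD only; no PSF/force-field parsing, so masses come from
  elements and the covalent guard is distance-based.
- The hydrogen-bond module requires hydrogens in the topology; donors
  with no resolvable H are skipped and tallied, not inferred.
- Correlation-time estimates degrade when τ approaches the trajectory
  length divided by ~50; the block-scheme warning is the guard rail.
- The two-component Gaussian fit is a density fit, not a mixture model
  with responsibilities; heavily overlapping modes resolve poorly.
- The comparison table quantifies differences; it does not decide
  significance.
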