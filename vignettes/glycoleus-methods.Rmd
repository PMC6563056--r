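---
title: "Methods: enhanced sampling and NMR back-calculation in glycoleus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced sampling and NMR back-calculation in glycoleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glycoleus)
```

`glycoleus` analyses the conformational ensembles of small
O-glycopeptides — GalNAc α- or β-linked to Ser/Thr dipeptide models —
through enhanced sampling on dihedral coordinates and back-calculation
of NMR observables. This vignette documents the model, every tunable
parameter, the synthetic systems used for validation, and the design
choices made where the methodology leaves the design open.

## The sampling model

All ensembles live on named periodic dihedral angles, stored in
degrees in the half-open canonical range [−180°, 180°). (Glycosidic
maps are often drawn on [0°, 360°]; that is a presentation choice, not
a storage convention — one internal convention prevents wrap bugs.)

Synthetic ensembles are generated by a Metropolis chain targeting
exp(−[U_surface + U_bias]/k_B T). Surfaces are sums of wrapped 2D
Gaussian wells (nearest-image distance per dimension, so periodicity
is exact to machine precision) plus optional cosine torsion terms
k(1 + cos(mθ − θ₀)). The proposal perturbs every angle independently
by a uniform deviate in ±`step_size` with periodic wrap — the simplest
proposal that is symmetric on the torus. Defaults: T = 300 K,
`step_size` = 30°, `record_every` = 10 steps. Identical seeds give
bit-identical trajectories; a non-finite energy aborts with a
diagnostic rather than sampling garbage.

These surfaces stand in for the molecular Hamiltonian behind the real
glycopeptide free-energy maps: they reproduce the features that
matter to the analysis code (periodicity, multiple basins separated by
multi-k_BT barriers, tunable well depths/widths) and are integrable by
1°-grid quadrature, which supplies an exact reference density for
every test. They do **not** emulate solvent, real force-field
energetics, or kinetics — passing tests demonstrate the correctness of
the sampling and analysis machinery, not the accuracy of any force
field on real data.

## Local elevation with umbrella sampling (LEUS)

The build-up phase (`le_build`) grows a memory bias on an
N_g × N_g grid over one angle pair. The standard discretisation is
N_g = 36 bins, basis width σ = 360°/N_g = 10°, and a force-constant
increment c = 0.005 kJ/mol deposited into the occupied bin at every
deposition event. The basis functions are wrapped Gaussians of
standard deviation σ centred at the bin centres, so the bias is
smooth, strictly periodic and non-negative; a continuous basis avoids
Metropolis artifacts at bin edges that a piecewise-constant bias would
create. Bookkeeping is exact: the total accumulated weight equals
(number of depositions) × c.

Deposition cadence is one deposition per sampler step by default and
configurable (`deposit_every`), since an MD implementation might
deposit per pairlist update instead; the cadence changes only how fast
the bias converges, not its fixed point.

In the umbrella phase (`us_sample`) the biases are frozen — the
sampler never mutates bias weights (guaranteed by copy-in semantics
and asserted by tests) — and one or more biases on disjoint angle
pairs contribute additively. The per-frame total bias energy is
recorded with the trajectory; it is the sufficient statistic for
unbiasing.

## Reweighting and free-energy maps

Unbiased expectations use weights w_i ∝ exp(+U_bias,i / k_B T),
normalised, with the maximum bias subtracted before exponentiation to
guard overflow. k_B is fixed at 0.0083144621 kJ/(mol·K). The Kish
effective sample size 1/Σw² is carried with every weight vector.

Free-energy maps bin an angle pair into an n × n weighted histogram
(bin j covers [−180 + jΔ, −180 + (j+1)Δ); 36 bins i.e. Δ = 10° by
default, matching N_g) and set G = −k_B T ln P on visited bins. The
global minimum over visited bins is anchored at exactly 0 kJ/mol;
unvisited bins carry NA and a FALSE mask entry, never a fake zero.
Contour plots use 5 kJ/mol spacing. The separate occurrence-colouring
export (`occurrence_map`) uses a 6° grid and clamps negative ln P to
zero; that clamp applies only to the colouring export, never to G.

Uncertainties are four-block errors throughout: the trajectory is cut
into four equal contiguous blocks, the weighted average is recomputed
per block (weights renormalised within the block), and the standard
deviation of the four block means is reported. Fewer than four frames
make the block error undefined, which is reported as NA with a
warning, not silently as zero.

Hamiltonian reweighting composes exp(−ΔU/k_B T) for a dihedral-term
perturbation ΔU(θ) = Σ Δk(1 + cos(mθ − θ₀)) with the umbrella
unbiasing factor when present. A candidate whose effective sample size
falls below a configurable floor (default 50) triggers a warning; in
the Monte Carlo parameter search such candidates are scored infeasible
(+∞), never silently accepted. The search objective is the sum of
squared J-coupling deviations (Hz²) plus λ times the sum of squared
propensity deviations, λ = 100 by default — chosen so that a 0.1
propensity error and a 1 Hz coupling error carry the same weight; both
the weight and the objective form are package choices, documented and
configurable, since no canonical objective exists for this
reparametrisation problem. The search itself is a seeded uniform
exploration of the bounded Δk box followed by Gaussian refinement
around the incumbent (σ = box width/10); with targets generated from
the ensemble itself, the null perturbation is evaluated first and is
exactly optimal.

## NMR observables

**J couplings.** Karplus relations J(θ) = a cos²θ + b cosθ + c are
evaluated per frame on the raw structural dihedral shifted by the
relation's offset, and the per-frame J series is then averaged —
never the Karplus of the mean angle, which the nonlinearity would
bias. The five shipped presets cover ³J_HNHα (6.51, −1.76, 1.60 Hz on
(CX−N−Cα−C) − 60°), ³J_HNH2 (9.6, −1.51, 0.99 Hz on
(C7−N2−C2−C1) + 60°) and ³J_HαHβ (9.5, −1.6, 1.80 Hz on N−Cα−Cβ−O1
with offsets −120° for Thr and 0°/−120° for the two Ser protons).
Every ensemble average necessarily lies inside the closed-form range
of its relation, which the tests assert.

**Virtual sites.** United-atom carbons carry no explicit hydrogens, so
NOE protons are constructed geometrically: CH gets one H at 0.10 nm
along the negative resultant of the unit vectors to its three heavy
neighbours; prochiral CH₂ gets two distinguishable sites (suffix 1/2)
in the plane bisecting its two heavy neighbours with a tetrahedral
H−C−H angle — swapping the neighbour order swaps only the labels, so
the Ser Hβ2/Hβ3 stereo-assignment is a labelling convention; applying
the opposite experimental assignment means swapping the two Ser
Karplus presets. CH₃ is represented by a pseudo-site at the carbon
with a +0.03 nm correction added to measured distances. The r⁻⁶
average over an explicit rotating methyl sits ~0.03 nm *closer* than
the carbon, so the +0.03 nm correction makes pseudo-distances a
conservative upper estimate (it can only under-call, never over-call,
an NOE violation); tests bound the discrepancy against an explicit
three-proton rotor swept over 360°.

**NOE scoring.** Ensemble distances are ⟨r⁻⁶⟩^(−1/6) (adequate for
these fast-tumbling solutes, whose rotational correlation times are
~0.5 ns). Violations are one-sided against experimental upper bounds,
max(0, computed − bound), and flagged significant at 1 Å. The
shipped reference table (`galnac_noe_reference()`) contains the
experimental bounds and published ensemble averages for the four
GalNAc model systems; its violation columns are deliberately absent
and always recomputed. Distance *distributions* report the weighted
arithmetic mean — a deliberately different statistic from the r⁻⁶
average.

## Conformational analyses

**Hydrogen bonds**: d(H···A) < 0.25 nm and ∠D−H···A > 135°, weighted
occurrence per donor/acceptor pair; the 2% reporting threshold is a
report filter only. **Propensities**: the α/β/P_II boxes shipped as
defaults (β: φ∈[−180,−100) ∧ ψ∈[50,180)∪[−180,−150); P_II:
φ∈[−100,−20) ∧ ψ∈[50,180); α: φ∈[−160,−20) ∧ ψ∈[−120,50)) are a
package choice — the literature uses several conventions — made
consistent with the conventional φ-bin splits at −100° and 0°; all
edges are half-open so the four labels partition the map exactly and
propensities sum to 1 under any weighting. **Clustering**: pairwise
all-atom RMSD after least-squares superposition on a fit selection
(backbone plus sugar ring atoms by default; the rotation is the
Kabsch-equivalent least-squares optimum, via `bio3d::fit.xyz`), then
greedy largest-neighborhood assignment at a 0.1 nm cutoff with ties
broken by the lowest frame index — sizes are non-increasing by
construction. **Coverage curves** restrict the *single* full
clustering to each time prefix and count the clusters needed to cover
99/95/75/50% of the prefix; re-clustering every prefix is the other
defensible reading, and the restricted-membership reading was chosen
because it is monotone in the data and far cheaper. **Rotational
correlation**: the autocorrelation of P₂ (NMR-relevant; P₁ available)
of the angle between v(t₀) and v(t₀+t), averaged over origins, fitted
to A·exp(−t/τ) + c by Levenberg–Marquardt with the plateau level and
1/e crossing as starting values. A non-decaying ACF (static vector) is
flagged unresolvable instead of returning a number.

## Numerical choices and degenerate inputs

* Histogram bin j covers [−180 + jΔ, −180 + (j+1)Δ); angles exactly at
  180° wrap to −180°.
* Weight vectors are normalised to sum 1 within 1e−12; maps always
  contain at least one exactly-zero bin.
* Zero LE build steps is a valid no-op: the umbrella phase then runs
  with a zero bias and the pipeline flags the run as unflattened
  rather than failing.
* Empty trajectories, unresolvable atom names, overlapping bias pairs,
  nonpositive NOE distances and unknown templates are rejected with
  the offending name in the message.
* The model-geometry builder uses idealised internal coordinates
  (0.153 nm C−C, 0.147 nm C−N, 0.143 nm C−O, 0.123 nm C=O, 0.100 nm
  X−H; tetrahedral/planar angles) and reproduces requested dihedrals
  to below 1e−6°; exact force-field geometry is out of scope.

## Problem sizes

The validation suite runs at desk scale, chosen so the full test suite
finishes in about a minute while every stochastic check retains a
comfortable margin: LE builds of 1e5 steps and umbrella runs of 1e6
steps for the free-energy closure (the reweighted two-basin gap
recovers the 3 kJ/mol quadrature reference within three block errors),
4e5-step ensembles for the Hamiltonian-reweighting total-variation
bound (< 0.05 at matched sampling), 3e5-step ensembles for the
planted-Δk recovery (within 20%), 100 random frames for the
hydrogen-bond brute-force equivalence, 1000 random ensembles for the
r⁻⁶ bound checks, and 20 000-frame series for the rotational-diffusion
recovery (τ = 1/(6 D_r) within 20%).

## Known limitations

* The toy sampler is Monte Carlo, not dynamics: no velocities, no
  thermostat, no kinetic information beyond the synthetic rotational
  diffusion generator.
* Explicit solvent — and with it water-bridged hydrogen bonds — is out
  of scope.
* Single-window exponential reweighting is used throughout; multi-window
  estimators (WHAM/MBAR) are not implemented.
* Uncertainties are four-block errors only; they underestimate when a
  block is shorter than the slowest relaxation.
* The shipped propensity boxes and CH₃ distance correction are
  documented package choices, not universal constants; both are
  configurable.
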