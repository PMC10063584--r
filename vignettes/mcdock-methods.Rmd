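---
title: "Multicanonical dynamic-docking analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicanonical dynamic-docking analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdock)
```

## The problem

Intrinsically disordered peptides that bind cryptic pockets pose a double
sampling problem: the ligand has no fixed fold, and the receptor's binding
site is closed most of the time. Plain canonical molecular dynamics at room
temperature gets trapped; raising the temperature destroys the very
ensembles one wants to study. Multicanonical sampling resolves this by
simulating a *modified* energy surface on which the potential-energy
histogram is flat across a wide temperature range (here 280–700 K), so the
system diffuses freely across barriers, and by *reweighting* the resulting
ensemble back to any canonical temperature afterwards. `mcdock` implements
the full analysis pipeline around this idea — bias estimation and
flattening, reweighting, free-energy landscapes over a distance-array PCA,
cluster free energies with contact-similarity merging, refinement and
stability scoring, and dissociation-pathway extraction — exercised on
coarse-grained toy systems with analytic oracles rather than on all-atom
trajectories.

## The multicanonical machinery

### Bias construction

The sampler targets $\exp[-E_{mc}(E)/RT_{mc}]$ at the sampling temperature
$T_{mc}$ (= the top of the temperature range, 700 K). The ideal mapping is
$E_{mc}(E) = RT_{mc}\ln n(E)$ with $n$ the density of states, for which the
energy histogram is exactly flat. `mcdock` estimates it iteratively:

1. a canonical seed run at $T_{high}$ gives
   $\ln n(E) = \ln P_{T_{high}}(E) + E/RT_{high}$ up to a constant, so the
   first estimate is `update_bias()` applied to the identity mapping;
2. each subsequent multicanonical run adds the flattening correction
   $RT_{mc}\ln P_{obs}(E)$, smoothed by a weighted spline, so over-sampled
   energies are penalized; a flat histogram is a fixed point.

Outside the canonical mean-energy window
$[\langle E\rangle_{T_{low}}, \langle E\rangle_{T_{high}}]$ (estimated by
reweighting the current run) the mapping continues with canonical tail
slopes $T_{mc}/T_{low}$ below and $T_{mc}/T_{high}$ above. Without these
tails a flattened bias lets a low-dimensional system random-walk to
arbitrarily extreme energies. The mapping is stored on a grid with linear
interpolation and linear extensions, evaluated identically in R and in the
C++ kernel, and is kept monotone non-decreasing (enforced after each
update).

One genuine limitation follows from monotonicity: a *one*-dimensional
double well has inverse-square-root density-of-states singularities at its
well minima, so $\ln n(E)$ is non-monotone and no monotone bias can flatten
its histogram to the 20% tolerance. Reweighting is unaffected (weights use
the actual bias, flat or not; the 1-D reweighted energy distribution agrees
with quadrature to a KS distance of about 0.02), so the 1-D well remains
the reweighting testbed while the 2-dof well — whose singularities are
integrated out — is the flattening testbed, converging to a max/min bin
ratio ≤ 1.2 within 8 iterations.

### Reweighting

Per-snapshot weights at temperature $T$ are
$w_j \propto \exp[E_{mc}(E_j)/RT_{mc} - E_j/RT]$, log-sum-exp stabilized
and normalized. Weights are per snapshot, not per energy bin, because every
downstream probability (landscape bin, cluster mass) is a plain sum of
member weights. The effective sample size $1/\sum w_j^2$ is always
attached; below 100 a warning is raised, since reweighted expectations then
rest on too few effective observations.

### Sampler

The engine is single-particle Gaussian-move Metropolis Monte Carlo (C++
kernel, self-contained xoshiro256+ generator seeded per trajectory from the
base seed and trajectory index, so runs are bitwise reproducible and
independent of R's RNG). Metropolis was chosen over a Langevin integrator
because its stationary distribution is exactly canonical — every analytic
test (equipartition, Boltzmann ratios, quadrature densities) then probes
the theory, not a discretization error. Analytic gradients for every term
are still provided (and tested against finite differences) for quench-mode
minimization. Default step size 0.35 Å gives 40–65% acceptance on the
bundled systems.

## Landscapes, clusters, representatives

Features are inter- and intramolecular atom-pair distances (sequence
neighbors within ±3 excluded for intramolecular pairs), which need no
superposition and respect periodic boxes via the minimum-image convention.
PCA is computed on the raw multicanonical ensemble; reweighting enters only
through the bin probabilities $P_i = \sum_{j\in i} w_j$ and
$\mathrm{PMF}_i = -RT\ln P_i$, minimum-shifted to zero with a 5 kcal/mol
display cutoff. Eigenvector signs are fixed (largest-magnitude loading
positive) so scores and landscapes are reproducible run to run. The default
grid is 100×100 bins over the score range padded by 2%.

Clustering uses K-means with k-means++ seeding (10 restarts, best inertia)
on the leading components covering >90% of the variance; the production
convention is $k'=1000$, scaled down to $\min(1000, n/10)$ for desk-scale
ensembles. Cluster free energies are $-RT\ln P_{k'}$ ranked ascending; one
representative per cluster is the member nearest its centroid (ties to the
lowest snapshot index). Representatives are then merged greedily in rank
order whenever the contact-preservation similarity (R-value) against an
already-retained representative exceeds 0.7 — masses add, the more stable
representative keeps its snapshot — and representatives below 2.5 kcal/mol
form the stable set.

The R-value itself is the fraction of the reference structure's contacts
preserved in the query, over heavy-atom pairs within 4.5 Å (intramolecular
pairs exclude sequence neighbors within ±2). The exact published contact
definition is not reprinted in the methods literature this follows, so the
atom-pair/4.5 Å choice is documented and configurable; it satisfies every
property the analysis relies on (identity = 1, range [0,1], per-residue
decomposition whose contact-weighted mean is the global value, asymmetry
between query and reference).

## Refinement, stability, pathways

Stable representatives are refined by canonical runs at 300 K with the
docking-era restraints removed; the refined structure is the pooled-tail
frame nearest the mean (the "final 40 ns of 100 ns" convention generalizes
to the final 40% of arbitrary trajectory lengths). Stability is the mean ±
sd across trajectories of the tail-averaged R-value against the starting
representative, at 300 K and 400 K with paired seeds.

The dissociation pathway splits the ligand center-of-mass coordinate
$\lambda$ (along the exit axis, restrained to [-2.5, 40] Å) into contiguous
2.5 Å windows and, walking outward from a bound start, picks in each window
the snapshot maximizing the R-value to the previous pick (ties: lower
ligand RMSD in the receptor frame, then lower index — a total order, so
paths are deterministic). Steps with R below 0.6 are flagged as putative
barrier crossings. No free-energy pre-filter is applied to window members.

## Structural observables

Secondary structure follows the Kabsch–Sander electrostatic hydrogen-bond
energy ($0.084\cdot332\cdot(1/r_{ON}+1/r_{CH}-1/r_{OH}-1/r_{CN})$, bond
below −0.5 kcal/mol; amide H placed 1 Å from N along the preceding C=O
direction), with α-helix from two consecutive 4-turns, 3₁₀ from 3-turns,
strand from bridge patterns, everything else coil. "Helicity" counts class
H only by default (strictest reading; H+G available via an argument).
Concordance with a reference DSSP implementation on deterministic backbone
fixtures (ideal helix, 3₁₀, extended, random coil built by
`build_peptide()`) is 100% after mapping to the four classes; the reference
labels are frozen as a plain-text fixture so the check runs offline.

Solvent accessibility is Shrake–Rupley with a deterministic golden-spiral
point set (960 points, probe 1.4 Å) over bundled Bondi radii. RASA — the
ligand's accessible area in the complex relative to the same conformation
isolated — is a pure burial measure; an extended-chain reference would
conflate burial with conformational change.

## The synthetic systems and what they do (not) show

`make_double_well()` provides the analytic testbed: quartic double well
(barrier 4 kcal/mol ≈ 7 RT at 280 K, asymmetry 1 kcal/mol, minima ±1.5 Å),
with a quadrature oracle for canonical means, energy distributions, well
populations and per-bin PMFs.

`make_cryptic_toy()` plants the mechanism ingredients of coupled folding
and binding at a cryptic site: four collinear attraction sites (P1
innermost … P4 outermost, 2 Å apart, depth = `coupling` = 3 kcal/mol,
width 1 Å) in a groove along x; a gate bead over the inner groove in a
y-double-well whose closed state is favored by `gate_bias` = 1.5 kcal/mol
and whose closed position sterically occludes the three inner sites (P4 is
accessible in either gate state — in the real system the outer sub-pocket
is the only one reliably formed without ligand); and a six-bead ligand
chain with weak 1-3 stiffness (0.3 kcal/mol/Å²) that is disordered free
and straightened ("folded") by the collinear sites when bound. The energy
scales were chosen once so that 300 K binding is stable but reversible and
700 K is fully disordered. Its oracle verifies by quenching that the global
minimum is simultaneously bound, gate-open and folded, and supplies labels
(bound below λ = 12 Å; folded when every 1-3 distance exceeds 80% of the
straight-chain value — a one-sided straightness criterion matched to the
chain's thermal fluctuations).

`make_planted_ensemble()` draws snapshots from binding modes with known
300 K masses, sampled with *equal* counts and per-mode energies chosen so
that reweighting the (identity-bias, 700 K) ensemble to 300 K recovers the
planted masses — reweighting is genuinely exercised, not bypassed. Modes
are bead-to-anchor assignments on well-separated anchors, so the pairwise
contact overlap between modes (and hence merge behavior) is exact by
construction.

What passing these tests shows: the estimators, transformations and
decision rules are correct on systems where the truth is computable. What
it does not show: force-field accuracy, solvent effects, sampling
convergence on rough all-atom landscapes, or any biological conclusion —
those depend on the simulation data fed in, not on this code.

## Numerical choices and degenerate inputs

* Gas constant fixed at 1.98720425864083×10⁻³ kcal/mol/K in one place.
* Energy-histogram bin width: 0.5 kcal/mol default; 0.1 kcal/mol
  (≈ RT₂₈₀/5) for the 1–2 dof wells, whose whole canonical range spans
  under 2 kcal/mol and would otherwise fall into one or two bins.
* Empty histogram bins inside the sampled range are bridged by
  interpolation with a warning; fewer than 5 occupied bins aborts with
  advice to lengthen the seed run.
* K-means ties, representative ties and pathway ties all break to the
  lowest index, making every pipeline stage deterministic under a fixed
  seed; the end-to-end report is byte-reproducible.
* Empty clusters are flagged and excluded from CFE tables; windows without
  snapshots abort pathway extraction with their bounds (the pipeline
  truncates the window list at the first empty window instead).
* Problem sizes in the tests and the acceptance script — 10⁵-frame
  reweighting runs, 600-snapshot planted ensembles, 20-seed pathway
  replicates, k' up to 1000 on 2×10⁴ frames — were chosen as the smallest
  sizes at which the statistical tolerances are comfortably resolved.

## Known limitations

* Single-bias reweighting only; combining runs under different biases
  (WHAM/MBAR) is out of scope.
* The Metropolis engine has no inertia; kinetics and rates are meaningless
  here, only ensembles matter. Transition-path or committor analysis is
  deliberately absent.
* The 8-class DSSP vocabulary beyond H/G/E (turns, bends, π-helix,
  isolated bridges) is not assigned; those classes map to C.
* The cryptic toy is a mechanism analog, not a molecular model: its
  "helicity" is chain straightness, and its gate is a single bead.
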