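---
title: "Dynamic residue interaction networks: model, parameters and design notes"
author: "mdrin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic residue interaction networks: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrin)
```

## The problem

Multi-domain redox chaperones of the thioredoxin fold — four domains in an
a–b–b′–a′ arrangement, catalytic cysteine pairs in a and a′ — interconvert
between "open" and "closed" conformations depending on the redox state of
the a′-domain disulfide. Comparing an oxidized and a reduced MD ensemble of
such a protein raises two questions this package answers at different
resolutions:

1. **Collective motion**: which domain-scale motions dominate, and how do
   their amplitudes and populations differ between states?
2. **Interaction persistence**: which individual residue–residue contacts
   are held in one state and released in the other?

The second question is the package's core contribution; the first is the
standard essential-dynamics stack needed to put the second in context.

## The lifetime statistic

Per frame $t$, a typed residue interaction network is built from geometric
criteria (below), giving binary series $A_{ij}(t)$ per residue pair and
interaction type. The pair's weight in the state's dynamic network is its
*maximum interaction lifetime*

$$\Gamma_{ij} = \max\,\{\tau : \exists\,\tau_0 \text{ with } A_{ij}(t)=1
\ \forall\, t \in [\tau_0, \tau_0+\tau-1]\},$$

the longest unbroken run of on-frames. This deliberately differs from
*occupancy* (the fraction of on-frames): a contact flickering on half the
time scores low, a contact held continuously for half the trajectory scores
high. For a pair that is never on, the window set is empty and $\Gamma = 0$
— this boundary case is adopted explicitly and such pairs are dropped from
the compiled graph. When a state is sampled by several independent
trajectories, $\Gamma$ is computed per trajectory and the maximum is taken:
a "consecutive" run spanning the splice point between two independent
simulations would be an artifact, so runs never cross trajectory
boundaries.

The two states are contrasted by the shrunken log fold change

$$\Delta_{ij} = \log_2\frac{\Gamma_{ij}^{ox}+\varepsilon}
{\Gamma_{ij}^{red}+\varepsilon},$$

computed over the union of the two edge sets. Internally this is evaluated
as a difference of logarithms, which makes the state-swap antisymmetry
$\Delta \mapsto -\Delta$ hold bitwise, not just to rounding.

**Parameters.** $\varepsilon$ (frames, default 1) bounds $|\Delta|$ at
$\log_2(T+1)$ for a $T$-frame ensemble and makes the statistic a
well-behaved shrunken fold change; it is recorded on every differential
graph. The significance cutoff on $|\Delta|$ defaults to 1 — a two-fold
persistence change — and should always be reported alongside results.
$\Gamma$ is stored in frames; any frame-to-time conversion is metadata the
user supplies, since a fixed frame spacing is not something the package can
infer.

## Interaction criteria

The five interaction types are decided by documented, user-overridable
geometric rules (`interaction_criteria()`, shipped as a versioned YAML in
`inst/extdata/`): hydrogen bond — donor–acceptor heavy-atom distance
≤ 3.5 Å plus a D–H···A angle ≥ 120° whenever a donor hydrogen is modeled
(heavy-atom-only fallback otherwise); salt bridge — charged-group centroid
distance ≤ 4.0 Å between Arg/Lys/His⁺ and Asp/Glu groups (His is treated as
protonated, a stated assumption); van der Waals — heavy-atom distance below
the element radii sum + 0.5 Å; π-π — aromatic ring-centroid distance
≤ 6.5 Å; cation-π — cation center to ring centroid ≤ 6.0 Å. Pairs closer
than 2 in sequence are never reported, since covalent neighbors are not
non-covalent contacts. These are literature-standard cutoffs chosen for
transparency and testability; they are *not* a re-implementation of any
particular contact-detection program, and numerical agreement with such
programs is not a goal.

## Essential dynamics choices

* **Superposition and PCA** act on Cα atoms; "backbone" RMSD uses N, Cα, C,
  O when present and falls back to Cα-only on coarse topologies. The fit
  selection defaults to the b/b′ base domains, which anchor terminal-domain
  hinge motions.
* **DCCM** uses the standard normalized displacement covariance
  $C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
  \sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$; atoms
  with zero displacement variance get undefined (NA) rows rather than a
  silent 0/0. The implementation is cross-checked in the test suite against
  an independent DCCM implementation (bio3d).
* **PCA** is computed by singular value decomposition of the centered
  coordinate matrix; degenerate directions carry zero eigenvalues instead
  of failing, eigenvalue sums equal the total coordinate variance to 1e-6
  relative, and projections have exactly diagonal covariance.
* **Free-energy landscapes** use a Gaussian-kernel density estimate on a
  component plane, $F = -\ln(p/p_{\max})$, so the global minimum is 0 and
  units are $k_BT$ without committing to a temperature. Bandwidth defaults
  to the normal-reference (Scott-type) rule per axis and is always recorded
  on the grid object. Basins are read off as strict local minima over the
  8-neighborhood below an `f_max` depth.
* **Torsions** follow the IUPAC right-handed sign convention with range
  (−180°, 180°]; the convention is pinned by tests against an independent
  torsion implementation, including the sign.
* Domain centers are unweighted Cα centers of geometry. Center-of-mass over
  all heavy atoms would be a defensible alternative; Cα-only keeps a single
  atom convention across centers, superposition and PCA.

## State classification

The linear discriminator scans every midpoint of consecutive sorted unique
training values (plus the two extremes), in both inequality directions, and
picks the training-accuracy maximizer; ties prefer the larger margin, then
the direction placing "ox" above the threshold. It is exactly equivalent to
the brute-force scan (a property the tests assert on a thousand random
inputs) and, being rank-based, invariant to monotone feature transforms.
The non-linear comparison uses `e1071::svm` with its default radial-basis
parameters (cost 1, γ = 1/p); the defaults are recorded on the returned
accuracy. Train/test assignment is a single independent coin flip per
snapshot — not cross-validation — so both classifiers are evaluated on the
same held-out half. When no split is given, training accuracy on all data
is reported as such; both conventions are available because single-feature
threshold accuracies on all data versus held-out data answer slightly
different questions.

## What the synthetic generator emulates — and what it does not

`make_hinge_trajectory()` builds domains as compact Gaussian blobs of Cα
pseudo-atoms (sd 4 Å) spaced 30 Å apart on a line; the terminal domain
rotates rigidly about a hinge axis through the boundary between the last
two domains by `amplitude * sin(2πt/T)`, and every atom receives
independent Gaussian jitter per frame. Scripted interactions attach typed
pseudo-atoms (donor/acceptor/charged-center/ring-centroid) whose partner
moves in and out of the geometric criterion exactly on scheduled frames, so
the detection stage recovers the scripted series verbatim. Default
conditions: 4 domains × 25 residues, amplitude 20°, jitter 0.1 Å, and
two-state feature mixtures with a unimodal shifted pair
(N(0,1) vs N(2,1), Bayes optimum Φ(1) ≈ 84.1%) and a state-bimodal pair
(N(0,1) vs ½N(−4,1)+½N(4,1)) — the mechanism by which a radial-basis SVM
outperforms any single threshold.

This emulates *kinematics and bookkeeping*, not physics: there is no force
field, no solvent, no realistic contact chemistry, and the sinusoidal hinge
explores its range far more evenly than a thermally activated system would.
Passing tests therefore demonstrate that the statistics are computed
correctly and recover planted ground truth; they do not certify behavior on
real trajectories, where convergence, protonation assignment and criterion
sensitivity all matter and should be examined per system (the
eigenvector-overlap check is the built-in tool for the first of these).

## Numerical and degenerate-input choices

* One master seed expands into fixed per-operation substreams, so each
  stage is independently reproducible and the full pipeline is
  byte-identical under one seed (tested on the exported GraphML).
* Schedules with target longest run $L$ and total on-count $m$ are feasible
  iff $T - m \ge \lceil m/L\rceil - 1$; infeasible requests are rejected,
  never silently adjusted.
* Coincident or collinear domain centers make an angle or torsion undefined
  for that frame; the value propagates as NA rather than an arbitrary 0.
* Multi-model PDB readers validate per-model atom counts up front and name
  the offending frame; writers round-trip coordinates to the format's
  1e-3 Å precision. TSV writers use shortest-round-trip number formatting,
  so read-back equals source exactly.
* Problem sizes used throughout the tests and the acceptance script —
  2,000-frame hinge ensembles, 1,000-frame scripted interaction recovery
  over 20 pairs per state, 10,000 samples per class for classifier
  calibration — were chosen as the smallest sizes at which the statistical
  assertions have comfortable margins under the generator's defaults.

## Known limitations

* Contact detection is geometric only: no energies, no solvent-mediated or
  probe-based contacts, no disulfide tracking, and His is always treated as
  protonated for salt bridges.
* The residue discrimination matrix fits one threshold per pair without
  multiple-testing control; it is a ranking device, not an inference
  procedure.
* The FEL is a density transform, not a thermodynamic calculation; basins
  are only as real as the sampling, and no barrier or path analysis is
  offered.
* DCD/XTC binary trajectory containers are not read directly; convert to
  multi-model PDB upstream.
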