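---
title: "Estimating ligand-binding kinetics with Markov state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ligand-binding kinetics with Markov state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandmsm)
```

## The estimation problem

High-throughput binding simulations produce thousands of short trajectories
of a ligand — a metal cofactor, a charged substrate — diffusing around a
receptor. No single trajectory samples the full binding/unbinding
equilibrium, so the rates and the standard free energy of binding have to
be reassembled statistically. A Markov state model does this by
discretizing conformational space into microstates and estimating the
transition probability matrix $T(\Delta t)$ at a lag time $\Delta t$; the
master equation $\mathrm{d}p/\mathrm{d}t = pK$ with
$T(\Delta t) = e^{K\Delta t}$ (row convention: $T_{ij}$ is the probability
of state $j$ at time $\Delta t$ given state $i$) then yields equilibrium
populations (the unit left eigenvector $\pi$), relaxation timescales
$\tau_s = -\Delta t / \ln\lambda_s$ from the subunit eigenvalues, mean
first passage times (MFPTs), and committor probabilities.

This vignette records the modelling choices behind each pipeline stage,
the parameters a user is expected to touch, and what the synthetic
benchmarks do and do not establish.

## Featurization

Frames are encoded as binary protein–ligand contact maps: one feature per
receptor reference atom (alpha-carbons in a typical setup), set to 1
exactly when the minimum Euclidean distance from that atom to any ligand
heavy atom is strictly below the contact cutoff (default 8 Å). Boxes with
several ligand copies are split into one trajectory per (run, ligand
copy): an approximation that treats copies as independent reporters of the
same single-ligand process, justified when inter-ligand interactions are
transient (charged ligands repel each other) and required to convert
per-copy binding times into bimolecular rates.

Coordination flags mark frames where the ligand's phosphate group lies
strictly within 4 Å of a declared catalytic ion. Both cutoffs are strict
inequalities; distances are plain Euclidean by default, with an optional
minimum-image mode for cubic periodic boxes (imaging conventions vary
across trajectory post-processing tools, so the simpler contract is the
default and the periodic mode is explicit).

## TICA

Time-lagged independent component analysis solves the generalized
eigenproblem $C(\tau)v = \lambda C(0)v$ with mean-free covariances pooled
over trajectories. Choices:

* **Symmetrized estimator**, $C(\tau) = \tfrac12\langle x_t x_{t+\tau}^\top
  + x_{t+\tau} x_t^\top\rangle$: guarantees a real spectrum regardless of
  sampling noise.
* **Ridge regularization** $C(0) + \varepsilon I$ with $\varepsilon =
  10^{-6}\,\mathrm{tr}\,C(0)/F$: binary contact columns are frequently
  collinear.
* **Constant columns dropped** (recorded in the model so the transform
  stays consistent), and the **lag must be an integer multiple of the
  frame spacing** — no interpolation, so results are bit-reproducible.
* Components are normalized against $C(0)$, giving unit-variance
  projections; no kinetic-map rescaling is applied (plain eigenvector
  projection).

The default lag is 2 ns and the default dimension 3 (5 is typical for
substrate pathway analyses with more complex state structure); both are
ordinary config parameters. For a state-jump process observed through
isotropic noise, the leading TICA eigenvalue is the propagator eigenvalue
diluted by the noise fraction of the variance — the test suite checks this
closed form rather than the bare eigenvalue.

## Discretization

k-centers follows the Gonzalez max-min rule: a seeded uniform draw picks
the first center, every subsequent center is the frame farthest from its
nearest existing center, and the covering radius is reported.
Deterministic for a fixed seed, and ties in the nearest-center assignment
go to the lowest center index. The cluster count is a required parameter:
appropriate values depend on the data volume and the dimensionality of the
projection, so no default is imposed.

Clusters observed with both coordination-flag values are split in two
(`n_microstates = k + #mixed`); splits are based on observed flag values
only, so empty microstates are never created. Splitting happens before
transition counting, so the flag distinction is available to the MSM at
every lag.

## Reversible MSM estimation

Transition counts use a sliding window (every frame pair $(t, t+\tau)$
within a trajectory), the standard choice that maximizes data use and is
consistent with the likelihood. Counting never crosses trajectory
boundaries. Estimation is restricted to the largest strongly connected
component of the count graph; frames outside it are excluded from
downstream population sums.

The reversible maximum-likelihood transition matrix maximizes
$\sum_{ij} C_{ij}\log T_{ij}$ under detailed balance via the standard
self-consistent fixed point on symmetric auxiliary variables
$x_{ij}=x_{ji}$, $T_{ij} = x_{ij}/\sum_k x_{ik}$, iterated until the
maximum relative change falls below $10^{-12}$ (cap $10^6$ sweeps).
The tests compare it against an independent generic optimizer of the same
constrained likelihood and require agreement to $10^{-8}$.

Implied timescales are $\tau_s = -\Delta t/\ln\lambda_s$ for eigenvalues
in $(0,1)$; eigenvalues within $10^{-12}$ of 1 report $\tau = \infty$ and
non-positive eigenvalues report no timescale. The lag scan re-counts and
re-estimates at each lag on the set of microstates active at every lag and
suggests the smallest lag whose slowest timescale changes by less than 10%
to the next lag — the usual "timescales stop depending on the lag"
criterion. Published analyses choose the lag per system from such scans;
the package therefore treats the MSM lag as a required parameter rather
than guessing one.

## Macrostates and kinetics

PCCA+ lumps microstates using the top-$M$ right eigenvectors: their rows
lie approximately in a simplex whose vertices are the metastable sets; the
inner-simplex construction picks the $M$ most extreme rows as vertices,
memberships are barycentric coordinates clipped to $[0,1]$ and
renormalized, and crisp assignments take the maximal membership (ties to
the lower index).

**Choosing $M$.** $M$ should follow the implied-timescale spectrum: $m$
slow processes separate $m+1$ metastable sets. Asking for more macrostates
than there are slow processes makes PCCA+ grab vertices from fast, noisy
eigenvectors, producing sliver macrostates of negligible population. The
synthetic binding benchmark is the instructive case: its two intermediates
live for fractions of a nanosecond, far below the 2 ns lag, so the
spectrum shows a single slow process and the correct macrostate count is
2, even though the generator has five states. The five-macrostate setting
matches analyses where the intermediates themselves are long-lived enough
to resolve.

Bulk and bound are labelled from a per-microstate contact score (the mean
number of receptor atoms in contact): the macrostate with the lowest
$\pi$-weighted mean score is bulk, the highest is bound; equality is a
degeneracy error rather than an arbitrary pick.

MFPTs solve $m_i = \Delta t + \sum_{j\notin\text{target}} T_{ij} m_j$ with
$m=0$ on the target; source values are stationary-weighted over the source
set (uniform weighting is available by flag). Macrostate passage times are
measured **between macrostate cores** — microstates with PCCA+ membership
of at least 0.9 in their macrostate (falling back to the full crisp set if
a core is empty). Transition-region microstates have memberships near
$1/M$; counting arrival at such a boundary state as arrival in the bound
state systematically shortens the apparent binding time (about 20% on the
binding benchmark), whereas core-to-core passage times track the analytic
ground truth to a few percent.

Rates and free energy follow the standard single-copy relations:
$k_\text{on} = 1/(\text{MFPT}_\text{on} \cdot C_\text{sim})$ with
$C_\text{sim} = n_\text{copies}/(N_A V_\text{box})$,
$k_\text{off} = 1/\text{MFPT}_\text{off}$, and
$\Delta G^0 = RT\ln(k_\text{off}/(k_\text{on} C^0))$ at $C^0 = 1$ M,
$R = 1.9872\times10^{-3}$ kcal/(mol K), $T = 298$ K by default (the
temperature binding simulations are commonly equilibrated at;
overridable). For rare events it is sometimes only possible to measure a
binding frequency; `on_rate_from_frequency()` implements
$k_\text{on} = f/C$. Note that the reciprocal pseudo-first-order time at
concentration $C$ is $1/(k_\text{on} C)$; for
$k_\text{on} = 1.85\times10^5$ M$^{-1}$s$^{-1}$ at 1 mM this is 5.4 ms —
the package implements the reciprocal relation exactly and leaves any
rounding to the caller.

## Bootstrap errors

Following the trajectory-elimination protocol, 7 independent runs each
remove 20% of the trajectories (seeded draw without replacement,
independent across runs) and rebuild everything from clustering onward
with the same parameters; k-centers uses a run-specific seed so the
discretization is genuinely resampled. Reported are mean and **sample
standard deviation** (labelled as such; whether published ± values are sd
or standard errors is often unstated). Runs that lose ergodicity are
skipped with a warning and reported in `n_effective_runs`. Because
re-clustering variability contributes a noise floor, the spread shrinks
with trajectory count somewhat more slowly than $1/\sqrt{N}$; the test
suite asserts the robust qualitative decrease.

## Synthetic benchmarks and their scope

The generator builds trajectories from continuous-time Markov jump
processes (exact Gillespie dynamics discretized on the frame grid,
stationary initial states by default, explicit start states for
binding-time experiments) embedded in feature space as well-separated
centroids plus isotropic Gaussian noise. Three fixed systems ship with the
package:

* `twostate` — slow bulk/bound exchange (mean dwells 20 ns / 50 ns,
  3 mM); used for TICA separation and the exact rate-population
  consistency identity.
* `binding5` — five states mimicking the structure of free-ligand binding
  data: dominant bulk (61% population), an off-pathway interface state
  that only exchanges with bulk, two on-pathway intermediates with sub-ns
  dwells, and a bound state with a 20 ns mean residence (12 mM box).
  Ground truth: MFPT$_\text{on}$ = 113 ns, MFPT$_\text{off}$ = 52 ns,
  $\tau_2$ = 34.6 ns at a 2 ns lag.
* `metastable_blocks` — two weakly coupled three-state blocks
  (0.002 ns$^{-1}$ across versus 0.5 ns$^{-1}$ inside) for macrostate
  lumping tests.

Centroid separations are at least 11 noise standard deviations. That makes
the discretization solvable by construction — the intended role: failures
then indicate estimator defects, not an ambiguous embedding. Real contact
maps are high-dimensional, binary, collinear and far noisier; passing
these benchmarks demonstrates correctness of the estimators, not that any
particular MD dataset is well discretized. The Brownian generator
(Euler–Maruyama with reflecting walls; the well force is the gradient of a
smooth half-cosine ramp over the outer 20% of the well radius, avoiding
force discontinuities) adds a continuous-space testbed whose free-diffusion
and Boltzmann-enrichment statistics are checked against closed forms.

Test problem sizes (e.g. 200 trajectories × 5000 frames for end-to-end
recovery, $10^4$–$10^5$ Monte-Carlo first-passage runs) were chosen so the
statistical tolerances in the tests correspond to ≥3 standard errors while
the full suite stays fast on a single CPU.

## Numerical choices and degenerate inputs

* Rate matrices must conserve probability to $10^{-12}$ (relative);
  off-diagonal negatives are rejected. Absorbing states are allowed in the
  generator (flagged in the output) but stationary draws then fall back to
  uniform initial states.
* Stationary distributions come from direct linear solves (one equation
  replaced by normalization), not power iteration; reducible inputs are
  errors, not warnings.
* Spectral computations on reversible matrices use the
  $\pi^{1/2}$-symmetrized similar matrix, so eigenvalues are real by
  construction.
* The pipeline clamps `tica_dim` and `n_macrostates` to what the data and
  spectrum support, with warnings, rather than failing deep inside a
  bootstrap run.
* All generators and estimators are bit-reproducible for a fixed seed;
  every run directory records the configuration hash, seed and package
  version.

## Known limitations

* Binary contacts only; distance- or Gaussian-valued featurization is out
  of scope.
* No Chapman–Kolmogorov validation plots, Bayesian transition-matrix
  sampling, or hidden Markov models; the bootstrap is the only uncertainty
  channel.
* Real-data input is limited to PDB topologies with DCD coordinate files
  (via bio3d) or the portable CSV+JSON bundle format; XTC files should be
  converted externally.
* The per-ligand independence approximation ignores inter-ligand
  correlations entirely; at high ligand concentrations or with strong
  ligand–ligand association the single-copy concentration conversion
  becomes questionable.
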