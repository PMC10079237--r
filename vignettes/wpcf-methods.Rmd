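---
title: "Weighted pair correlation functions and spatial signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted pair correlation functions and spatial signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(wpcf)
```

This vignette is the package's own account of the statistics and the
simulation model it implements: the assumptions behind each piece, the
tunable parameters and why their defaults are what they are, and the limits
of what the test suite can establish.

## The statistics

### Cross-type pair correlation

For a point pattern in a bounded window of area $A$, with $N_B$ points of a
source category and $N_T$ of a target category, the cross-PCF at distance
band $[r_k, r_k + dr)$ compares the observed density of targets in annuli
centred on source points with the density $N_T/A$ expected under complete
spatial randomness (CSR):

$$ g_{BT}(r_k) \;=\; \frac{1}{N_B N_T} \sum_{i \in B} \sum_{j \in T}
   \frac{A}{A_{r_k}(x_i)} \, I_k(\lVert x_i - x_j \rVert), $$

where $I_k$ is the indicator of the half-open distance band and
$A_{r_k}(x_i)$ is the area of the annulus around $x_i$ *inside the window*.
Values of 1 mean "no correlation"; larger values mean targets cluster at
that distance from sources, smaller values mean exclusion.

Two geometric choices matter:

* **Border correction.** On `clipped` windows, $A_{r_k}(x)$ is computed
  exactly as a difference of two circle–rectangle intersection areas (the
  classical signed decomposition into circle–quadrant areas), not by Monte
  Carlo; the Monte-Carlo estimator survives only as a test oracle. Because
  the correction attaches to annulus *centres*, $g_{BT} \ne g_{TB}$ on
  clipped windows; on `periodic` windows (torus metric, no clipping) the
  statistic is exactly symmetric, which the tests exploit.
* **Binning.** Bins are contiguous and half-open, $r_0 = 0$. The defaults
  `dr = 0.1`, `n_bins = 191` resolve the 0–19.1 cell-diameter range in which
  tumour-scale structure (perivascular niches, exclusion zones of 10–15
  diameters) lives, and set the default signature-vector length below.

### Weighted pair correlation

Categorical cross-PCFs discard the continuous structure of marks such as
macrophage phenotype $p \in [0,1]$. The wPCF replaces the hard indicator on
the annulus-centre population with a weight $w_p(P, p_i)$ measuring how
close a point's mark is to a target mark $P$:

$$ wPCF(r_k, P, B) \;=\; \frac{1}{W_P\, N_B} \sum_i \sum_{j \in B}
   \frac{A}{A_{r_k}(x_i)}\, w_p(P, p_i)\, I_k(\lVert x_i - x_j\rVert),
   \qquad W_P = \sum_i w_p(P, p_i). $$

The default kernel is triangular, $w_p(P,p) = \max(1 - |P - p|/\Delta P, 0)$
with $\Delta P = 0.2$: wide enough that each row pools enough points for a
stable estimate, narrow enough that rows at $P$ and $P \pm 0.2$ are
independent signals. A Gaussian kernel is available as a smooth
alternative, and an indicator kernel realises the $\Delta P \to 0$ limit in
which each row is exactly the cross-PCF of the matching sub-population —
this reduction is asserted in the test suite, as is exact agreement of the
production code with a naive double-loop implementation on small patterns.

Rows of the surface with $W_P = 0$ (no point carries a mark near $P$) are
**undefined** and are carried as `NA` plus an explicit mask — never silently
as 0 or 1, because both are meaningful wPCF values.

The two-mark extension `wpcf_two_marks()` weights both the annulus centres
(towards $P_1$) and the counted points (towards $P_2$), normalised by
$W_{P_1} W_{P_2}$, and is symmetric under swapping the two roles on
periodic windows.

One wording ambiguity had to be resolved: the weighting could plausibly be
attached to either index of the double sum. We attach it to the
annulus-centre index (mark-carriers centre the annuli; the categorical
population is counted), which is the form whose $\Delta P \to 0$ limit
reproduces sub-population cross-PCFs with the correct normalisation.

### Validation patterns

`make_line_pattern()` builds the canonical check: reference points on the
line $y = 1$ and uniformly scattered circles marked with their distance to
that line (or its square). By construction the wPCF towards the reference
category must ridge along $P = r$ (or $P = r^2$); the test suite recovers
the ridge to within $\Delta P$ over $r \in [0.1, 0.8]$, averaged over seeds.
Crosses are placed at $x = (i - \tfrac12)\,\mathrm{edge}/n$ — the midpoint
convention avoids giving the two endpoints double weight. `make_banded()`
generalises the construction to arbitrary mark–distance laws with bounded
noise, so ridge recovery can be tested under controlled degradation, and
`make_csr()` generates the null model (every statistic $\approx 1$).

## The simulation model

The agent-based model is an off-lattice, cell-centre model of a small
(40 × 40 cell diameter) vascularised tissue patch, built to generate
labelled point patterns resembling multiplex images: stromal (S), tumour
(T) and necrotic (N) cells, macrophages (M) with a continuous phenotype
mark, and fixed point vessels (B). Units are one cell diameter, one hour,
and drag = 1, so a force of 1 moves a cell at 1 diameter/hour.

**Mechanics.** Cells interact by linear springs within `r_int = 1.5`
diameters: repulsion (stiffness `spring_k = 10`) below the rest length (sum
of radii), adhesion (stiffness `spring_adhesion = 1`) out to the cutoff.
The two stiffnesses differ deliberately: with equal stiffness, the
long-range attraction of second-shell neighbours exceeds first-shell
repulsion in aggregate and tissue collapses into dense clusters — a known
pathology of single-stiffness linear springs at this cutoff. Positions
follow the overdamped law $\nu \dot x = F$ by forward Euler; within each
event timestep `dt = 0.05` h the stiff spring forces are integrated with
`mech_substeps = 4` sub-steps (the event clocks, fields and chemotaxis are
held at the step resolution). A cell displaced more than one diameter in a
sub-step raises a stability error rather than silently corrupting the
state.

**Fields.** Five diffusibles live on a unit-spacing grid: oxygen (vessels
supply, stromal and tumour cells consume), CSF-1 (tumour-derived,
recruits macrophages), CXCL12 (perivascular, attracts M2 macrophages),
TGF-β (tumour-derived, drives the phenotype transition) and EGF
(M2-derived, attracts tumour cells). Each advances by explicit five-point
diffusion with sub-stepping inside the stability bound, point sources
deposited on nearest grid nodes, and exact exponential integration of the
linear decay term — so a source-free uniform field decays as $e^{-\lambda t}$
to floating precision, which the tests assert, and a single point source
relaxes to the 2-D Green's-function profile $\propto K_0(r\sqrt{\lambda/D})$,
which the acceptance suite checks against the Bessel oracle. Negative
concentrations cannot arise (consumption is a linear sink; the scheme
clamps at zero only against rounding).

**Macrophages.** Extravasation at each vessel is a Poisson-like event with
per-hour probability $P^\star c/(c + c_{1/2})$ in the local CSF-1 level
$c$; newcomers carry phenotype $p = 0$. While local TGF-β exceeds
`g_crit`, $p$ rises at `delta_p` per hour to its cap of 1, irreversibly.
Chemotactic force interpolates with phenotype — $\chi_c^m (1-p)$ up the
CSF-1 unit gradient, $\chi_\xi^m\, p$ up the CXCL12 unit gradient — plus an
isotropic random force of magnitude `random_motility`. Because the unit
gradient is undefined at a flat field, gradients below `grad_tol` (
$10^{-3}$ concentration/diameter) contribute no force; the tolerance is
set well below the CXCL12 gradient scale of the domain interior, which is
small because vessels surround the centre roughly isotropically. A
macrophage within `r_int` of tumour cells kills one, chosen uniformly, with
per-hour probability $P^\star_\varphi (1 - p^{10}/(p^{10} + 0.5^{10}))$ —
maximal for M1, halved at $p = 0.5$, negligible for M2 — then cannot kill
again for `t_cool` hours. Killed tumour cells become necrotic, shrink
linearly over `necrosis_clear_time` and disappear.

**Cell cycle.** Stromal and tumour cells progress their cycle only above
their hypoxia threshold (`omega_H_*`; the pause is reversible) and become
necrotic below their necrosis threshold (irreversible). Tumour thresholds
are lower than stromal ones — tumour cells are the more hypoxia-tolerant
population, and with the vessel-free central margin this puts tissue
oxygen between the two, so stroma is broadly quiescent while the tumour
rim proliferates. Stromal cells additionally pause under mechanical
compression, detected when the effective radius (half the
nearest-neighbour separation) drops below $\sqrt{a^{str}_H}$ of the relaxed
radius. Cycle durations are drawn per cell within 25 % of
`cycle_duration` to desynchronise divisions; daughters appear at a small
random offset and relax mechanically.

**Event probabilities** are `rate * dt` per step, valid for `rate * dt ≪ 1`
and guarded by an explicit error when `p_star * dt` would exceed 1.

### Default parameters and the growth regimes

No external parameter table exists for this model at this scale; the
defaults in `abm_params()` are the package's own, fixed by two
requirements: (i) each mechanism's analytic limit must hold (half
saturation, ramp time, kill curve — asserted in the tests), and (ii) on the
desk-scale domain, 150 simulated hours, the three qualitative regimes of
immune-mediated tumour control must emerge in the corners of the
$(\chi_c^m, c_{1/2})$ plane where they belong, and nowhere else:

* **Equilibrium** (weak CSF-1 chemotaxis, reluctant extravasation —
  e.g. $\chi_c^m = 1$, $c_{1/2} = 0.8$): macrophages spread through the
  stroma, remain predominantly M1, and their contact killing at the tumour
  rim roughly balances rim proliferation; the mass stays compact and clear
  of the vasculature.
* **Escape** (strong chemotaxis, moderate extravasation — e.g.
  $\chi_c^m = 3.5$, $c_{1/2} = 0.7$): macrophages push through the stroma
  into the tumour, where TGF-β converts them; the resulting M2 cells
  migrate towards perivascular CXCL12 while secreting EGF, and tumour
  cells trail the EGF gradient to the vessels — the perivascular-niche
  phenotype. Intravasation itself is deliberately not modelled: cells
  reaching a vessel stay in the domain, and "escape" is detected from the
  final geometry.
* **Elimination** (high extravasation — low $c_{1/2}$): macrophage numbers
  overwhelm the tumour while it is small.

These labels are assigned by `auto_label()`: Elimination at ≤ 5 surviving
tumour cells, otherwise Escape if any tumour cell sits within 1 diameter
of a vessel, otherwise Equilibrium. The thresholds are configuration (they
stand in for a human rater), not biology.

Calibration was done against these qualitative regime identities only —
never against any downstream classification accuracy. Parameters the
regimes pivot on: the stroma acts as a mechanical barrier whose effective
threshold (set by `spring_k` against `random_motility`) separates
$\chi_c^m \approx 1$ (macrophages largely held in the stroma) from
$\chi_c^m \gtrsim 1.5$ (macrophages reach the tumour); `g_crit` is placed
so that TGF-β exceeds it only inside a tumour mass, keeping Equilibrium
macrophages M1; `p_phi_star` is placed so one rim macrophage kills at
roughly the rate one rim tumour cell divides, making the Equilibrium
balance and the Elimination overwhelm both reachable; and the vessel-free
central margin (`vessel_exclusion = 14`) is wide enough that a contained
tumour cannot reach a vessel by growth alone within 150 h, so Escape
requires the migration mechanism.

## The classification pipeline

A snapshot's **PCF signature** is the triple
$\{wPCF(r,p,B),\; wPCF(r,p,T),\; g_{BT}(r)\}$ on shared grids.
`vectorize_signature()` flattens it in a fixed order (vessel-surface rows
mark-major, then tumour-surface rows, then the cross-PCF), giving
$191 \times (2 \times 101 + 1) = 38{,}773$ entries at the default grids.
Undefined entries are imputed with 1 — the CSR no-correlation baseline,
consistent with tumour-free snapshots whose defined statistics hover
around 1 — and the imputation mask is retained so the choice stays
auditable. Imputing 0 instead would fabricate a strong "exclusion" signal
out of missingness.

`fit_reduced_model()` mean-centres the vectors, takes principal components
(up to 100, capped at the rank the training set supports), and fits a
radial-basis-kernel SVM with library-default hyperparameters on the
leading coordinates. PCA identities (orthonormal basis, ordered variances,
zero projection of the training mean, exact full-rank centroid
reconstruction) are asserted in the tests. `centroid_signature()` maps a
class centroid back through the truncated basis and reshapes it into the
signature layout, so the "typical" surface of each regime can be plotted;
`signature_trajectory()` projects a time series of snapshots into the
fitted basis, where a single simulation can be watched drifting between
regimes.

## Problem sizes used by the test and acceptance suites

The package's checks run at desk scale, chosen as the smallest sizes at
which each property is still unambiguous: CSR normalisation with two
populations of 500 on a periodic 40-square over 20 seeds; oracle
equivalence on dozens of ≤ 30-point clouds; border correction against a
$10^6$-sample Monte-Carlo oracle; ridge recovery on the 200 + 1000-point
line patterns over 5 seeds; regime checks with ≥ 5 seeds per parameter
setting at $t_{end} = 150$ h; and a 3 × 3 × 3 sweep for the end-to-end
pipeline (27 simulations, PCA, SVM, held-out accuracy against the
majority-class baseline with positive silhouette in the first three
components). A full-scale replication (hundreds of simulations to
$t = 500$ h on a larger domain) is an HPC exercise, not part of the test
suite.

## What the synthetic data do and do not establish

The generators and the ABM produce point patterns with known ground truth,
which is exactly what validating a spatial statistic requires — the ridge
of `make_line_pattern()` is known by construction, the CSR expectation is
exactly 1, and the ABM regimes are controlled by two parameters. Passing
these tests shows the statistics measure what they claim to measure. It
does **not** show that real multiplex images satisfy the generators'
assumptions: real cell segmentations have position- and
intensity-dependent noise, marker intensities are not calibrated to
$[0,1]$, tissue windows are not rectangles, and cell densities vary by
orders of magnitude across a slide. Applying the pipeline to real imaging
data needs a mark-normalisation and windowing step that is out of scope
here.

## Numerical choices and degenerate inputs

* Bin edges are half-open ($r_k \le d < r_k + dr$); a pair exactly on an
  edge belongs to the outer bin.
* Slices require an exact grid hit by default; interpolation is opt-in.
* Empty populations yield *undefined* results (NA + flag), never
  exceptions, so sweep pipelines keep running through tumour-free
  snapshots.
* `wpcf_slice` at an undefined row returns an all-NA curve.
* The ABM's RNG is a single stream seeded once per run: identical
  (seed, parameters) give bit-identical trajectories, and the fixture
  generators restore the caller's RNG state.
* Degenerate geometry (coincident cell centres) exerts no force — the pair
  direction is undefined — and is resolved by the next random kick or
  division offset.

## Known limitations

* The ABM is 2-D and desk-scale; quantitative regime boundaries shift with
  domain size, vessel layout and $t_{end}$.
* Escape depends on a chain of mechanisms (conversion → CXCL12 homing →
  EGF trailing); it is the most fragile regime and the reason the regime
  tests use seed majorities rather than single runs.
* The SVM uses library-default hyperparameters deliberately (the pipeline
  is a proof of concept, not a tuned classifier); accuracy on small sweeps
  is limited by class imbalance among the 27 runs.
* Marks are one-dimensional; the two-mark wPCF exists, but the two-marked
  *populations* must still be supplied separately.
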