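# wpcf

Spatial statistics for 2-D point patterns whose points carry **both** a
categorical label and a continuous mark — the situation produced by
multiplex-image cell segmentations (cell type plus a continuous marker
intensity) and by agent-based tumour simulations (cell type plus macrophage
phenotype). The package is for quantitative cancer biologists and
modellers who need to ask not just "do cells of type A cluster around
cells of type B?" but "cells with *which marker level* cluster around
type B, and at what distance?"

## What it computes

**Cross-type pair correlation function (cross-PCF).** For source category
$B$ and target category $T$ on a window of area $A$,

$$ g_{BT}(r_k) = \frac{1}{N_B N_T} \sum_i \sum_j
   \frac{A}{A_{r_k}(x_i)}\,\Theta(B, q_i)\,\Theta(T, q_j)\,
   I_k(\lVert x_i - x_j \rVert), $$

with exact analytic border correction $A_{r_k}(x)$ (annulus ∩ window) on
clipped windows and the torus metric on periodic ones. 1 = no correlation,
\>1 clustering, \<1 exclusion.

**Weighted pair correlation function (wPCF).** The cross-PCF generalised
to continuous marks $p_i \in [0,1]$: annuli are centred on mark-carrying
points, each weighted by a kernel $w_p(P, p_i)$ measuring closeness of its
mark to a target mark $P$ (triangular by default,
$w_p = \max(1 - |P-p_i|/\Delta P, 0)$, $\Delta P = 0.2$):

$$ wPCF(r_k, P, B) = \frac{1}{W_P N_B} \sum_i \sum_j
   \frac{A}{A_{r_k}(x_i)}\, w_p(P, p_i)\,\Theta(B, q_j)\,
   I_k(\lVert x_i - x_j\rVert), \qquad W_P = \sum_i w_p(P, p_i). $$

The result is a surface over (distance $r$, target mark $P$) that reads as
a continuous stack of cross-PCFs — one per mark value — with undefined rows
(no points near that mark) carried explicitly as `NA` + mask. A two-mark
variant weights both ends of each pair.

**An off-lattice tumour–macrophage simulator** (`abm_run()`): stromal,
tumour and necrotic cells plus macrophages with a continuous phenotype
mark (0 = anti-tumour M1 … 1 = pro-tumour M2) and fixed point vessels,
coupled to five diffusible fields (oxygen, CSF-1, CXCL12, TGF-β, EGF).
Varying macrophage CSF-1 chemotaxis (`chi_c_m`) and the extravasation
half-saturation (`c_half`) moves the system between tumour
**Equilibrium**, **Escape** (perivascular niches, tumour reaching the
vasculature) and **Elimination** — the three outcomes of cancer
immunoediting.

**A classification pipeline**: each snapshot is summarised as a *PCF
signature* $\{wPCF(r,p,B), wPCF(r,p,T), g_{BT}(r)\}$, flattened to a
38,773-entry vector, reduced by PCA and classified by an RBF-kernel SVM
(`fit_reduced_model()`, `classify_signature()`); time series of snapshots
become trajectories through principal-component space
(`signature_trajectory()`).

## Worked example

The canonical validation pattern: 200 reference points (category `B`) on
the line $y = 1$, and 1000 points (category `M`) scattered uniformly in a
2 × 2 square, each marked with its distance to the line. By construction,
points at distance $r$ from the line carry marks close to $P = r$, so the
wPCF surface must ridge along $P = r$.

```r
library(wpcf)
cloud <- make_line_pattern("linear", seed = 1)
print(cloud)
#> point cloud: 1200 points
#>    B=200  M=1000  S=0  T=0  N=0
#> window [0, 2] x [0, 2] (clipped), area 4

binning <- radial_binning(dr = 0.025, n_bins = 40)
surface <- wpcf(cloud, target = "B", binning = binning)
print(surface)
#> wPCF surface vs 'B': 101 target marks x 40 bins (dr = 0.025), 0 undefined row(s)

# a horizontal slice reads as a cross-PCF for points with marks near 0.3:
slice <- wpcf_slice(surface, P = 0.3)
binning$r_mid[which.max(slice$values)]
#> [1] 0.3875

# the ridge of the surface tracks P = r to within the kernel half-width:
ridge <- surface$p_grid[apply(surface$values, 2, which.max)]
sel <- binning$r_mid >= 0.1 & binning$r_mid <= 0.8
max(abs(ridge[sel] - binning$r_mid[sel]))
#> [1] 0.1375
```

The slice at $P = 0.3$ peaks near $r \approx 0.39$ (points marked 0.3 sit
0.3 from the line, but the *nearest cross* is usually offset laterally, so
the modal pair distance slightly exceeds the perpendicular distance —
visible in the slight upward bow of the ridge), and the argmax ridge stays
within the kernel half-width $\Delta P = 0.2$ of the constructed law.
`plot(surface)` draws the heatmap ($P$ vertical, $r$ horizontal);
`plot(cloud)` draws the pattern.

Simulation and labelling in two lines:

```r
snaps <- abm_run(abm_params(chi_c_m = 3.5, c_half = 0.7),
                 t_end = 150, snapshot_every = 50, seed = 1)
auto_label(snaps[[length(snaps)]])
#> [1] "Escape"
```

## Command line

A thin CLI over the same functions is installed as `exec/wpcf`:

```sh
wpcf fixtures line --variant linear --seed 1 --out pattern.csv
wpcf pcf wpcf pattern.csv --target B --dr 0.025 --nbins 40 --out surface.csv
wpcf abm run --seed 1 --tend 150 --snapshot-every 10 --out run1/
wpcf sweep run --grid chi_c_m=0.5:4.5:3 c_half=0.1:0.9:3 --reps 3 --out sweep/
```

Every run writes a JSON manifest (arguments, seed, version, outputs) next
to its outputs, sufficient to reproduce it exactly.

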