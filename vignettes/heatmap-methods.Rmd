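---
title: "Methods: from trajectory time series to molecular heat maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from trajectory time series to molecular heat maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

poremap ranks molecules in an MD trajectory of a liquid system by how
strongly their local structural changes co-vary with a slow global process.
The machinery assumes nothing about the process beyond two ingredients:

* **Fast variables.** Each pair of representative sites (one characteristic
  atom per molecule: lipid phosphorus, water oxygen) defines a
  minimum-image distance trace $X_{ij}(t)$. Its absolute forward difference
  $r_{ij}(t) = |X_{ij}(t+\Delta t) - X_{ij}(t)| / \Delta t$ is a
  non-negative local rate of change, placed on the midpoint time grid.
  Relative distances are used because liquids offer no global frame of
  reference for superposition; there is nothing to align to.

* **A slow activity** $a(t) \ge 0$, one scalar per frame, describing global
  structural variability. Two sources are built in: the Gaussian-smoothed
  rate of contact-forming or contact-breaking events of a two-cutoff
  distance graph, and a raw unit-cell dimension (during electropore
  formation under NPT the cell compresses along z and elongates in x/y, so
  the box itself marks the pore).

The bridge between the two time scales is a dependence measure $I$ applied
pointwise in time,

$$R(i,j) = I\big(r_{ij}(t),\, a(t)\big),$$

with $I$ either the Pearson cross-correlation or the mutual information.
$R$ is a positive symmetric matrix; because only spatially proximal pairs
are computed it is banded, and its columns compress to their masked average

$$R(i) = \operatorname{mean}_{j:\,\text{computed}} R(i,j),$$

the per-residue *heat*. Sorting heat descending (ties broken by ascending
residue id) ranks molecules by importance for the activity; rankings are
invariant under positive rescaling of $R$, so the overall scale of the
activity (rate vs. count normalization) is immaterial.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `low_cutoff` / `high_cutoff` | 11 / 13 | Å | should bracket the nearest-neighbour distance of the coarse-grained sites; for a lipid phosphorus layer the lower value ≈ 11 Å matters most, the upper is typically 1–2 Å higher and suppresses recrossing noise |
| `smoothing_sigma` | `"auto"` = 5 % of the window | ps | sets the temporal detail of $a(t)$; the 5 % rule of thumb is a good starting point and results are robust in a factor-of-two neighbourhood |
| cull cutoff | none (lipids), 15 recommended for solvent | Å | pairs never within the cutoff in any analysed frame carry no contact signal; culling makes solvent-scale systems (~12 000 sites) tractable |
| stride / window | user | frames | the stride bounds the fastest resolvable variable; windows should isolate the process of interest |

The hysteresis detector is a two-state machine per pair: state PRESENT iff
the distance last crossed below `low_cutoff`, ABSENT iff it last crossed
above `high_cutoff`; distances inside the buffer never change state, so
fluctuations inside `[low, high]` generate no events. The initial state at
the first frame is PRESENT only if $d <$ `low_cutoff`: a trajectory that
*starts* inside the buffer counts as ABSENT, which avoids phantom breaking
events from borderline starting contacts (the alternative convention would
instead emit a breaking event the first time a borderline contact drifts
out, which is noise, not signal).

The smoothed activity is a kernel rate estimate: a unit-mass Gaussian of
standard deviation `smoothing_sigma`, truncated at ±4σ and renormalized, is
placed on each event time, so the time integral of $a(t)$ recovers the
event count. Forming and breaking events are kept separate; during pore
formation breaking activity is sustained and not compensated by forming,
which is why breaking is the default activity source.

## The mutual information estimator

Pearson correlation captures linear co-variation and is cheap, but a
uniform-bandwidth density estimate behind a mutual information estimator
fails on activities that are exactly zero for part of the window — a point
mass defeats any fixed bandwidth. The estimator here is a plug-in
leave-one-out kernel estimator with adaptive per-sample bandwidths:

1. standardize each variable robustly, $(x - \mathrm{median})/(\mathrm{IQR}/1.349)$
   (sd fallback when the IQR degenerates), so the estimate is invariant
   under affine rescaling of either input;
2. evaluate a pilot density with the fixed Silverman bandwidth
   $h_0 = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.349)\,n^{-1/5}$;
3. give the kernel centred on sample $k$ the bandwidth
   $h\,\lambda_k$ with $\lambda_k = (\hat f_{\text{pilot}}(x_k)/G)^{-1/2}$,
   the Abramson square-root law ($G$ = geometric mean of pilot densities,
   $\lambda$ clipped to $[0.05, 20]$ as a numerical guard);
4. form leave-one-out marginal and joint densities with *the same*
   per-variable product kernels and average
   $\log \hat f_{RA}/(\hat f_R \hat f_A)$ over the samples.

Sharing kernels between the joint and the marginals makes the estimator
exactly symmetric in its arguments and cancels most of the bias under
independence; leave-one-out removes the self-term bias. The final global
bandwidth is $h = 0.5\,h_0$. That factor was fixed a priori by bias
arithmetic, not tuned: Gaussian smoothing with bandwidth $h$ inflates the
covariance of a bivariate Gaussian to $\rho/(1+h^2)$, so at $n = 5000$ a
full Silverman bandwidth ($h \approx 0.19$) biases the $\rho = 0.9$ mutual
information by about $-0.13$ nats, while $h \approx 0.10$ keeps the
smoothing bias below $0.05$ nats; functional plug-in estimates tolerate the
extra variance of undersmoothing far better than densities do.

Negative estimates (possible for the plug-in form) are estimation noise and
are clamped to zero, mirroring the treatment of negative Pearson
correlations as a noise-floor measurement. Inputs with zero variance define
dependence 0. Below 50 samples the KDE is unreliable and the estimator
returns 0 with a warning; that floor is necessary, not sufficient — on
heavily zero-inflated activities the leave-one-out plug-in estimate carries
a negative finite-sample bias and typically needs a few hundred samples
before genuine dependence clears the zero clamp (the 500-frame default
synthetic window is comfortably enough; a 120-frame window is not). Pearson
degrades more gracefully at small n. The estimator involves no resampling: results
are run-to-run identical for identical inputs, which makes whole-pipeline
outputs byte-for-byte reproducible.

This adaptive KDE is a functional stand-in for the dedicated
bandwidth-adaptive density estimation solver used by the original analysis
toolchain (published separately); the requirement it satisfies is the same
— bandwidths that adapt to zero-inflated activities — but the internals are
the classical pilot/Abramson construction, and no claim of algorithmic
equivalence is made.

When Pearson is combined with a box-dimension activity, note that Pearson
expects positively co-correlated features: the z dimension *shrinks* during
pore formation, so use the (elongating) x dimension with Pearson; for
mutual information the distinction does not matter, and z is conventional.

## The synthetic generator: what it does and does not emulate

No public MD trajectories exist for the published electroporation systems,
so the package ships a seeded geometric generator whose defaults state the
world the pipeline is tested in: 64 sites per leaflet on jittered square
lattices (8.75 Å spacing) in a 70 × 70 × 120 Å box, 500 frames at a 10 ps
stride, pore onset at frame 300. From onset, the sites found within 12 Å of
the box centre are pushed radially outward by 0.5 Å/frame for 50 frames
(breaking their mutual contacts), while the box follows a linear
volume-conserving schedule (z −0.08 Å/frame, x/y up), applied *affinely* to
the in-plane coordinates the way an NPT barostat rescales positions.
Ground truth (the pore-lining set, the onset time) is recorded exactly.

Two modelling choices deserve explanation:

* **Jitter is stationary vibration, not diffusion.** `jitter_sigma`
  (default 0.3 Å/frame) is the rms magnitude of an independent per-frame
  in-plane displacement about each site's lattice anchor. A cumulative
  random walk at the same per-frame scale would let diagonal lattice
  neighbours (12.4 Å apart, inside the 11–13 Å buffer) drift across the
  thresholds and generate a steady pre-onset event background, contradicting
  the quiescent-then-porating phenomenology the fixture is meant to state.
  Real lipids do diffuse laterally; that feature is deliberately absent, so
  a green end-to-end test establishes recovery of a planted signal over
  *thermal* noise, not over slow contact turnover.

* **Linear deformation schedule.** The real NPT box response is smooth but
  irregular; linearity is sufficient to test the monotone box-activity
  properties and keeps the ground truth trivial to state.

The generator performs no physics — no forces, no electrostatics, no water.
An optional distractor flag displaces one random non-pore site far from its
anchor before onset, emulating outliers not associated with the pore, for
false-positive characterization.

## Numerical conventions

* Units are Å and ps internally; GRO nm values are converted on read.
  Frame indices are 0-based at the interface (with an explicit flag for
  1-based GROMACS-style frame numbers); site/pair indices are 1-based
  inside R.
* Minimum image wraps per axis with `round()` (round-half-to-even); a
  displacement of exactly half a box length is a measure-zero tie whose
  resolution is convention-dependent.
* Distances always use the owning frame's box; trajectories are never
  unwrapped.
* Pair culling is "ever within cutoff over the analysed window": one
  streaming sweep with a per-pair flag. A per-frame mask would change which
  pairs are computed near the cutoff; the window-level reading is the
  package's choice.
* B-factor output rescales each heat map linearly to [0, 99.99] (max →
  99.99, all-zero map → all 0.00); heat values themselves are stored raw
  and rescaled only at visualization.
* Triclinic cells are a hard error everywhere.

## What a green test suite establishes — and what it does not

The acceptance properties verify: exact agreement of the periodic geometry
with brute-force image enumeration; exact agreement of the hysteresis
detector with an explicit state machine; kernel mass conservation of the
activity; exact agreement of the Pearson path with the textbook formula;
recovery of the Gaussian closed form $-\tfrac12\ln(1-\rho^2)$ by the MI
estimator; robustness of the MI estimator to 50 % exact zeros; recovery of
the planted pore-lining set and onset time from the synthetic world by both
dependence methods; and concordance of heat maps across independent
activity sources (graph-breaking vs. box-z). They do not establish
performance on real bilayer MD data — membrane undulations, lipid
diffusion, protonation/force-field artefacts and genuinely ambiguous pore
precursors are all outside the stated synthetic world.

## Known limitations

* Pairwise distance geometry scales quadratically with site count; solvent
  systems need the 15 Å significant-interaction cull to stay tractable.
* Only orthorhombic boxes are supported.
* Alternative activity definitions (Delaunay-type proximity graphs,
  RMS-fluctuation activities that presuppose a global reference frame) and
  basin/quiescent-period segmentation are intentionally out of scope, as is
  any significance testing of $R$ entries: the method ranks raw values.
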