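---
title: "Methods: force-curve mechanics and assay quantification in vsmcq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-curve mechanics and assay quantification in vsmcq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmcq)
```

`vsmcq` quantifies vascular smooth muscle cell (VSMC) mechanics and
signaling from standard laboratory readouts: AFM force curves, Fura-2
calcium traces, fluorescence micrographs, TNBSA plate-reader tables, qPCR
Cq tables and immunoblot band intensities. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The flat-punch indentation model

A cylindrical (flat-punch) tip of radius $a$ indenting a linear-elastic,
incompressible half-space obeys

$$F = \frac{2 a E}{1 - \nu^2}\, d,$$

with Young's modulus $E$ (Pa), Poisson ratio $\nu$ (0.5 for cells) and
indentation depth $d$. Unlike the spherical or conical Hertz variants the
force is *linear* in depth, so at a fixed contact point the modulus is a
one-parameter least-squares slope through the origin — which is what makes
the contact-point grid search below cheap.

The measured quantities are piezo position $z$ (increasing toward the
sample) and cantilever deflection $\delta$; force is $F = k\delta$ after
baseline subtraction, and the indentation is the tip–sample separation

$$d = (z - z_c) - \delta,$$

i.e. piezo travel past the contact point minus the part of it absorbed by
cantilever bending. This correction is essential for soft samples: with
$k = 0.1\,$N/m and $E \approx 600\,$Pa about 2% of the travel goes into
deflection, but for stiff dishes nearly all of it does.

## The force-curve algorithm

For each curve (`fit_young_modulus()`):

1. **Baseline and noise** (`estimate_noise()`): a straight line is fitted
   over the leading `baseline_fraction` (default 0.3) of samples; the force
   noise $\sigma$ is the SD of the residual force. The fitted line is
   subtracted from the whole curve, making the analysis invariant to
   deflection offsets and linear drift.
2. **Experimental contact point** (`find_contact_point()`): the first
   sample whose baseline-subtracted force reaches $3\sigma$ *and* stays at
   or above that threshold for the next `guard = 5` samples. The guard
   rejects isolated noise spikes (a single $\ge 3\sigma$ outlier occurs
   with probability ~0.13% per sample); sustained exceedance was chosen
   over strict monotone growth because the latter is almost surely violated
   by any noise while serving the same anti-spike purpose.
3. **Candidate grid**: contact-point candidates from 50 nm before to 50 nm
   after the experimental contact point in 5 nm steps, inclusive — 21
   candidates.
4. **Window-growing fit** (`fit_window_at_candidate()`): per candidate, the
   fit window starts at `min_window = 10` samples past the candidate and
   grows one sample at a time; at each size $E$ is the origin-constrained
   least-squares slope and the RMSD of fitted force is computed
   incrementally. Growth stops at the last window whose RMSD is within
   $3\sigma$. A candidate whose smallest window already violates the rule
   is infeasible.
5. **Selection**: the feasible candidate with the most data points, ties
   broken by lowest RMSD, then by proximity to the experimental contact
   point, then by grid order (fully deterministic). The complete grid is
   returned for audit.

"Lowest RMSD" was chosen as the tie-break reading of the selection rule
(rather than lowest RMSD *variation* across window sizes), because the
alternative is ill-defined for candidates accepted at a single window size;
the choice only matters for exact ties in the point count.

### The detection offset and the grid half-width

The $3\sigma$ crossing sits systematically *after* true mechanical contact
by $\approx 3\sigma / s_F$, where $s_F = kC/(k+C)$ (with
$C = 2aE/(1-\nu^2)$) is the post-contact force slope per metre of travel.
The candidate grid exists precisely to walk the contact estimate back from
this offset. The two scales should match: the method operates as designed
when $3\sigma/s_F \lesssim$ the 50 nm grid half-width, which for the
default geometry corresponds to baseline noise up to roughly 5% of the
maximal force. Well below that operating point the grid's left edge no
longer reaches the true contact region and recovered moduli acquire a
negative bias of a few percent to ~10%; far above it, contact is detected
too late for the grid to compensate. `grid_halfwidth` is therefore a
config parameter: it should be set to about $3\sigma/s_F$ for the
instrument at hand. Parameter-recovery results in this package are
validated at the 5%-noise operating point, where the median recovered
modulus is within 5% of truth across 200–5000 Pa.

### Numerical choices

* The self-consistent deflection in the generator solves
  $k\delta = C((z - z_c) - \delta)$; because the flat-punch model is linear
  this fixed point has the exact closed form
  $\delta = C(z - z_c)/(k + C)$, which is evaluated directly (no iteration
  residual).
* Both the detection threshold and the RMSD gate use an effective noise
  $\max(\sigma,\ 10^{-7}\max|F|,\ 10^{-18}\,\mathrm{N})$. The relative term
  keeps noiseless synthetic curves well defined: the incremental
  RSS update cancels catastrophically at $\sqrt{\varepsilon} \approx
  10^{-8}$ of the force scale, so the floor sits one order above that and
  still ~5 orders below any real instrument noise.
* Indentations are clipped at $d \ge 0$; samples pulled negative by noise
  contribute their force to the residual but not to the slope.
* On a *perfectly* noiseless curve, only a candidate that coincides with
  the true contact can pass the RMSD gate with contact data; with 5 nm
  sample spacing the grid provably contains the true contact and the fit
  is exact (this configuration is used in the unit tests). This is a
  property of any tolerance-gated grid search, not an implementation
  artifact; real curves always carry noise.

### Cell height and rigidity time courses

Cell height is the difference between mean dish and mean cell contact
positions (`compute_cell_height()`), in nm. With $z$ increasing toward the
sample the cell contact comes first, so `dish - cell` is positive; a
negative result is folded back with a warning and a flag. Noiseless
synthetic pairs recover a constructed height within one sample spacing —
the contact detector always lands on the first sample past contact, and
this one-sample offset cancels between the two surfaces up to their
spacing difference.

Stimulated rigidity is reported as a percentage of the pre-stimulation
control on the ratio convention, $100\,E_\mathrm{post}/E_\mathrm{pre}$
(`rigidity_pct_change()`): an unchanged cell reads 100%, a doubling reads
~200%. The ratio convention (rather than $100(E_\mathrm{post} -
E_\mathrm{pre})/E_\mathrm{pre}$) was chosen because reported control
responses of ~210% with post-stimulation moduli about twice the basal
value are consistent only with the ratio reading.

## Calcium calibration and metrics

The 340/380 nm ratio $R$ maps to free calcium through the standard
saturation equation

$$[\mathrm{Ca}^{2+}] = K_d\,\beta\,\frac{R - R_\mathrm{min}}
  {R_\mathrm{max} - R},$$

with $K_d = 224$ nM at room temperature and literature-typical
$R_\mathrm{min} = 0.8$, $R_\mathrm{max} = 8$, $\beta = 10$ as *defaults
only* — all four constants are mandatory inputs for real data and should
come from an on-instrument saturating-calcium calibration. Ratios outside
$[R_\mathrm{min}, R_\mathrm{max})$ are masked, not clipped: clipping would
silently bias window means.

The four-phase protocol (60 s stabilization, 60 s calcium-free baseline,
180 s agonist stimulation, 150 s calcium re-addition) is segmented at
cumulative boundary times. The three readouts are defined operationally:

* **basal** — mean over the last 20 s of the calcium-free baseline
  (avoiding the medium-switch artifact at its start);
* **release** — stimulation-window maximum minus basal;
* **entry** — mean over the last 30 s of the re-addition window minus the
  mean over the last 20 s of the stimulation window.

Release and entry are differences and thus invariant to additive trace
offsets. All window lengths are arguments.

The synthetic generator inverts the calibration exactly, so the zero-noise
round trip generator → ratio → calibration → metrics is exact to
$<10^{-9}$ nM. Ratio noise defaults to 0.002 ratio units (~0.7 nM at
basal), the scale of ROI-averaged photometry; note that the release
readout is a window *maximum*, whose positive noise bias grows with
per-sample noise, so heavy-noise traces should be smoothed or the peak
estimated differently before trusting mean recovery at the sub-nM level.

## Micrograph quantification

`remove_background()` estimates the smooth background as the greyscale
morphological opening with a disc of the given radius — the flat-disc
approximation of the rolling-ball algorithm, exact for backgrounds that
are flat at the disc scale and agreeing to within the local background
curvature otherwise. The canonical radius for full-frame micrographs is
1000 px; tests use smaller rasters with proportionally smaller radii. A
radius exceeding both image dimensions degenerates to subtracting the
global minimum, with a warning.

White noise is summarized (max, SD) over a user-chosen fluorescence-free
region; the standard cutoffs are 40 grey values for eGFP and 100 for Texas
Red. `integrated_density()` sums pixels *strictly above* the cutoff, so
noise whose maximum equals the cutoff contributes nothing; integer
arithmetic makes the density exactly additive over any image partition and
monotone non-increasing in the cutoff. Output stays in native camera
counts and is never rescaled.

## Plate assays

**TNBSA.** Free-amine molarity comes from a glycine standard line fitted
by OLS (standards and samples share the dilution scheme, so dilution
factors cancel); dividing by the protein molarity (molar mass 66,472 g/mol
for HSA, config-overridable) gives free amines per molecule, and percent
modification is $100(1 - n_\mathrm{free}/83)$ with the denominator
counting 59 lysines plus 24 arginines (the alpha-amino terminus is
excluded from the denominator on purpose). Endpoints are exact and results
outside $[0, 100]$ are clipped with a flag.

**qPCR.** Relative quantities $RQ = E^{\Delta Cq}$ per gene (efficiency
$E$, default 2), normalized per sample by the geometric mean of the
flagged reference-gene quantities. The default calibrator is the per-gene
mean Cq across samples, so changing the calibrator rescales a gene's NRQs
by a single global factor; per-sample global Cq shifts cancel exactly. A
single reference gene is allowed with a warning; three stable genes
(*Tubb5*, *Rpl19*, *Pum1*) are the simulated default.

**Immunoblots.** Lane ratios target/loading, reported as percent of the
series maximum; scale-invariant by construction.

**Group comparisons.** `compare_groups()` is an orchestration layer only:
Shapiro–Wilk per group gates between one-way ANOVA (with Dunnett-vs-control
via `multcomp`, or Bonferroni pairwise t tests) and Kruskal–Wallis with
Dunn's post hoc. Degenerate groups (constant values) fail the gate and are
flagged. The Dunn z statistics (rank sums with tie correction) are the one
statistical primitive computed in-package, as no installed package
provides them; with two groups $z^2$ reproduces the Kruskal–Wallis
statistic, which the tests use as a cross-check. The empirical type-I
error at $\alpha = 0.05$ is verified to sit inside the binomial 95% CI
over 200 simulated null datasets.

## What the synthetic data does and does not show

The generators emulate the *statistical structure* each stage assumes:
linear-elastic indentation with Gaussian force noise and linear drift;
piecewise four-phase calcium kinetics (5 s linear rise, single-exponential
decay, $\tau = 30$ s) inverted exactly through the calibration; constant
background plus Gaussian blobs plus bounded uniform noise; Cq tables with
exact encoded fold changes. Passing recovery tests therefore demonstrates
that the estimators are correct *for data obeying their models*. They do
not demonstrate robustness to viscoelasticity, adhesion, photobleaching,
uneven illumination, PCR plate effects, or calibration misspecification —
all deliberately out of scope. Default sample sizes (100 curves or traces
per condition, 200 curves for contact stability, 200 null datasets) keep
the full validation suite under a minute on one CPU while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Only approach segments and the flat-punch geometry are analyzed; no
  spherical/conical models, no retract/adhesion analysis, no viscoelastic
  fitting.
* The grid half-width must be matched to the instrument noise (see above);
  the audit grid returned by `fit_young_modulus()` makes mismatches easy
  to spot (the selected candidate pinned at the grid edge is the red
  flag).
* The calibration constants and the tip radius are inputs; the package
  deliberately refuses to guess the radius silently (a default triggers a
  warning, and the pipeline config makes it mandatory).
* Calcium ROI extraction from image stacks and gel densitometry are
  upstream of this package; it consumes their tabular outputs.
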