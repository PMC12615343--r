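---
title: "From amplitude sweeps to printability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From amplitude sweeps to printability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheoprint)
```

## The problem

Extrusion-based 3D food printing works only inside a narrow rheological
corridor. The ink must be a yield-stress fluid: soft enough that the printer
can push it through a millimetre nozzle at a useful rate, and stiff enough
that deposited tracks carry the layers above them. `rheoprint` implements a
desk-scale version of the analysis that links oscillatory rheology of such
inks to two printability read-outs — the required extrusion force and the
geometric fidelity of the printed object, measured from a top-view
photograph. Because no raw laboratory data ship with the package, every
stage has a synthetic counterpart (noisy sweeps, rendered photographs,
correlated cohorts) so the whole pipeline is testable end to end.

## The amplitude-sweep model

An amplitude sweep records the storage modulus $G'$ and loss modulus $G''$
while the oscillatory strain amplitude $\gamma$ is ramped (here
log-spaced over $10^{-5}$–$1$, i.e. 0.001 %–100 %, at 1 Hz). For
yield-stress inks both moduli show a low-strain plateau (the linear
viscoelastic, LVE, regime) followed by a power-law decay once the
microstructure starts to break down. The package fits the descriptive
model

$$G'(\gamma) = G_0\left[1+(\gamma/\gamma_{cr,1})^a\right]^{(n_1-1)/a},
\qquad
G''(\gamma) = \tan\delta\; G_0
\left[1+(\gamma/\gamma_{cr,2})^a\right]^{(n_2-1)/a},$$

with parameters

* $G_0$ (Pa): LVE storage modulus;
* $\tan\delta$: LVE loss factor $G''/G'$ (solid-like when small);
* $\gamma_{cr,1}, \gamma_{cr,2}$: critical strains ending the plateau
  (dimensionless fractions — the yield stress
  $\sigma_Y = G_0\,\gamma_{cr,1}$ only has units of Pa if the strain is a
  fraction, so readers convert percent to fraction at ingest);
* $n_1, n_2$: strain-thinning indices (1 = no thinning; food inks
  typically fall around $n_2 \approx 0.3$–$0.4$ with $n_1 \approx 2 n_2$,
  although the fitter imposes no ratio);
* $a$: crossover sharpness, fixed at 1.5 by default (`free_a = TRUE`
  releases it).

### Fitting choices

The data span several decades in both axes, so `fit_sweep()` minimizes the
summed squared residuals of $\log_{10} G'$ and $\log_{10} G''$ jointly; a
linear-space objective would be dominated by the plateau points.
Parameters are log-transformed inside the optimizer, which enforces
positivity without constraints. Starting values come from the data ($G_0$,
$\tan\delta$ as medians over the lowest strain decade; $\gamma_{cr}$ from
the first crossing of $0.8\,G_0$, log-interpolated; $n = 0.3$), and the
Levenberg–Marquardt engine is restarted from five deterministic
perturbations (critical strain $\times\{0.3, 1, 3\}$, indices $\pm 0.1$),
keeping the best final objective — the fit is a pure function of the data
and options. Noise-free model data are recovered to better than $10^{-6}$
relative error; at 5 % multiplicative noise on 33 points the median
parameter errors stay below 10 %, with $\gamma_{cr,1}$ the hardest
parameter when $G'$ thins weakly (large $n_1$).

Two constraint switches matter in practice. `equal_gamma = TRUE` ties
$\gamma_{cr,1} = \gamma_{cr,2}$ (the downstream statistics always use
$\gamma_{cr,1}$). And a sweep that never leaves the plateau carries no
information about $\gamma_{cr}$ or $n$: the fit is then flagged
`degenerate` rather than returning silently arbitrary values (the flag
triggers when the fitted critical strain lies beyond the measured range or
both indices are $\approx 1$).

### Derived flow predictions

From the fitted parameters the package computes the classical yield-stress
predictions for printing:

* `extrusion_force()`: for a Herschel–Bulkley ink in a straight cylindrical
  nozzle of radius $R$ and length $L$,
  $F_{max} = \sigma_Y [1 + (\dot\gamma_{min}/\dot\gamma_{cr})^{n}]\, 2\pi R L$ —
  the force needed to sustain the minimum process shear rate;
* `self_support()`: a printed column of height $H$ holds its own weight
  when $\sigma_Y > 3\rho g H$ (strict inequality at the boundary), giving
  $H_{max} = \sigma_Y/(3\rho g)$;
* `critical_gel_tan()` / `critical_gel_m()`: for critical gels with
  $G' \sim G'' \sim \omega^m$, $\tan\delta = \tan(m\pi/2)$, used to map
  frequency-sweep exponents onto the $\tan\delta$ axis of the printability
  window.

## Image analysis: from photograph to Dev

The printed design is four connected cylinders in a 2 × 2 layout with
4-fold rotation symmetry and a designed outer/inner radius ratio of 1.34.
`analyze_image()` runs the measurement chain:

1. convert to HSV and apply two class-specific threshold rules
   (`filter_spec`): the S-rule selects the whole object, the C-rule only
   the cylinder walls. Hue uses the 0–180 half-degree convention of the
   shipped dough defaults (`(80<H<120) | S>25` and
   `H>90 & S<130 & V>100`); rules written for 0–360 degrees are declared
   as such and halved at ingest. Rules for protein- and fiber-rich inks
   depend on the photographed material; the shipped files are starting
   points to tune per dataset.
2. clean the wall mask by erosion then dilation (5 × 5 box, 2 iterations
   each — small specks die, the ~60 px wall survives), flood-fill the
   background from an image corner and invert: what remains are the
   enclosed cylinder interiors, whose centroid is the object center.
   Blobs outside the object are absorbed by the fill, so the center is
   robust to them.
3. crop a 900 px square (about the 40 × 40 mm design) around the center,
   masked by the S-mask and zero-padded at the frame edge; divide by its
   own mean to cancel illumination gradients.
4. average the four 90° rotations — for a perfect 4-fold-symmetric object
   this is the identity — and keep one quarter (top-left, fixed for
   determinism; after averaging all four are equivalent).
5. binarize the quarter at 1.25 × its mean, and compute the method-of-
   moments features of the binary mask $f(x,y)$: area $A$, centroid
   $(C_x, C_y)$, second central moments and the polar moment
   $I = M_{20} + M_{02}$. Coordinates put pixel centers at integers,
   origin top-left. (A config switch weights the moments by the grayscale
   values instead; the binary form is the default.)
6. invert the annulus relations $A = \pi(R_2^2 - R_1^2)$,
   $I = (\pi/2)(R_2^4 - R_1^4)$ to
   $R_2^2 = I/A + A/2\pi$, $R_1^2 = I/A - A/2\pi$. An unrealizable pair
   ($R_1^2 < 0$) is clamped to a solid disk and flagged. These closed
   forms are verified in the tests both symbolically (exact pairs invert
   at machine precision) and against rendered masks (radii within 1 % at
   $R_2 \geq 300$ px).

The fidelity metric aggregates three dimensionless deviations from the
design, with the centroid expressed in the frame where its target is
$(R_2, R_2)$ — the quarter corner facing the object center:

$$\mathrm{Dev}^2 = (R_2/R_1 - 1.34)^2 + (C_x/C_y - 1)^2 +
(\bar C/R_2 - 1)^2, \qquad \bar C = (C_x + C_y)/2.$$

Dev = 0 is a perfect print; track widening inflates the first term,
adhesion to neighbors drags $\bar C$ below $R_2$. `dev_metric()` accepts a
weight vector normalized so equal weights reproduce the plain sum;
`entropy_weights()` provides the entropy-weight method (information
content $1 - e_j$ of each column's normalized distribution) that justifies
equal weighting rather than silently replacing it.

**A structural caveat found while testing:** the rotation-averaging step
makes the binarized quarter symmetric about its diagonal for *any* input,
so the measured $C_x/C_y$ is ≈ 1 even for strongly asymmetric objects —
anisotropic distortion surfaces in Dev only through the other two terms.
Observations that $C_x/C_y \approx 1$ across samples are therefore partly
a property of the algorithm, not only of the prints.

## Synthetic data: what it emulates and what it does not

`simulate_sweep()` evaluates the model forward and applies multiplicative
lognormal noise (independent per point and modulus, $\sigma$ chosen so the
factor's coefficient of variation equals `noise_cv`) — rheometer error
scales with the signal. It does not emulate instrument artifacts such as
inertia effects, edge fracture or point-to-point drift.

`render_topview()` draws the four-cylinder design with anti-aliased edges
(8 × 8 subpixel sampling in a 1 px band). Widening is modeled as track
thickening at a fixed print-path centerline: the cylinder centers and the
centerline radius $(R_1+R_2)/2$ stay at their design values while the wall
thickens so the drawn ratio is exactly $1.34 + w$. The centroid deviation
then emerges geometrically — the outer radius grows while the center stays
put, so $\bar C/R_2 - 1 = R_{2,design}/R_2 - 1 < 0$ — reproducing the
observed coupling between widening and center displacement without an
extra knob. Ground truth records the drawn radii, centers and the analytic
Dev of the drawn geometry. At $w = 0.2$ adjacent walls overlap and the
union geometry is no longer an exact annulus; that, not pixelation, is the
main source of the ~0.01 mean absolute difference between pipeline Dev and
drawn Dev across $w \in \{0, 0.05, 0.1, 0.2\}$. The default colors place
the rule-flipping HSV channel of each material boundary at about half edge
coverage, so segmentation counts track rasterized counts. Defects are
purely geometric: no slumping, extrusion physics or baking effects are
simulated.

`generate_cohort()` samples a 38-ink cohort (18 carbohydrate-rich doughs,
10 protein-rich, 10 fiber-rich — the study size) with explicit
Gaussian-latent correlation structure on log scale: critical strains
correlated at 0.95 within class, $n_1 \approx 2 n_2$, $G_0$
anti-correlated with $n_2$ (stiffer inks must thin more strongly to remain
extrudable), force proportional to $\sigma_Y$ per class with fiber inks on
their own slope. Class medians for $\gamma_{cr,1}$ are anchored at the
characteristic strains of the three classes, $\{0.3, 1.5, 4\}\times
10^{-2}$; $\tan\delta$ is lognormal with class medians
$\{0.25, 0.30, 0.35\}$ and log-sd 0.45, wide enough that a 38-ink cohort
brackets the printability window on both sides. The deviation response is
a convex function of $\log\tan\delta$ crossing the 0.1 threshold exactly
at the configured window bounds (0.15 and 0.5 by default) — a modeling
choice that makes window recovery testable, not a mechanistic claim. All
generators are pure functions of their spec, seed included.

## Statistics

`pairwise_regression()` is ordinary least squares on declared axis
transforms, with $r^2$ the squared Pearson correlation of the transformed
data. Decade-spanning quantities ($G_0$, $\sigma_Y$, $\gamma_{cr}$,
force) default to $\log_{10}$ axes; bounded ones ($\tan\delta$, $n_1$,
$n_2$, Dev) to identity. The transform is recorded in every result. No
outliers are removed automatically and no multiple-testing adjustment is
applied; exclusions are a user decision.

`collapse_gamma_cr()` implements the master-curve construction: per-class
positive scales $s_c$ (reference class fixed at 1) minimize the summed
squared vertical residuals of Dev around a single monotone non-increasing
trend in $\log_{10}(\gamma_{cr,1}/s_c)$, fitted by isotonic regression.
Among the two readings of the published objective (pairwise distances
between data sets vs distance to a pooled trend) the pooled-trend form is
implemented; it is the one that generalizes beyond two classes. The
offsets are found on a 0.05-decade grid refined by local optimization, so
the result is deterministic. A constructed two-class shift of 5× is
recovered within a few percent; the absolute characteristic strain is
reported as $s_c$ times the reference class's geometric-mean
$\gamma_{cr,1}$.

`extract_window()` reads the printability window directly: the range of
$\tan\delta$ over inks with Dev below the threshold (0.1), requiring at
least 2 such inks. Tightening the threshold can only narrow the window.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use: 33-point sweeps (20
noise-free draws; 100 noisy replicates), rendered fixtures at 1080 px
frames with $R_2 = 215$ px (560 px / 110 px for the fast unit fixtures), a
660 px annulus oracle mask, and one 38-ink cohort per run. These sizes
keep the full suite under a minute while leaving rasterization errors
($\propto 1/R_2$) a factor of a few below the tolerances they are checked
against. Key numeric guards: strict positivity at every constructor,
optimizer tolerances at $10^{-15}$, degenerate-fit and empty-mask
conditions flagged rather than silently absorbed, and the solid-disk clamp
in the radius inversion.

## Known limitations

* Sweep-only rheology: no flow curves, frequency sweeps, LAOS or
  thixotropy — the critical-gel relation is the only bridge to
  frequency-domain exponents.
* Segmentation thresholds for non-dough classes are placeholders; HSV
  thresholding is sensitive to lighting and camera, and real photographs
  (shadows, specular highlights, substrate texture) are harder than the
  rendered fixtures.
* The $C_x/C_y$ term of Dev is structurally suppressed by the symmetry
  averaging (see above).
* The collapse assumes a monotone Dev–$\gamma_{cr}$ trend; a
  non-monotone master curve would need a different trend representation.
* Passing the synthetic end-to-end tests shows the machinery is
  self-consistent at realistic noise levels; it does not validate the
  physics of any particular ink.
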