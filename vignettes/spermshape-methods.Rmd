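---
title: "Outline morphometrics of sperm heads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of sperm heads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermshape)
```

## The problem

Rodent sperm heads are falciform: a flattened ovoid body carrying an apical
hook whose length and curvature vary between genotypes and are sensitive to
defects of head morphogenesis. Visual scoring of "abnormal" heads is
subjective and discards most of the shape information. The standard
quantitative alternative is outline-based geometric morphometrics: trace the
closed head contour, encode it with elliptic Fourier descriptors (EFDs),
normalize away nuisance transformations, and study the coefficient space
with principal component analysis (PCA). In mouse data analyzed this way,
the leading component typically captures head width and a second component
the length and direction of the hook, and group differences concentrate on
the hook component. This package implements that pipeline end to end,
together with the auxiliary per-cell measurements usually reported alongside
it (acrosome area from PNA staining, nuclear vacuole counts, CASA-style
kinematics) and the group statistics used to compare genotypes against a
wild-type control.

## Elliptic Fourier descriptors

A closed contour traversed counterclockwise is a pair of periodic functions
$x(t)$, $y(t)$ of the cumulative chain length $t \in [0, T)$. `efd_decompose()`
computes the truncated series

$$x(t) = A_0 + \sum_{n=1}^{H} a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T},
\qquad
y(t) = C_0 + \sum_{n=1}^{H} c_n \cos\frac{2\pi n t}{T} + d_n \sin\frac{2\pi n t}{T}.$$

Because contours arrive as sub-pixel polygons, $x(t)$ and $y(t)$ are
piecewise linear in $t$ and the harmonic integrals have an exact closed form
in the segment increments; no numerical quadrature is involved. The default
$H = 20$ gives the conventional $4H = 80$-number shape code
(`efd_flatten()`), which excludes the translation terms $A_0, C_0$.

A consequence of chain-length parameterization worth knowing: a 2:1 ellipse
is *not* a pure first harmonic. Its first-harmonic semi-axes come out near
$(1.83, 1.07)$ rather than $(2, 1)$, with the balance of the energy in the
odd harmonics. This is a property of the parameterization, shared by every
standard EFD implementation, not an approximation error; the test suite
pins the exact values against an independent trapezoidal-quadrature oracle.

### Normalization

`efd_normalize()` removes, in order: the starting-point phase
$\theta_1 = \tfrac12 \operatorname{atan2}\!\big(2(a_1 b_1 + c_1 d_1),\,
a_1^2 + c_1^2 - b_1^2 - d_1^2\big)$, applied to harmonic $n$ as a rotation
by $n\theta_1$ in the $(\cos, \sin)$ plane; the spatial orientation
$\psi_1 = \operatorname{atan2}(c_1', a_1')$ of the first-harmonic major
axis; and size, by dividing through by the post-rotation $a_1$. On output
$a_1 = 1$, $b_1 = c_1 = 0$, and coefficient vectors of rotated, scaled,
translated and re-indexed copies of one contour agree to machine precision.

The half-angle formula determines $\theta_1$ only modulo $\pi$: the
starting point can land on either end of the major axis, and the two
choices flip the sign of every even harmonic while both leave $a_1 > 0$.
Left unresolved, this breaks start-point invariance for shifts past half
the contour. We therefore normalize both candidates fully and keep the
lexicographically larger coefficient vector (ties below $10^{-9}$ skipped).
The rule is arbitrary but deterministic, depends only on the shape, and is
exactly invariant under the nuisance group — which is all a canonical form
needs.

### Chirality

For counterclockwise contours $d_1 > 0$ always holds after normalization,
so the sign of $d_1$ records traversal orientation, not handedness.
Handedness — a left- versus right-pointing hook — lives in the signs of the
mirror-odd entries ($b_n$, $c_n$). By default it is *preserved*, because
hook direction is biologically meaningful; `canonical_chirality = TRUE`
additionally normalizes over the mirror image (recomputing $\theta_1$ for
the mirrored coefficients, whose phase is $-\theta_1$) and applies the same
lexicographic rule, so that a shape and its mirror map to one vector. Use
it when slides may be imaged flipped.

## Shape PCA and mean shapes

`fit_shape_pca()` performs covariance PCA (centered, unscaled) on the
specimen-by-80 coefficient matrix. Correlation PCA would inflate the three
near-constant entries left by normalization ($a_1, b_1, c_1$), so it is not
offered; centering makes those entries inert. Two components are retained
by default — the conventional pair for sperm heads — and loading signs are
fixed by making each loading's largest-magnitude entry positive, so runs
are bit-reproducible. `mean_shape(model, k, m)` reconstructs the contour of
the mean vector displaced by $m$ score standard deviations along component
$k$ (default display: $0, \pm 2$ SD), the standard way to visualize what a
shape PC encodes. All genotypes are pooled for the fit by default; passing
a subset of rows fits on that subset.

## Synthetic data: what it emulates and what it does not

The generator exists so that every downstream stage has ground truth. A
head is a star-shaped radial profile: a superellipse ovoid (length x width,
exponent 2.5) plus a von-Mises-shaped radial bump for the hook, with
amplitude `hook_length`, direction `hook_angle` and concentration
`hook_sharpness`. Defaults (body 80 x 45 px, hook 25 px with dimensionless sharpness 12, at
~0.2 µm/px) give proportions comparable to a mouse sperm head imaged at a
typical 100x setup. Boundary noise is radial Gaussian jitter
smoothed with a periodic moving average, so noise-free and mildly noisy
contours remain simple polygons. Population draws truncate each parameter
at $\pm 3$ SD and at physical bounds.

Rendered channels emulate a segmentation-friendly phase-contrast head mask,
a Hoechst-like nuclear channel with dark vacuole disks placed by rejection
sampling fully inside the eroded head, and a PNA-like acrosome crescent
covering a set fraction of an anterior boundary band. There is no point
spread function, no shot noise, no touching cells, and no focus variation:
passing the recovery tests shows the *computational* pipeline is correct
and calibrated, not that segmentation of real micrographs is solved.
Motility tracks are straight, sinusoidal (lateral oscillation on a straight
progression) or direction-correlated random walks; none models wall
effects or hyperactivation.

## Auxiliary measurements

Acrosome area thresholds the PNA channel inside the head mask dilated by 2
px (boundary-hugging crescents would otherwise be clipped) and converts
counts with `pixel_size^2`. Vacuoles are connected components inside the
1-px-eroded head whose intensity drops at least 50% below the median head
intensity, filtered to $[4\ \mathrm{px}^2,\ 25\%$ of head area$]$; the
relative threshold makes detection invariant to affine intensity
rescaling. Prevalence is reported with a Wilson 95% interval.

Kinematics follow standard CASA definitions: VSL from the net
displacement, VCL from the frame-to-frame path, VAP from a centered
5-frame moving-average path whose window shrinks at the track ends. The
smoothed path starts and ends on the raw track, so
$\mathrm{VCL} \ge \mathrm{VAP} \ge \mathrm{VSL}$ holds for every track
(convexity and the triangle inequality); the suite asserts it on a
thousand random walks. The motile call, VCL $\ge 25$ µm/s, is a documented
stand-in for instrument-internal criteria and is configurable.

## Group statistics

`one_way_anova()` is the classical between/within F test; letters encode
comparison p-values as `a` ($p<0.05$), `b` ($p<0.01$), `c` ($p<0.001$).
Comparisons against the control group use Dunnett's many-to-one procedure
by default — the standard choice when every genotype is compared with the
same wild-type — with Holm-adjusted pairwise Student t-tests as the
alternative (`method = "holm_t"`). Reports state which method produced the
letters. Degenerate inputs follow fixed conventions rather than erroring:
zero within-group variance yields $p = 1$ when the means agree and
$p \to 0$ when they do not.

## Numerical choices and degenerate inputs

* Contours are validated to be counterclockwise simple polygons;
  consecutive duplicate vertices are dropped on entry.
* Boundary tracing uses marching squares at iso-level 0.5 on a zero-padded
  mask (`grDevices::contourLines`), whose fixed saddle-point rule makes
  tracing deterministic; the largest-area iso-contour is kept, which also
  discards interior holes. Border-touching components warn and set a
  `clipped` flag.
* Resampling to 256 points (Nyquist-safe for $H = 20$, and comfortable for
  the $H = 127$ round-trip tests) interpolates uniformly in cumulative arc
  length. Resampling is an exact fixed point only when the input's segments
  are already equal; on curved contours a second pass moves points at the
  $10^{-4}$ level because chords shorten corners — the defining property to
  test is uniform spacing along the *source* polygon, which is what the
  suite checks.
* Normalization residuals are asserted at $10^{-9}$ on exact inputs and
  $10^{-6}$ on noisy ones; the lexicographic tie tolerance is $10^{-9}$.
* Dunnett p-values come from `multcomp` and carry the usual $\sim 10^{-4}$
  quasi-randomization jitter; equalities involving them are tested at that
  scale, exact arithmetic (ANOVA, t) at $10^{-12}$.

## Problem sizes in the shipped experiments

The parameter-recovery experiment uses two populations of 100 specimens
(hook length means 2 within-group SDs apart, SD 4 px), where the hook PC
correlates with ground truth at $|r| > 0.9$ and the control comparison is
letter `c`; the matching null calibration runs 200 replicates of identical
populations and keeps the flagged-letter rate at the nominal 5-10%. The
vacuole experiment renders 300 heads with prevalence planted at 33.1% — a
realistic figure for a vacuole-prone genotype — and recovers it within the
binomial sampling error. These sizes keep each experiment in the tens of
seconds on a single core while leaving the statistical margins wide.

## Known limitations

Single-cell scenes only; no splitting of touching heads and no tracking.
The EFD code handles closed curves only (no open-curve variant). PCA is
unsupervised; no discriminant analysis is provided. The acrosome and
vacuole units are only as meaningful as the supplied `pixel_size`, and
absolute PNA areas depend on staining and thresholding — between-group
contrasts are the meaningful readout, which the pipeline preserves.
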