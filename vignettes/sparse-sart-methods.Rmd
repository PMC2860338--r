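---
title: "Sparsity-constrained SART for few-view fan-beam CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-constrained SART for few-view fan-beam CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsart)
```

## The reconstruction problem

Computed tomography recovers an attenuation image $f \in \mathbb{R}^N$
(here an $n \times n$ pixel grid, $N = n^2$) from projection measurements
$g \in \mathbb{R}^M$ linked by a linear model

$$ g = A f + e, $$

where $A = (a_{mn})$ is the system matrix and $e$ is measurement noise.
Reducing the number of projection views reduces the radiation dose, but it
makes the system strongly underdetermined: with 25–55 views and a
128-element detector, $M = $ 3200–7040 measurements constrain $N = 16384$
pixels. The package implements an iterative scheme that compensates for the
missing data with a sparsity constraint in an invertible transform domain,
together with everything needed to study it end to end: a fan-beam
simulation environment, the transform and shrinkage machinery, and an
experiment driver.

## The fan-beam projector

The acquisition model is a circular full scan: the X-ray source moves on a
circle of radius 57 cm around the rotation axis, and a flat *virtual*
detector of length 20 cm with 128 equispatial elements passes through the
origin, perpendicular to the source direction. For view angle $\theta$ the
source sits at $(-R\sin\theta, R\cos\theta)$ and the detector axis runs
along $(\cos\theta, \sin\theta)$; views are equiangular over $[0, 2\pi)$.
Any consistent orientation convention would do; this one is frozen so runs
are bit-reproducible.

Each measurement integrates attenuation over a narrow *strip*: the triangle
spanned by the source point and the two endpoints of one detector element.
The matrix entry $a_{mn}$ is the exact area (cm²) of the intersection of
that strip with pixel $n$'s square, computed by Sutherland–Hodgman convex
polygon clipping in compiled code; entries below $10^{-12}$ cm² are
dropped. The tests validate the areas against two independent oracles: a
plain-R clipping of the whole strip against the image square (row sums) and
dense subpixel point sampling (individual entries).

The row sums $a_{m+}$ and column sums $a_{+n}$ feed the SART weighting
diagonals $\Lambda^{M+} = \mathrm{diag}(1/a_{m+})$ and
$\Lambda^{+N} = \mathrm{diag}(1/a_{+n})$. Beams that miss the grid and
pixels never intersected get a zero weight, which removes them from the
update (the weighted residual is zero there, so such pixels stay at their
current value).

## Sparsifying transform

The sparsifier is the separable two-dimensional Haar wavelet transform at
full dyadic depth with *orthonormal* filters, so Parseval holds exactly and
the $\ell_p$ radius of an image's coefficients is well defined in the same
scale as the image itself. Full depth maximizes sparsity of the piecewise
constant phantom. The transform interface is a plain forward/inverse pair on
flat coefficient vectors, so another invertible basis can be swapped in
without touching the solver. Grid sides must be powers of two for the
projected schemes.

## Shrinkage and the $\ell_p$-ball projection

For a weight $w \ge 0$ and exponent $p \in [1, 2]$, the scalar companion
map

$$ F_{w,p}(x) = x + w\,p\,\mathrm{sgn}(x)\,|x|^{p-1} $$

is an odd, strictly increasing bijection for $p > 1$; its inverse
$S_{w,p} = F_{w,p}^{-1}$ is the generalized soft-threshold. The package
uses closed forms at $p = 1$ (classical soft-thresholding), $p = 3/2$ and
$p = 2$, and a safeguarded Newton/bisection inversion elsewhere, accurate to
$|F(S(y)) - y| \le 10^{-10}\max(1, |y|)$. The bracket $[0, |y|]$ is always
valid because shrinkage never increases magnitude; ties at $|x| = w$ need no
special casing since soft-thresholding is continuous there.

Projection onto the $\ell_p$ ball of radius $R$ applies $S_{\mu,p}$
componentwise with an *adapted* threshold $\mu$: if the coefficient vector
already lies inside the ball, $\mu = 0$ and nothing changes; otherwise
$\mu$ solves

$$ \Big(\sum_\gamma |S_{\mu,p}(\phi_\gamma)|^p\Big)^{1/p} = R $$

by dichotomy (bisection). The shrunk radius is continuous and nonincreasing
in $\mu$, so the search is globally convergent; it starts on
$[0, \max_\gamma|\phi_\gamma|]$ (doubling the upper end when $p > 1$, where
a finite threshold never reaches radius zero), and stops when the radius
matches within $10^{-8}\max(1, R)$ or after 200 steps — both exposed as
parameters, since no canonical values exist. For $p = 1$ the result agrees
with the exact sort-based $\ell_1$ projection to $10^{-6}$, which the tests
assert on vectors up to length $10^4$.

## The iteration

One iteration of the core scheme is

$$ f^k = \mathbb{P}_{R}\big(f^{k-1} + \alpha\,\beta^k\,\tilde r^k\big),
\qquad
\tilde r^k = \Lambda^{+N} A^T \Lambda^{M+}\, (g - A f^{k-1}), $$

with the steepest-descent step $\beta^k = \|\tilde r^k\|^2 / \|A \tilde
r^k\|^2$ and $\mathbb{P}_R$ the Haar-domain $\ell_p$-ball projection. The
scheme variants are

* **A** — the full iteration with a fixed radius target $R^\*$;
* **B** — the same step with the projection disabled (no regularization);
* **C** — the "interior" variant, growing the radius target as
  $R^k = \big(0.4 + 0.6\,(k/k_{\max})^{0.05}\big) R^\*$ so the feasible
  ball slowly expands toward $R^\*$ (it equals $R^\*$ exactly at
  $k = k_{\max}$);
* **AD/BD/CD** — direct counterparts with $\alpha = 1$ and identity
  weighting ($\tilde r = A^T(g - Af)$), the plain accelerated projected
  gradient;
* **SART** — the classical update $f \leftarrow f + \lambda \tilde r$ with
  a fixed relaxation $\lambda \in (0, 2)$, kept as a reference and as a
  cross-check of the compiled iteration path.

All schemes start from $f^0 = 0$ (so the initial relative error is exactly
100%) and stop when the relative reconstruction error

$$ E^k = 100 \cdot \|f^k - f^\*\|_2 / \|f^\*\|_2 $$

against the ground truth drops below a threshold (0.1% in the study
conditions) or when the iteration budget (20000) is exhausted. In
simulation the radius target is taken from the ground truth,
$R^\* = \|\Phi f^\*\|_p$ with $\Phi$ the Haar analysis operator; in practice
it would be an estimate, which is exactly the regime the interior scheme is
designed for. A run whose error grows beyond ten times its initial value
(or turns non-finite) aborts with a diagnostic recommending a smaller
`alpha0`; without ground truth the discrepancy $\|g - Af^k\|$ plays the
same role. Both the factor ten and the zero start are implementation
choices — fail fast, reproduce exactly.

## The step-scale constant $\alpha$

The weighted residual $\tilde r$ lives on a different scale than the
unweighted gradient $A^T(g - Af)$, and the method compensates with

$$ \alpha = \alpha_0 \sqrt{ \frac{\max_n (A^T A \mathbf{1})_n }
 {\max_n (\Lambda^{+N} A^T \Lambda^{M+} \Lambda^{M+} A \Lambda^{+N}
 \mathbf{1})_n } }, $$

four sparse matrix–vector products on the all-ones vector. The two maxima
are $1$-norm/$\infty$-norm bounds on the squared operator norms whose ratio
defines $\alpha$; the constant $\alpha_0$ absorbs the looseness of those
bounds, and the method's stated calibration rule is to reduce $\alpha_0$
whenever the iteration fails to converge.

For this package's exact-area projector the bounds turn out to be nearly
sharp: a power-iteration measurement of the true operator norms gives a
bound/true ratio of about 1.03 at 64 × 64 with 55 views. Running at
$\alpha_0 = 2$ therefore over-relaxes the definitional $\alpha$ by a factor
of two — the iterate oscillates and the error stalls well above the
stopping threshold, and $\alpha_0 \ge 4$ diverges outright. Applying the
calibration rule lands at $\alpha_0 = 1$, which converges cleanly; the
study driver (`experiment_plan()`) and the acceptance script use that
value, while `reconstruct()` keeps the conventional default
`alpha0 = 2` for data where the bound is loose. The same rule applied to
the random-matrix recovery test below lands at $\alpha_0 = 0.5$.

## Synthetic data

The generator reproduces the study conditions: the canonical ten-ellipse
modified (high-contrast) Shepp-Logan phantom rasterized by pixel-center
sampling on the $[-10, 10]^2$ cm square (20 cm field of view, 10 cm compact
support radius; intensities accumulated in exact tenths so cancelling
regions are exactly zero), the fan-beam geometry above, and — for noisy
variants — additive i.i.d. Gaussian noise with standard deviation
$0.001 \cdot \max_m g_m$, a "0.1% noise" level referenced to the maximum
measurement. The reference quantity for percentage noise is genuinely
ambiguous (per-datum relative and SNR-referenced are also defensible);
max-referenced noise is frozen here and isolated behind the `level`
argument of `add_noise()`. Noise realizations are seeded and reproducible.

What the simulation does *not* model: polychromatic spectra and beam
hardening, scatter, detector blur and afterglow, photon statistics
(Poisson), and any mismatch between the forward model used for simulation
and reconstruction — data are generated by the same discrete projector that
reconstructs them. Passing tests therefore demonstrate the solver's
behavior under its own model class, not clinical image quality.

Rasterization is point-sampled with inclusive ellipse membership, no
anti-aliasing. The widely quoted count of nonzero Haar coefficients for the
128 × 128 phantom is 1708; this rasterization yields 1711 (within 0.2%),
and no standard convention we tested — the MATLAB-style grid with spacing
$2/(n-1)$ (1622), edge-aligned sampling (1692/1721), strict membership,
alternative intensity tables, other decomposition depths or count
tolerances — reproduces 1708 exactly. The count is stable for thresholds
from $10^{-12}$ to $10^{-2}$, so it is a property of the raster, not of the
tolerance; the acceptance suite asserts the published value and documents
the three-coefficient discrepancy rather than papering over it.

## Desk-scale test problems

The test suite exercises the full study pipeline at reduced size so it runs
in minutes: the scheme-ordering checks use a 64 × 64 phantom, a 64-element
detector and 2000 iterations per run across 25/35/45/55 views (noise-free
and 0.1% noise), sizes at which all the qualitative orderings of the
full-scale study already manifest. The sparse-recovery property uses a
32 × 32 image with 20 nonzero Haar coefficients measured by a 160 × 1024
uniform random nonnegative matrix and a 50000-iteration budget — projected
gradient onto an exact-radius $\ell_1$ ball has a slow terminal phase, and
the budget covers it. The two full-scale 55-view runs (Scheme-A and
Scheme-B at 128 × 128, 20000 iterations) are kept in the acceptance suite
because they are the study's headline numbers.

## Known limitations

* The terminal error of the *unregularized* schemes (B/BD) on consistent
  data equals the component of the phantom in the null space of the system
  matrix — a property of the discretized projector, not of the algorithm.
  Direct-scheme iterates stay in the row space of $A^T$, so no
  unregularized run from a zero start can do better than that bound.
  Published error figures for nominally identical geometries therefore
  depend on the beam model used and need not transfer across
  implementations; the package's own numbers are reproducible to the last
  iteration.
* Projection schemes require dyadic grids (full-depth Haar). Other
  invertible sparsifiers can be plugged in through the same forward/inverse
  interface.
* The solver addresses 2D fan-beam data only; cone-beam and helical
  geometries, ordered-subset acceleration and multiscale solvers are out of
  scope.
* Convergence is observed empirically (and asserted by the tests); no
  convergence proof is claimed for the weighted iteration.
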