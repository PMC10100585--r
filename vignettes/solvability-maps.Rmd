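---
title: "Monte Carlo image solvability maps: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo image solvability maps: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(solvmap)
```

## The question the map answers

A tomographic acquisition is modeled as a linear system $AX = P$: $x_i$ the
image pixels, $p_j$ the measured line integrals, $a_{ij}$ the length of ray
$j$ inside pixel $i$. When the detector does not cover the object
(projections truncated at both ends — the interior problem) or the angular
sampling is incomplete, the system cannot be solved stably *as a whole*; the
condition number $\sigma_{\max}/\sigma_{\min}$ of $A$ is then effectively
infinite and says nothing about *which* pixels remain recoverable. The
diagonal of the Moore–Penrose projector $A^{+}A$ answers the per-pixel
question — an entry of 1 marks an unknown the generalized solution recovers
— but needs the dense SVD of $A$, feasible only for toy systems, and it
knows nothing about the reconstruction algorithm actually used.

The solvability map answers the per-pixel question empirically, for any
algorithm. Draw $n$ random phantoms $X^{(m)}$, simulate their measurement,
reconstruct each with algorithm $G$, and average the squared-error images:

$$e_i = (x_i - x_i^{\mathrm{true}})^2, \qquad
\mathrm{Map} = \frac{1}{n}\sum_{m=1}^n E\!\left(G(P^{(m)})\right).$$

Low values mark pixels the geometry/algorithm pair reconstructs stably. The
map depends on both the geometry and the algorithm — that is a feature: it
compares algorithm variants under the same scan.

## Simulation protocol

Each phantom is the sum of four ellipses with uniform random centres
(central 70 % of the grid), semi-axes (4–23.5 % of the side; 15–90 pixels at
the 384-pixel full scale), orientation and intensity (0.2–1); overlaps add.
The image is smoothed by a Gaussian of $\sigma = 1$ pixel and min–max
normalized to $[0,1]$. Since no published parameter distributions exist for
this protocol, these ranges were chosen once so that typical objects are
substantially larger than the truncated detector's field of view — the
regime the interior problem is about — and are expressed as fractions of
the grid side so the same family is produced at any scale. Overlapping
ellipses add (rather than overwrite) because addition keeps the generator
order-independent.

**Inverse-crime avoidance.** Data are never generated with the operator
that inverts them. Phantoms live on a $3\times$ finer grid (384×384, pixel
$1/3$) with a $3\times$ finer detector; after forward projection, Poisson
noise is applied to the fine line integrals, and each group of 3 adjacent
fine bins is *averaged* into one reconstruction-scale bin (averaging, not
summing, keeps the values on the line-integral scale the coarse system
matrix expects). Reconstruction uses the independent 128×128 operator. The
ground truth for the error image is the $3\times 3$ block mean of the fine
phantom — the natural partner of the detector bin-down. The pipeline
asserts that the two operators are distinct discretizations.

**Noise.** Poisson noise acts directly on the line integrals
(emission-style): each measured value $v$ becomes
$\mathrm{Poisson}(c\,v)/c$ with dose $c = 500$ counts per line-integral
unit by default. The published experiments state that Poisson noise was
used but not its magnitude, so absolute map minima (noise floors) are not
comparable across implementations; all qualitative comparisons reported
here (naive vs modified, truncated vs untruncated, ROI vs non-ROI) are
insensitive to the dose over a wide range.

## Geometry

The scan is parallel-beam: `n_views` equally spaced angles over 180° (180
stops at 1° by default). Bin $b$ of a detector with width $w$ and centre
offset $\delta$ sits at $s_b = (b - (n_\mathrm{bins}-1)/2)\,w + \delta$; a
nonzero $\delta$ makes the detector asymmetric about the rotation axis.
Sinograms live on an **extended virtual detector**: the smallest symmetric
detector that covers the grid diagonal and contains every physical bin
centre on its lattice (odd bin count for integer-lattice physical centres,
even for half-integer ones). The physical bins form the measured subset;
the unmeasured bins are where the naive algorithms put zeros and the
modified algorithms put the current forward projection.

The published figure of the asymmetric scanner does not quantify its
asymmetry, only that the truncated detector has 107 bins; the default
offset is $+39$ bin widths, which leaves the near edge 14.5 pixels from the
axis so that the fully-measured region is nonempty and clearly smaller than
the object. (Offsets must keep the physical centres on the extended
lattice: integer multiples of $w$ for odd bin counts, which is why the
64×64 test profile scales $+39$ to $+19$ rather than $+19.5$.)

**Angular-coverage ROI.** A pixel is fully measured when the ray through
its centre hits the measured span at every view (membership rule: signed
distance within [first measured centre $-w/2$, last measured centre
$+w/2$]). For a *symmetric* detector this region is the centred disk of
radius half the measured span. For an asymmetric detector over a half-turn
it is **not** a disk: the signed distances of the lines through a point
$P = R(\cos\varphi_0, \sin\varphi_0)$ sweep $R\cos(\theta-\varphi_0)$ over
a 180° interval, so the fully-measured set is the intersection of the 180
measured strips — a convex "keyhole": the strip $|x| \le$ near-edge
distance up to the far-edge radius on one half-plane, plus the near-edge
half-disk on the other. The tests freeze this closed form and check the
enumerated coverage map against it; the 180°-rotation invariance of
coverage holds exactly only in the symmetric case and is tested there.

## Projector

$a_{ij}$ is the exact intersection length of the bin's *central ray* with
pixel $i$, computed by Siddon-style ray marching in C++ and stored as a
sparse matrix; forward projection is `A %*% x` and back-projection the
literal transpose, so $\langle Ax, y\rangle = \langle x, A^{T}y\rangle$
holds to rounding by construction. Pixel membership of each ray segment is
decided by its midpoint, which gives axis-aligned boundary-running rays a
consistent half-open convention ($x\in[x_0,x_1)$, $y\in(y_0,y_1]$);
near-zero direction components are snapped to exactly zero so `cos(pi/2)`
at the 90° view cannot push midpoints across a pixel boundary. The dense
oracle (`build_dense_matrix`) recomputes the same weights by an independent
pure-R slab-clipping route, and the test suite requires entry-wise
agreement below $10^{-12}$; single central rays leave visible pixelization
jitter on curved edges (a few percent of the chord length), which is the
tolerance used in the chord-length tests.

## Reconstruction variants

With $q_j = \sum_n a_{nj} x_n^k$:

* **GD** (least squares): $x^{k+1}_i = x^k_i - \alpha \sum_j a_{ij}(q_j - p_j)$,
  from the zero image. The default step is $\alpha = 1.9/\lambda_{\max}$,
  with $\lambda_{\max}$ of $A^{T}A$ estimated by 50 deterministic power
  iterations — just inside the $2/\lambda_{\max}$ stability bound, so the
  residual is non-increasing. Non-finite iterates raise an error naming the
  step size.
* **ML-EM** (Poisson likelihood):
  $x^{k+1}_i = \frac{x^k_i}{\sum_j a_{ij}} \sum_j a_{ij}\, p_j / q_j$, from
  the all-ones image. Iterates stay nonnegative and zeros persist, so
  finite support only needs to be imposed on the initial image; denominators
  are guarded by $\varepsilon = 10^{-12}$, small enough not to bias any bin
  with appreciable signal.
* **Finite support**: a mask of pixels allowed to be nonzero, derived per
  phantom from the downsampled truth ($>0$) dilated by one pixel (the block
  mean can shave single-pixel boundaries). GD zeroes out-of-support pixels
  after every update — enforcing after the update is the natural reading of
  a constraint on $x^{k+1}$, and on toy systems it reproduces exactly the
  unconstrained iteration restricted to the support columns.
* **Truncation modification**: before each update, unmeasured $p_j$ are
  overwritten with the current $q_j$, so those bins exert no data-fit force
  (for ML-EM, their ratio is forced to 1). The naive alternative keeps
  $p_j = 0$ there — the incorrect-but-common implementation whose failure
  the maps expose.

Iteration counts are not published; the defaults (200 GD, 100 ML-EM) sit on
the error plateaus of toy problems, and the reduced test profile halves
them (100/50) consistently with its halved problem size. The
reconstruction array always spans the full grid even when the detector is
small, so the truncated object has somewhere to exist.

## Problem sizes used by the tests and the acceptance script

The full protocol (384/128, 180 views, $n = 1000$) runs in hours; the
package's own experiments use a reduced profile chosen once: 64×64
reconstruction (192×192 phantoms), 90 views over 180°, truncated detector
53 bins at offset $+19$ (untruncated: 93 bins), $n = 50$ phantoms, dose
500. At this scale the qualitative structure of the published comparison is
clear-cut: naive map maxima exceed the truncation-modified maxima by
factors of 30–40, truncated naive maxima exceed untruncated ones by three
orders of magnitude, untruncated minima are strictly positive, and the mean
map value inside the coverage ROI is an order of magnitude below the mean
over object pixels outside it.

The dense-oracle comparison uses a deliberately *underdetermined* truncated
toy (24×24 grid, 21 bins at offset $+7$, 24 views: 504 measured rays for
576 unknowns). That choice matters: at 90 views the discrete truncated
system is numerically full-rank — the interior problem's ill-posedness
shows up only in singular values that stay above any honest rank cutoff —
and $\mathrm{diag}(A^{+}A)$ is uniformly 1, carrying no ordering
information. With fewer rays than unknowns the rank deficiency is
structural, $\mathrm{diag}(A^{+}A)$ spans $[0.23, 1]$, and its complement
correlates strongly (Spearman $\approx 0.88$) with a 200-phantom Monte
Carlo map of the truncation-modified GD variant — the support-free variant,
since the pseudo-inverse knows nothing about object support. The
singular-value cutoff for numerical rank is $\sigma < 10^{-10}\sigma_{\max}$
throughout, an operational stand-in for "essentially infinite" condition
numbers.

## Numerical choices and degenerate inputs

* Phantom draws whose pre-normalization image is constant (e.g. one ellipse
  covering the grid) are redrawn from the same stream, at most 10 times,
  then error.
* Gaussian smoothing uses reflective boundaries (kernel truncated at
  $4\sigma$) so phantoms touching the frame do not acquire dark rims; it is
  a small separable convolution written here because the boundary rule is
  part of the protocol.
* `generate_phantom` and `add_poisson_noise` run on private RNG streams and
  restore the caller's `.Random.seed`; phantom $m$ of a run uses seed
  $\texttt{base} + m$ and noise seed $\texttt{base} + m + 10^6$, making runs
  bit-reproducible, checkpoint/resume exact, and phantom/noise streams
  independent.
* The map accumulator keeps running sums, so resuming from a checkpoint and
  an uninterrupted run produce identical maps; a checkpoint records its
  configuration and refuses to resume a different one.
* The map min/max summary is taken over the full reconstruction array, with
  no restriction to the object region.
* Display saturation: $1 - e^{-20v}$ reaches 1.0 in double precision near
  $v \approx 1.84$; tests of strict monotonicity and inverse recovery
  restrict to the representable range.

## What the tests do and do not show

The synthetic protocol emulates randomized smooth blob-like objects,
monoenergetic noiseless-optics parallel-beam physics, and ideal detectors.
It does not emulate transmission-style log-law noise, scatter, beam
hardening, detector blur, fan/cone geometries, or anatomically realistic
textures. Conclusions supported by the tests are therefore about the
*relative* stability structure (which pixels, which algorithm variant,
which acquisition), which is what a solvability map is for — not about
absolute error levels on any real scanner, which depend on dose and physics
the protocol deliberately idealizes.
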