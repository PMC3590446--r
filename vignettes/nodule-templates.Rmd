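---
title: "Deformable gray-level templates for lung nodule detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable gray-level templates for lung nodule detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodtemplate)
```

## The detection model

Lung nodules in windowed chest CT appear as roughly isotropic bright
blobs whose gray level decays smoothly from a peak at the center toward
the parenchymal background. `nodtemplate` models a nodule's cross-section
with a central-symmetric Gaussian profile

$$q(r) = q_{\max}\, e^{-(r/\rho)^2}, \qquad 0 \le r \le R,$$

where $q_{\max}$ is the peak gray level, $R$ the nodule radius in pixels
and $\rho$ the decay constant. The boundary condition $q(R) = q_{\min}$
ties $\rho$ to the calibration of the gray window:

$$\rho = R\,(\ln q_{\max} - \ln q_{\min})^{-1/2},$$

so $\rho$ is never a free parameter here; `template_spec()` always derives
it from $(R, q_{\max}, q_{\min})$. The default calibration
$q_{\max} = 255$, $q_{\min} = 61$ describes 8-bit windowed lung CT where
segmented vascular/nodular tissue bottoms out around gray 61; with it,
radii of 5 and 30 pixels give $\rho \approx 4.18$ and $25.08$.

Four template shapes cover the nodule taxonomy:

* **circle** — small nodules confined to one slice;
* **sphere** — larger solid nodules spanning three consecutive slices;
  the outer layers follow the offset profile
  $q_v(r) = q_{\max} e^{-(r^2+v^2)/\rho^2}$ with inter-slice offset $v$
  (default 7 pixels) and therefore have radius $\sqrt{R^2 - v^2}$;
* **hollow_sphere** — cavity nodules; the interior out to 75% of $R$
  is removed from the support mask (excluded from matching rather than
  filled with a background value, so the cavity's unknown content never
  biases the correlation);
* **semicircle** — juxtapleural (lung-wall) nodules; the `angle`
  parameter is the direction of the outward normal of the flat edge,
  measured counterclockwise from $+x$.

The closed-form gray-level density of the 2D template,

$$\psi(q \mid q_{\min}, q_{\max}) = 2\pi R
  \sqrt{\frac{\ln q_{\max} - \ln q}{\ln q_{\max} - \ln q_{\min}}},$$

is implemented exactly in this form (`gray_level_density()`). Note that
it omits the $1/q$ Jacobian a strict change of variables would add; we
treat it as an unnormalized profile and normalize numerically when
comparing against empirical histograms. The discrepancy is small — the
Kolmogorov distance between the normalized closed form and the gray
histogram of a rendered circle template is about 0.05 for $R \ge 15$ —
and the tests bound it at 0.1.

Rasterization uses pixel-center membership (a pixel belongs to the
support if its center lies within the shape) with no anti-aliasing, on
odd-sided stencils of side $2\lceil R \rceil + 1$ so the template center
is a single pixel.

## Matching by genetic search

Matching maximizes the normalized cross-correlation (NCC) between a
rendered template and the congruent subvolume, restricted to the
template's support mask. NCC is invariant to affine gray rescaling, so
the same template matches nodules of varying contrast. Windows that
leave the volume are invalid (score $-\infty$) rather than padded —
padding would bias the correlation; windows with zero gray variance are
likewise invalid.

The search space is not the whole volume: a prior segmentation of
vessels, bronchi and abnormalities (supplied as a mask, or approximated
by `space_from_threshold()`) provides the candidate locations. Small
components are discarded (26-connectivity) and in-plane enclosed holes
are filled, because region-based segmentations return filled objects and
the center of a cavity nodule — where the hollow template must sit —
lies in its enclosed interior.

A genetic algorithm optimizes position, radius and (semicircles)
orientation. Chromosomes are bit strings: 9/9/5 position bits, 5 radius
bits and, for semicircles, a 4-bit angle gene in 22.5° steps. Position
fields are resized to the smallest width that covers each axis of the
actual volume; on a small volume the clinical-scale defaults would
waste most mutations on positions that decode off-lattice and are
immediately repaired. Crossover is single-point at rate 0.75 and mutation per-bit at
rate 0.05; locations falling outside the search space are repaired to
the Euclidean-nearest member (ties broken lexicographically). The
population (default 100) is split across the connected components of the
search space proportionally to their voxel counts (floor of 20): each
segmented object evolves its own subpopulation, so a weakly correlated
object — a cavity nodule whose thin ring yields NCC ceilings near 0.9 —
cannot be starved of evaluations by a brighter object elsewhere. Within
a component, generations (default 50) use deterministic crowding: each
child competes only against its phenotypically nearest parent. Crowding
was chosen over plain tournament selection after the latter collapsed
the whole population onto the single best nodule; a multi-nodule image
is a multimodal optimization problem, and crowding is the standard
parameterless niching scheme for it. Each component's run ends with a
memetic polish: the full radius/angle codebook is rescored over a small
neighborhood ($\pm4$ in-plane, $\pm1$ slice) of the component's best
individual, pinning near-converged niches to their exact optimum.

Every individual ever evaluated whose similarity exceeds the threshold
(default 0.8) is harvested, not only the final population. The harvest
is deduplicated by greedy non-maximum suppression (descending score;
suppress centers within $\max(R_i, R_j)$ voxels of an accepted one).
`exhaustive_match()` evaluates every location/radius/angle combination
and serves as the reference oracle the GA is measured against in the
tests.

## False-positive reduction

Each candidate is summarized by three features:

* $U = \max_\theta d(\theta) - \min_\theta d(\theta)$, the radial
  nonuniformity of the segmented object's border around the candidate
  center, from rays cast in 8 directions (0.25-pixel steps, bilinear
  mask interpolation, stopping at the first background crossing), on the
  single slice through the center;
* $q_{\mathrm{ave}}$, the mean gray level over the template support;
* $q_{10}$, the 10th-percentile gray level over the support, with
  lower-value interpolation (`quantile(type = 1)`): the threshold below
  which 10% of support voxels fall.

A naive Bayes rule with equal priors classifies candidates as true
(TPN) or false (FPN) positives; the three features are treated as
independent, and each class-conditional density is a linear combination
of Gaussians (LCG) allowed to carry negative-weight components. The fit
is sequential: positive components by standard univariate EM
(quantile-spread initialization with seeded jitter, variance floored at
$10^{-4}\widehat{\sigma}^2$, convergence at relative log-likelihood
change below $10^{-6}$ or 500 iterations), then negative components
placed greedily on the largest lobes where the positive mixture
overshoots a kernel estimate of the empirical density, their weights
halved until the total density is non-negative over the evaluation
range. Signed weights always sum to one, so the model integrates to one.
A fully joint re-estimation of all components was considered and
dropped: the sequential construction already satisfies every property
the classifier relies on (non-negativity, normalization, generator
recovery), and the joint step adds a second, harder-to-diagnose
optimization for no measured gain at this training size. With no
negative components the fit is a standard Gaussian mixture, and the
tests verify it is a fixed point of a reference EM implementation
(mclust).

Lung-wall (semicircular) candidates are classified from the two gray
features only: their center sits on the flat edge against the pleura, so
$U$ is dominated by the wall geometry rather than the nodule. A
posterior of exactly 0.5 resolves to FPN, favoring specificity. Default
component counts are 2 positive and 1 negative per density; the exact
counts used by the modified-EM literature are not fixed, and with 20
training samples per class anything richer overfits.

## The phantom generator

`make_phantom()` renders nodules with the same analytic templates the
matcher probes with, on a uniform background (default gray 20), plus
vessel-like tubes with the identical Gaussian radial profile (the
canonical false-positive confusers) and additive Gaussian noise. The
mask returned is the noiseless foreground — the stand-in for the tissue
segmentation. Because plant and probe share one renderer, a planted
nodule's NCC optimum is exactly its true parameters, which makes the
phantom a sharp oracle for recovery experiments; what it does *not*
emulate is real CT texture, partial-volume blur, speculated or irregular
nodule boundaries, or nodules attached to vessels, so passing recovery
tests here demonstrates the search machinery, not clinical sensitivity.

The canonical evaluation volume (`default_nodule_layout()`) is
$128 \times 128 \times 9$ voxels with ten non-overlapping nodules on a
grid — radii 5–20 pixels, all four shapes, two semicircle orientations —
plus three vessels, at noise $\sigma = 5$; this size keeps an exhaustive
oracle run affordable while exercising every shape class. The feature
generator (`make_feature_training_set()`) draws 20 samples per class
(vessel-like FPN, lung TPN, wall TPN) by default. Its class means are
not arbitrary: a rendered 2D template has
$q_{\mathrm{ave}} = q_{\max}(1 - q_{\min}/q_{\max}) / \ln(q_{\max}/q_{\min})
\approx 136$ and $q_{10} = q_{\max} e^{-0.9 \ln(q_{\max}/q_{\min})}
\approx 70$ for the default calibration, so the TPN classes center
there; FPNs get lower gray statistics (thin vessels suffer partial
volume) and large $U$ (elongated cross-sections), wall TPNs sit slightly
below lung TPNs.

## Numerical choices and limitations

* Gray levels are stored as doubles throughout, even for 8-bit sources,
  so continuous profiles compare exactly.
* Coordinates are 0-based $(x, y, z)$ triples with $z$ the slice axis,
  including in all serialized CSV output (asserted on read).
* The NCC kernel and connected-component labeling are small C++
  routines; everything else is plain R over them.
* `run_pipeline()` re-scores each merged candidate over the radius
  codebook and $\pm1$-voxel center offsets (`refine_candidates()`)
  before feature extraction: features measured on a support inflated by
  a few pixels of radius error would otherwise leak background into
  $q_{\mathrm{ave}}$.
* Ground-truth scoring uses a matching radius of $\max(3, R/2)$ voxels,
  a size-proportional criterion exposed as a pipeline argument.
* The GA's recall is inherently stochastic; the tests run it under
  fixed seeds against the exhaustive oracle and require 90% recovery on
  the canonical phantom. Cavity nodules are the hardest class — their
  NCC ceiling under noise is the lowest and their basin of attraction
  the narrowest — and they dominate the residual misses.
* The two preprocessing segmentation stages of a clinical pipeline are
  out of scope; the threshold stand-in assumes the gray modes of
  tissue and background are separable, which real LDCT only
  approximates.
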