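---
title: "Wavelet-domain fuzzy segmentation of dermoscopic images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain fuzzy segmentation of dermoscopic images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermseg)
```

## The problem

Dermoscopic photographs show a pigmented lesion — typically darker and
texturally distinct — on surrounding skin. Computer-aided diagnosis pipelines
need a binary lesion/skin segmentation as their first step, and the
clinically interesting measure of a segmenter is how well a continuous
per-pixel lesion score separates the two classes, summarized by the area
under the ROC curve (AUC) against a dermatologist-drawn ground-truth mask.

`dermseg` implements a family of clustering segmenters that operate on
wavelet-transform features of the three color channels:

* **WK-Means** — K-means on each channel's wavelet feature image;
* **W-FCM** — fuzzy C-means (FCM) on the same features;
* **W-CPSFCM** — FCM whose cluster count is chosen automatically by a
  Mamdani fuzzy inference system (cluster preselection);
* the same three without the wavelet step (`kmeans`, `fcm`, `cpsfcm`); and
* a statistical region merging (**SRM**) baseline.

## The pipeline

For an RGB image $I[n,m]$ the `w*` methods proceed channel by channel:

1. **Wavelet feature.** One scale of the separable 2-D discrete wavelet
   transform (Mallat pyramid) splits the channel into an approximation
   subband $A$ and detail subbands $D_h, D_v, D_d$. The default feature is
   $A$ at scale $J$; alternatively the detail magnitude
   $|W| = D_h^2 + D_v^2 + D_d^2$ with orientation phase
   $\Theta = \alpha$ or $\pi - \alpha$ (by the sign of $D_h$),
   $\alpha = \arctan(D_v / D_h)$. Note the magnitude is the *sum of squares*
   by default; a `sqrt_magnitude` switch yields the Euclidean norm instead —
   downstream clustering differs only in the geometry of cluster centers
   under this monotone transform. The feature is resampled back to the image
   grid by nearest neighbor and affinely rescaled to $[0, 255]$.
2. **Clustering.** The feature's pixel intensities are clustered
   (K-means, FCM, or CPSFCM), and converted into a continuous lesion score:
   the cluster with the lowest center is the lesion (lesions are darker;
   `polarity = "light"` flips this), the score is the FCM membership to the
   lesion cluster(s), or for K-means the soft distance ratio
   $1 - d_\text{lesion} / (d_\text{lesion} + d_\text{other})$. With more
   than two clusters, every cluster whose center falls below the weighted
   global mean intensity counts as lesion and their memberships sum.
3. **Fusion.** The red channel's score map is aligned with the green by
   nearest-neighbor interpolation (NNI) and averaged; the result is fused
   with the blue the same way. The fused score in $[0,1]$ is the
   classifier output the ROC sweep needs; thresholding at 0.5 gives the
   default binary mask.

Fusing *continuous scores* rather than label maps is a deliberate design
choice: the evaluation protocol sweeps a classification threshold, which
requires a graded output, and averaging label maps would be ill-defined.
Fusion by mean is commutative and idempotent.

## Models

**K-means** alternates nearest-centroid assignment (squared Euclidean
distance, lowest index on ties) with centroid means until no centroid moves
more than `tol`. Initialization is deterministic farthest-point seeding
started from the point nearest the global mean, so runs are reproducible
without randomness; optional seeded restarts exist. An emptied cluster is
re-seeded at the point farthest from its centroid.

**FCM** minimizes
$E = \sum_j \sum_i \mu_{ij}^k \lVert x_i - c_j \rVert^2$
by alternating the membership update
$\mu_{ij} = 1 / \sum_m (\lVert x_i - c_j\rVert / \lVert x_i - c_m\rVert)^{2/(k-1)}$
with the weighted center update
$c_j = \sum_i \mu_{ij}^k x_i / \sum_i \mu_{ij}^k$. Every membership column
sums to one; a point coinciding with a center takes the limiting crisp
membership (uniform over coinciding centers). The objective is
non-increasing across iterations — asserted in the test suite on every run.
Defaults: fuzziness $k = 2$, `tol = 1e-5` on $|\Delta E|$, 300 iterations
cap. These are documented choices; the source method leaves them to the
user.

**CPSFCM** preselects the cluster count: the two most similar channels
(smallest sum of squared per-pixel differences — compared without the
square root, which orders pairs identically) are averaged into a grayscale
image; its intensity range $D = V_{\max} - V_{\min}$ and the pixel count
feed a Mamdani system with six Gaussian "Distance" sets, five "Size" sets
and five "Cluster" sets. For each candidate count $c \in [2, 40]$,
$Q(c) = \max_i \min\{\min\{\mu_\text{dist}(D), \mu_\text{size}(s)\},
\mu_i(c)\}$ over 30 rules; the argmax (smallest on ties) is $N$. Cluster
counts are integers, so max-membership defuzzification over the integer
grid is used rather than centroid defuzzification. FCM then starts from
equidistant centers $c_j = V_{\min} + jD/N$ — anchored at $V_{\min}$ so the
centers lie inside the data — and converges in few iterations.

The published description of this system does not enumerate its 30 rules,
and its set-parameter tables label the width column "Variance". Two
decisions follow. First, the default rule base is the monotone 6×5 grid
with consequent rank $\mathrm{clamp}(\lfloor (i+j)/2 \rfloor, 1, 5)$ —
small range and small image give "very few" clusters, maximal both give
"too many" — and both the rules and the sets are replaceable through plain
text files (`read_rules()`, `read_fuzzy_sets()`). Second, the width column
is interpreted as the Gaussian spread $\sigma$, not $\sigma^2$: values like
16–45 on a 0–255 universe are plausible spreads, while as variances the
sets would be needle-thin and leave most of the universe uncovered.

**SRM** sorts 4-adjacent pixel pairs by the maximum channel difference and
merges regions whose channel averages differ by at most
$\sqrt{b^2(R) + b^2(R')}$ with
$b(R) = g\sqrt{\ln(2/\delta) / (2Q|R|)}$, $\delta = 1/(6|I|^2)$ — the
canonical bound of the SRM literature, since the method's defining
publication family leaves $b$ implicit; an `as_printed` variant comparing
against $b^2(R) + b^2(R')$ without the square root is available behind a
flag. Its score map inverts region mean brightness so SRM, too, yields a
continuous output.

## Wavelet implementation notes

No wavelet transform was available as an R dependency, so the Mallat
pyramid is implemented in the package, with two boundary conventions:

* **symmetric** (default): half-sample reflection; each level stores
  $\lfloor (n + L - 1)/2 \rfloor$ coefficients per axis per subband
  ($L$ = filter length). This expansive convention makes the round trip
  exact (~1e-10 per pixel orthonormal, better than 1e-6 for
  biorthogonal 6.8) for arbitrary sizes and avoids wrap-around artifacts.
* **periodization**: circular, non-expansive ($n/2$ per axis, even $n$
  only). Under it, orthonormal banks conserve energy *exactly*
  (Parseval); under symmetric extension the extra boundary coefficients
  break exact energy equality, which is why the energy test runs in this
  mode.

Built-in banks: Haar, Daubechies 4, Coiflets 3, biorthogonal 6.8, with the
canonical published coefficients. Other families — e.g. atomic-function
wavelets, whose coefficients are not published — load from four-section
plain-text coefficient files (`read_filter_bank()`).

One subtlety matters for accuracy: a subband sample $m$ is centered at
input coordinate $2m - L/2 + 0.5$ under the symmetric offset convention
($2m - 0.5$ under periodization). `feature_image()` compensates for this
group delay when resampling the subband back to the image grid; ignoring
it shifts the feature by $\approx L/2$ pixels and visibly smears every
lesion boundary. The generic `nni_resample()` — used for fusing score maps
of equal provenance, where no relative delay exists — keeps the plain
half-pixel-center convention.

The number of scales $J$ defaults to 1 (a single decomposition step, as in
the framework's flow diagram); deeper pyramids are configurable, and an
inadmissible $J$ errors naming the maximum.

## Synthetic validation data

Real dermoscopy atlases are not redistributable, so validation runs on a
deterministic generator (`generate_lesion()`): an elliptical lesion whose
polar radius is modulated by a low-order random Fourier series (irregular
border), radially shaded interior, on a light-tan textured skin background,
with per-pixel Gaussian noise added last; the ground-truth mask is the
exact pre-noise region. The shading and texture fields are mean-centered
within each region, so the configured `contrast` is *exactly* the mean
gray-level gap between skin and lesion, and in the noiseless limit
thresholding at the contrast midpoint recovers the mask exactly — the
fixtures are solvable by construction. All randomness flows from one
Mersenne-Twister seed and the session RNG state is restored afterwards.

The standard suite crosses contrast {30, 60, 100} with noise
$\sigma$ {5, 15, 25} at 128×128 — sizes chosen so the whole suite segments
in well under a minute per method. Defaults (radius 0.28 of the image
side, eccentricity 0.8, irregularity 0.25, shading 8 and texture 4 gray
levels) give lesions covering ~15–25% of the frame, in line with typical
cropped dermoscopy framing.

What the fixtures do *not* emulate: hair and ruler occlusions (the source
imagery is pre-cleaned), vignetting, chromatic texture (the generator's
deviations are achromatic, so channel fusion mainly averages noise), and
multi-focal pigmentation. Passing on these fixtures therefore demonstrates
correct mechanics and noise robustness, not clinical performance.

## Numerical and degenerate-input choices

* Affine rescale to $[0,255]$ returns flat inputs unchanged (no 0/0).
* $\Theta$ at $D_h = 0$ takes the arctangent limit: $\pi/2$, $3\pi/2$, or 0.
* Constant images and constant feature channels degenerate to a single
  cluster with a warning and a uniform score.
* Argmin/argmax ties resolve to the lowest index everywhere, making every
  path deterministic given its inputs.
* ROC thresholds are the unique score values (quantile-capped on request),
  masks use the closed rule `score >= t`, and the trapezoidal AUC then
  equals the Mann–Whitney pair statistic with half credit for ties — the
  suite asserts agreement with a brute-force pairwise oracle to 1e-12.
* Undefined sensitivity/specificity (an empty class) yields `NA`, not an
  error, keeping batch tables rectangular.

## Known limitations

* A half-resolution subband sample that straddles the lesion border gives
  one score to pixels of both classes, so the wavelet methods cannot reach
  exact sensitivity = specificity = 1 on curved boundaries; exact
  separation is demonstrated on dyadic-aligned two-level images, where the
  Haar bank preserves two-level structure exactly (longer filters ring at
  step edges).
* Noise tails widen an image's intensity range, and wavelet features are
  rescaled to the full $[0,255]$, so the preselection's range input
  saturates on wavelet features; the automatic count is most informative
  for the raw-channel CPSFCM.
* SRM's union-find is plain R; at 128×128 it takes a few seconds per
  image, which is fine for validation but not interactive use.
* 16-bit PNG output is not portably writable here; score maps are written
  as 8-bit PNG previews plus lossless plain-text `.tsv` companions.
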