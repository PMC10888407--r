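---
title: "Unsupervised two-stain IHC scoring: model, parameters and design"
author: "ihcscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised two-stain IHC scoring: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The model

A bright-field image of tissue stained with hematoxylin (H, nuclei) and
DAB (brown chromogen marking the protein of interest) mixes the two dyes
multiplicatively in intensity, hence additively in optical density. With
`Io` the incident intensity (255 for 8-bit images), each pixel's OD
vector is

$$x_n = -\log(I_n / I_o) \approx W h_n, \qquad h_n \ge 0,$$

where the columns of the 3×2 matrix $W$ are the per-channel absorbances
of the two stains and $h_n$ their concentrations at pixel $n$. Scoring a
cohort means (i) estimating $W$ and $H$ per image with no reference
image or annotation, (ii) summarizing each image's DAB content in a few
scalar features, and (iii) clustering the cohort into five ordered
expression levels.

Key assumptions, inherited from the physics and the staining chemistry:

* OD vectors live (up to noise) in the cone spanned by the two stain
  vectors; the third principal component of the uncentered second-moment
  matrix is negligible.
* Many pixels are *stain-dominant*: nuclei carry almost pure
  hematoxylin, DAB deposits sit mostly outside nuclei. The angular
  density of the projected OD cloud therefore peaks near the two stain
  directions.
* Features increase (in general) with DAB expression, so the norm of the
  feature vector orders the cohort and can initialize the clustering
  deterministically.

## Stain separation

**Uncentered PCA.** We eigendecompose $R = XX^\top/N$ without mean
subtraction — centering would destroy the cone geometry of OD data. The
two leading eigenvectors $q_1, q_2$ (eigenvalues $L_1 \ge L_2$) span the
stain plane. Eigenvector signs are fixed by requiring a non-negative
entry sum, so angles land in a reproducible frame.

**Unit-power projections.** The projections are
$Z = \mathrm{diag}(L_1^{-1/2}, L_2^{-1/2})\,[q_1\,q_2]^\top X$, so each
row of $Z$ has mean square one. Because both stains are absorbent in all
channels, their directions are only ~37° apart in OD space; equalizing
component powers stretches the minor direction and widens the angular
gap, which is what makes the density peaks resolvable. The lift back to
3-D, $\hat W = [q_1\sqrt{L_1}\; q_2\sqrt{L_2}]\,\hat B$, is the exact
inverse of the projection on the plane.

**Angular density peaks.** Foreground pixel angles
$\theta_n = \mathrm{atan2}(z_{2n}, z_{1n})$ are binned into 1000 equal
bins over the occupied range; each bin stores the mean projection norm
of its members (empty bins hold 0 — peaks live in dense regions, so
interpolation would buy nothing). The profile is smoothed by an
eighth-order Butterworth low-pass filter with normalized cutoff 0.035,
applied forward and backward (zero phase) so peak positions do not
shift; the filter input is padded by symmetric reflection (500 bins) to
suppress the IIR boundary transient. One stain angle is the global
maximum of the smoothed profile; because spurious secondary bumps can
shadow the true second peak, the other angle is the maximum over the
half of the angular range not containing the first peak. A column with
no density in the opposite half marks a single-stain image, which is
flagged degenerate and later handled with the cohort-average basis.

**Stain identity.** The two estimated columns are ordered
(hematoxylin, DAB) by cosine similarity to the classical reference OD
directions (0.650, 0.704, 0.286) and (0.269, 0.568, 0.778); ties break
toward the larger blue-channel OD being DAB. This makes column order
deterministic and biologically meaningful; the reference vectors play no
role in the estimation itself.

**Deconvolution and refinement.** Concentrations solve the
overdetermined system by the left pseudoinverse,
$\hat H = (\hat W^\top \hat W)^{-1} \hat W^\top X$; negative entries are
clipped to zero, and any pixel left with exactly one positive
concentration is refit against that single stain vector
($h = \max(0, w^\top x / \|w\|^2)$), removing the bias that discarding
the negative component would leave. The basis is then re-estimated once:
for each stain, the planar projections of pixels whose concentration is
at least 10× the other stain's are averaged (and renormalized), the
refined basis lifted, and the concentrations recomputed. A stain with no
dominant pixels keeps its previous column. We run exactly one refinement
pass; iterating further mostly re-selects the same dominant pixels.

**Cohort stage.** The per-image bases (excluding degenerate fits and
physically implausible ones — any lifted entry below −0.05 of its column
norm) are averaged entry-wise into $\bar W$, and every image is
re-deconvolved with $\bar W$. This stabilizes images with very low DAB,
whose own DAB column is poorly determined while their concentrations
under the shared basis remain accurate.

## Features

With $\bar w_2$ the DAB column of $\bar W$ and $\bar h^m_2$ image $m$'s
DAB concentration row under the shared basis ($N_m$ pixels):

* $f_1$: mean DAB intensity
  $M_1(m) = \frac{1}{3N_m}\|\bar w_2\|_1 \|\bar h^m_2\|_1$, divided by
  its cohort maximum. Dimensionless, in [0, 1], maximum exactly 1.
* $f_2$: robust-maximum ratio. $R_s(m)$ is the 99th percentile of the
  entries of the rank-one intensity matrix $\bar w_s \bar h^m_s$ (all
  $3N_m$ entries, linear-interpolation percentile). With
  $m^\* = \arg\max_m R_2(m)$,
  $f_2(m) = [R_2(m)/R_2(m^\*)]\,/\,[R_1(m)/R_1(m^\*)]$. A floor of
  $10^{-9}$ on $R_1$ guards hematoxylin-free synthetic edge cases; real
  two-stain tissue always has $R_1 > 0$.
* $f_3$: like $f_1$ with 2-norms (root mean power),
  $M_3(m) = \frac{1}{3N_m}\|\bar w_2\|_2 \|\bar h^m_2\|_2$, cohort-max
  normalized.
* $f_4$: $\frac{1}{\sqrt{3N_m}}\|\hat w^m_2\|_2 \|\hat h^m_2\|_2$ under
  each image's *own* basis — OD units, not cohort-normalized, degree-one
  homogeneous in the concentrations. Degenerate images fall back to the
  shared basis and are flagged.

Each feature normalizes by its own image's pixel count, so cohorts may
mix magnifications. $f_1$–$f_3$ are invariant to the intensity-scale
split between $W$ and $H$; all four are pixel-permutation invariant.

## Scoring

The feature vector norm $\|f(m)\|_p$ orders the cohort. Sorted norms
follow, approximately, a power function of the rank; raising them to a
power $q$ straightens the curve so that five equal-length intervals of
$\|f(m)\|_p^q$ are a sensible initial partition. $q$ is fitted
automatically: each half of the sorted sequence is fitted as
$y = a\,\mathrm{rank}^b$ by least squares on the raw scale (the log-log
slope only seeds the fit — on tier-structured cohorts a pure log-log
regression underweights the upper curvature and overestimates $q$), and
$q = 2/(b_1 + b_2)$; with four features this comes out close to 1/2. The
fallback when a half has too few positive values is $q = 1/2$.

Intervals are half-open $[\ell, u)$ with the top interval closed (the
boundary rule is ours; only boundary-sitting images feel it). Initial
centroids are member means; an empty interval receives the uniform
vector whose reshaped norm equals the interval midpoint,
$(v^{\*1/q}/T^{1/p})\,\mathbf 1$. k-means then runs exactly three
assignment+update rounds with distance $\|x - c\|_p$ (a cluster that
empties keeps its centroid frozen), and scores follow the ascending
p-norm order of the final centroids. Everything is deterministic;
rescoring identical inputs yields byte-identical output.

Defaults follow the validated configurations per feature-subset size:

| features used        | p   | q       | iterations |
|----------------------|-----|---------|------------|
| f1, f2               | 1.5 | 1/1.8   | 1          |
| f1, f2, f3           | 1.9 | 1/1.75  | 2          |
| f1, f2, f3, f4       | 2.5 | auto (≈1/2) | 3      |

$p$ outside [1, 3] warns: the method is only validated inside that
interval, where results are insensitive to $p$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_floor` | 1 intensity level | clip before the log; keeps OD finite at I = 0 |
| `tau_bg` | 0.05 OD (1-norm) | background mask for the angular profile only; 0 disables |
| `n_bins` | 1000 | angular resolution of the density profile |
| `butter_order`, `butter_cutoff` | 8, 0.035 | profile smoothing filter |
| `dominance` | 10 | concentration ratio defining stain-dominant pixels |
| `eps_rank` | 1e-4 | `L2/L1` below this flags a single-stain image |
| `n_clusters` | 5 | score levels |

The natural logarithm is used throughout; any fixed base rescales all OD
vectors uniformly and cancels in every angle, ratio and normalized
feature. Background pixels are excluded only from the angular profile:
their angles are noise-dominated while their concentrations are ≈ 0
anyway, so they are harmless in deconvolution and features.

## The synthetic generator

The paper-style validation data (xenograft tumor cohorts scored by
experts) is not redistributable, so the package ships a generator whose
cohorts exercise every stage against known ground truth. Each image is
built in concentration space and rendered through the exact forward
model ($X = WH$ plus OD-space Gaussian noise, then 8-bit quantization):

* **Hematoxylin**: ~60 Gaussian nuclear blobs (sd 1.5 px) with lognormal
  amplitudes (median 1.5 OD), floored at 0.2 so nuclei have crisp
  boundaries rather than sub-quantization halos.
* **DAB**: a smooth random field (bilinear interpolation of a coarse
  Gaussian grid) thresholded at zero — leaving genuinely DAB-free tissue
  — then compressed onto a moderate plateau so even tier-5 images stay
  out of the deep quantization regime (real acquisitions are exposed to
  avoid saturation). DAB is excluded from nuclear pixels, emulating a
  cytoplasmic/membrane chromogen displaced by the nucleus.
* **Tiers**: the field is normalized to unit mean over tissue and scaled
  by `tier_dab_scale` = (0.05, 0.3, 0.8, 1.5, 2.5) across five tiers —
  roughly quadratic in tier, the shape the norm-reshaping stage expects.
* **Background**: an unstained band (15% of the image) on a random side.
* **Noise**: additive OD-space Gaussian (sd 0.02), chosen over Poisson
  shot noise because the method is linear in OD space where its
  assumptions live.

Early versions drew nuclei additively on top of an everywhere-positive
DAB field. That violates the stain-dominance assumption the angular-peak
estimator rests on — with strong DAB under every nucleus there are no
hematoxylin-dominant pixels, and the estimated H direction drifts by
tens of degrees — and saturated tier-5 renderings scattered dark-pixel
angles through quantization. Both failure modes are properties of
unrealistic imagery, not of the estimator; the displacement and plateau
design reflects how real tissue behaves (nuclei stay visibly blue even
in strongly DAB-positive fields).

What the generator does *not* emulate: chromatic stain variability
(every pixel mixes the same two directions), uneven illumination,
tissue texture within nuclei and stroma, out-of-focus blur, and
overlapping chromogen co-localization. Passing tests therefore
demonstrate correctness of the algorithmic chain under the stated model,
not robustness to scanner- or protocol-level artifacts.

## Numerical choices and degenerate inputs

* Problem sizes: validation cohorts are 20–50 images of 64×64 pixels —
  large enough that every stage (including the 1000-bin profile) behaves
  as at full size, while a full cohort run stays in seconds.
* The left pseudoinverse is computed by solving the 2×2 normal
  equations; the basis is rejected as rank-deficient when the Gram
  determinant vanishes relative to its diagonal.
* Lifted basis entries in (−10⁻⁶, 0) are clipped silently (projection
  leakage); an entry below −0.05 of its column norm warns and excludes
  the image from the cohort average.
* All-zero OD matrices (blank images), single-angle profiles, cohorts
  with identical feature norms, and DAB-free cohorts raise informative
  errors; degenerate rank-one images are scored with the cohort basis
  and flagged rather than dropped.
* Ties in the k-means assignment go to the lowest cluster index; ties in
  centroid norms keep cluster-index order — both arbitrary but fixed, so
  determinism holds.

## Limitations

Two chromatic stains only: no fluorescence, no >2-stain unmixing, no
whole-slide formats, no illumination correction (`Io` is a fixed
scalar). The features deliberately quantify *amount* of DAB, not its
subcellular localization; images whose diagnostic difference is purely
spatial will not be distinguished. Scores are cohort-relative by
construction (two features are cohort-max normalized), so a score is
meaningful only within the cohort it was computed in.
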