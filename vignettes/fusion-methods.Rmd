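---
title: "Multi-modal medical image fusion in the shift-invariant shearlet domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal medical image fusion in the shift-invariant shearlet domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Different imaging modalities of the same anatomy carry complementary
information: CT renders bone and dense structure, MRI soft tissue, PET
metabolic activity. Image fusion combines two co-registered slices into a
single image that preserves the salient content of both. `sistfuse`
implements a transform-domain fusion chain: decompose both sources with a
shift-invariant shearlet transform (SIST), fuse the directional high-pass
subbands with a learned per-pixel decision map, fuse the low-pass subband
with a keypoint-matching rule, and invert the transform.

This vignette records the model, the tunable parameters, the numerical
choices, and the design decisions taken where the procedure was genuinely
open — in the level of detail a maintainer needs to modify the package
safely.

# The transform

## Non-subsampled pyramid

The multiscale step is an undecimated (a-trous) pyramid: at level $j$ the
running low-pass $f^j$ is filtered with a separable maximally-flat binomial
kernel — by default $\tfrac{1}{16}(1,4,6,4,1)$, dilated by $2^{j-1}$ — and
the high-pass detail is the difference
$g^{j+1} = f^j - f^{j+1}$. Nothing is downsampled, every plane keeps the
input's resolution, and reconstruction is the plain sum
$f^0 = f^M + \sum_j g^j$, which holds to machine precision by construction.
All filtering is performed in the FFT domain with periodic (circular)
boundary handling, so the transform commutes *exactly* with circular
translation — the property the tests pin down to $10^{-8}$.

The kernel half-order is a configuration constant (`maxflat_order`, default
2). Changing it changes the scale partition but not any reconstruction or
invariance identity, which is why those identities rather than specific
coefficient values are what the test suite asserts.

## Directional localization

Each level's high-pass plane is split into $2^k$ directional subbands by
multiplying its FFT with smooth angular windows. The angle variable is
*pseudo-polar*: piecewise linear in the shear $\xi_2/\xi_1$ on the
horizontal frequency cone and $\xi_1/\xi_2$ on the vertical cone, which
matches the shearlet tiling and is exact on the cone diagonals. On this
angle we place raised-cosine ($\cos^2$) bumps with spacing $\pi/n$: adjacent
bumps overlap and sum to one *identically*, so the squared windows returned
by `build_shearing_filters()` tile the frequency plane exactly
($\sum_k |W_k|^2 = 1$ at every bin).

One convention deserves emphasis: decomposition multiplies the spectrum by
the *squared* window $W_k^2$. This folds the analysis and synthesis halves
of the tight frame into one step, so that (a) the directional planes of a
level sum exactly to that level's pyramid plane and (b) inversion is plain
summation over all planes. The alternative — applying $W_k$ twice, once in
each direction — is algebraically identical at reconstruction but leaves
the individual planes without the additive property that makes the fusion
rules and the tests simple.

The DC bin, where the angle is undefined, is shared equally among the
directions; the pyramid high-pass planes carry essentially no DC energy, so
this choice is inert.

Levels are ordered finest (level 1) to coarsest; the default configuration
uses 4 levels with 32, 32, 16, 16 directions — more orientations at the
finer scales, where directional detail lives.

Inputs with non-dyadic sides are reflect-padded to the next power of two
and cropped after reconstruction; the Meyer-type windows and the dilated
kernels assume dyadic grids.

# The high-pass fusion rule

High-pass coefficients are fused by a per-pixel convex combination
$F_H = D \cdot A_H + (1 - D) \cdot B_H$ driven by a decision map $D$
produced in four steps.

**Feature detection.** A small siamese network scores 16×16 sliding-window
patch pairs: two identical branches (three 3×3 convolutions, stride 1,
ReLU, then one 2×2 max-pool with span 2, channels 16–32–64) produce feature
vectors $\phi(A)$ and $\phi(B)$; the head maps the *difference*
$\phi(A) - \phi(B)$ through a bias-free linear layer and a sigmoid. This
antisymmetric head is a deliberate design choice where the architecture was
open: it enforces $s(A,B) + s(B,A) = 1$ identically and pins identical
patches to exactly 0.5, which makes self-fusion an exact fixed point of the
entire pipeline rather than an approximate one.

The network runs once per *level*, not per directional subband, on the
aggregate root-sum-square energy plane of that level's directions. A
per-direction pass would cost 96 forward sweeps instead of 4 per image pair
with no stated benefit, and a shared per-level map keeps the directions of
a level mutually consistent. This granularity is an interpretation — the
procedure could equally be read as per-subband — and is recorded as such.

Subband windows are affinely normalized to $[0,1]$ per window pair (joint
min/max) before scoring, because the network is trained on $[0,1]$
intensity patches while subband coefficients are signed and unbounded.

**Training.** No clinical training corpus is bundled; the network is
trained at desk scale on synthetic pairs from `make_training_pairs()`: a
procedurally textured sharp patch versus a Gaussian-degraded copy (blur
width uniform in 0.75–3 px), labels balanced, everything a pure function of
the seed. The loss is binary cross-entropy with Adam (learning rate
$10^{-3}$, batch 64, 12 epochs over 2000 pairs by default; roughly a minute
on one CPU core). A 20% held-out split is scored after training and stored
in the model metadata; the suite requires ≥ 0.90 and verifies a
label-shuffled control sits at chance. What this proxy task trains is a
*relative sharpness / feature-energy* detector; what it does not give is
the modality-specific semantics a network trained on clinical pairs would
learn. Passing tests therefore demonstrate the mechanism, not clinical
performance.

**Segmentation and consistency verification.** The window scores are
spread back over the pixel grid — each pixel averages the scores of every
window covering it (windows slide with stride 2 by default; border pixels
the stride skips inherit the nearest covered value) — and thresholded
strictly at $\tau = 0.5$ (suggested range 0.4–0.7 for non-medical
imagery). The resulting binary map is refined by a guided filter (radius
$r = 8$, regularization $\varepsilon = 0.1$) guided by the mean aggregate
source plane $(E_A + E_B)/2$: an edge-preserving smoother that removes
isolated misclassifications while letting the decision boundary follow real
edges. The guide choice is ours; the refined map is kept *soft* (clamped to
$[0,1]$, not re-binarized), reading the final combination as a genuinely
pixel-weighted scheme.

The guided filter itself is the standard per-window ridge regression with
border-truncated box means; the suite checks it against an independent
brute-force implementation to $10^{-8}$.

# The low-pass fusion rule

The low-pass planes carry the smooth anatomy. Both planes (jointly
normalized to $[0,1]$) are run through a full SIFT
detector–descriptor pipeline implemented in the package:
difference-of-Gaussians scale space (3 scales/octave, base blur 1.6 px, up
to 4 octaves), subpixel refinement, contrast threshold $0.04/3$ and edge
ratio 10, 36-bin orientation assignment, and the 4×4×8 gradient-histogram
descriptor, unit-normalized with 0.2 clipping.

Descriptors are matched by Euclidean distance. Two acceptance criteria are
provided: the default is Lowe's ratio test (nearest < 0.75 × second
nearest); selectable by flag is the literal *second-largest* criterion
(nearest distance strictly below the second largest of the query's sorted
distances). The literal criterion accepts nearly every query once the
candidate set is moderately large, and with exactly two candidates it
compares the nearest distance against itself and can never fire — a
zero-distance (identical) descriptor is therefore special-cased to match.
Both behaviors are tested; neither is silently substituted for the other.

A match survives only if its two keypoints are *colocated* — within 2 px
Euclidean (exact equality of subpixel coordinates would never fire).
Surviving matches mark image regions whose content *and* position agree
across modalities. They are rasterized into a dense binary `match_map` as
disks of radius 6 × keypoint scale (the descriptor support of a SIFT
keypoint spans roughly $6\sigma$), and the low-pass planes combine as
$F_L = \text{match\_map} \cdot A_L + (1 - \text{match\_map}) \cdot B_L$:
the first source wins where the two agree, the second elsewhere. Which
source wins in matched regions is asymmetric by construction and
configurable in spirit (swap the inputs); the swap-sensitivity of the whole
pipeline is measured in the suite and is below 10% on the recovery phantom.
If either plane yields no descriptors the map is all zeros (with a
warning), so $F_L = B_L$; a per-pixel-average fallback is available.

# Quality metrics

Four standard objective measures, computed on the 8-bit scale with 256-bin
histograms:

* **SD** — population standard deviation of the fused image.
* **En** — Shannon entropy, bounded by 8 bits.
* **MI** — fusion mutual information $I(A;F) + I(B;F)$ from 256×256 joint
  histograms (the unnormalized two-term convention).
* **$Q^{AB/F}$** — the Xydeas–Petrović edge-preservation measure: Sobel
  strength/orientation per image, sigmoid preservation factors
  ($\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5$;
  $\Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8$),
  weighted by source edge strength. Two conventions are ours: orientation
  differences are wrapped modulo $\pi$ (keeping the orientation factor in
  $[0,1]$), and the preservation factors are normalized by their value at
  perfect preservation so the measure attains exactly 1 when the fused
  image equals both sources — the raw constants saturate near 0.97, which
  would make the upper bound unreachable. Sobel gradients use circular
  borders, consistent with the package's periodic convention, which makes
  all four metrics exactly invariant to joint circular shifts. The
  constants are exposed in `qabf_params()`.

The entropy/MI quantization is shared (round to 255ths), so the identity
$\mathrm{MI}(A,A,A) = 2\,H(A)$ holds to rounding error. MI estimated from
a 256×256 joint histogram carries a positive small-sample bias of order
$(255)^2 / (2 N \ln 2)$ bits; independence checks in the suite use 256×256
images, where the bias is under a bit.

# Synthetic phantoms

Three seeded generators provide every input the tests need, built from
band-limited noise (white noise shaped to an annulus of normalized
frequency 0.008–0.25 with $1/f$ amplitude weighting, so blob-scale
structure survives the SIFT base blur while fine detail feeds the
sharpness cue) plus soft-edged random ellipses:

* `make_complementary_blur_pair()` — ground truth $G$; source A blurs the
  right half ($\sigma = 3$ px), source B the left. The untouched halves
  equal $G$ verbatim, so the ideal fusion is known and recovery error is
  measurable.
* `make_modality_phantom_pair()` — shared geometry (skull ring, internal
  ellipses) rendered CT-like in one image (bright boundaries, dark
  interior) and MRI-like in the other (soft filled gradients); intensity
  correlation over the shared structures is below 0.5.
* `make_shifted_pair()` — an image and a known circular translation, for
  keypoint colocation tests.

Default size 256×256, matching the standard preprocessing size for
clinical slices. These phantoms exercise the machinery — complementary
sharpness, shared geometry with decorrelated contrast, known ground truth —
but are not physically realistic CT/MRI/PET simulations: no noise model
beyond Gaussian blur, no modality-specific artifacts, no misregistration.
Results on them bound what the pipeline can do under ideal co-registration,
nothing more.

# Numerical choices and degenerate inputs

* Periodic boundaries everywhere (FFT filtering, metric gradients); the
  one exception is SIFT's scale-space pyramid, where window clipping at
  borders follows standard practice.
* Directional planes are kept real: the windows are point-symmetric in
  frequency, so the inverse FFT's imaginary residue is at rounding level
  and is discarded.
* Constant planes: no DoG extrema, so SIFT returns an empty set (not an
  error); score maps on identical inputs are exactly 0.5 by antisymmetry;
  a constant input through the guided filter returns itself.
* Score-window pairs with zero joint range normalize to equal patches and
  score 0.5.
* Reconstruction is clamped to $[0,1]$ before writing: the convex fusion
  rules cannot overshoot, but the transform's band recombination can, by
  rounding-level amounts.
* Max-pool gradient ties break toward the first window offset
  (deterministic); Adam state is rebuilt per call, and every stochastic
  step (split, shuffle, init) derives from explicit seeds, so training is
  bit-reproducible.

# Problem sizes in the test suite

The suite trains the default 2000-pair model once and shares it across
files; the scoring-accuracy check trains a second model plus a
label-shuffled control at the same scale. Transform identities run at
64–256², the guided-filter oracle at 32² (the brute-force oracle is
$O(r^2 HW)$), and end-to-end recovery at the default 256². These sizes are
the package's chosen operating points: large enough that every property is
exercised at the default configuration, small enough that the whole suite
runs in minutes on one core.

# Known limitations

* The scoring network is trained on a synthetic sharpness proxy, not on
  clinical multi-modal pairs; its decision semantics on real CT/MRI data
  are untested here.
* Inputs must be co-registered; there is no registration step.
* Color fusion carries chroma from the functional source unchanged
  (BT.601 luma/chroma); out-of-gamut colors after luma replacement are
  clamped per channel.
* The SIFT implementation targets fidelity and determinism, not speed;
  dense keypoint scenes cost seconds, not milliseconds.
* 3-D volumes, DICOM/NIfTI ingestion, and compactly-supported shearlet
  variants are out of scope.
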