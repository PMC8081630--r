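# sistfuse

Multi-modal medical image fusion in the shift-invariant shearlet domain.

Clinicians routinely read pairs of co-registered slices from different
modalities — CT with MRI, MRI with PET — because no single device captures
bone, soft tissue and function at once. `sistfuse` merges such a pair into
one image that keeps the salient content of both sources. It is aimed at
medical-imaging researchers who need a transparent, fully seeded,
CPU-only fusion pipeline with objective quality scoring and reproducible
synthetic benchmarks.

## Method

Both images are decomposed with a **shift-invariant shearlet transform**
(SIST): an undecimated à-trous pyramid with maximally-flat binomial filters
(4 levels by default) whose high-pass planes are split into directional
subbands (32, 32, 16, 16, finest to coarsest) by Meyer-type windows on the
pseudo-polar frequency grid. Every subband keeps full resolution, the
squared windows tile the frequency plane exactly, and reconstruction is
plain summation — round trips are exact to ~1e-12.

The two subband families are fused by different rules:

* **High-pass (detail):** a siamese CNN (three 3×3 conv layers + 2×2
  max-pool per branch, antisymmetric scoring head) scores 16×16 sliding
  windows of each level's aggregate energy planes; scores are averaged
  into a per-pixel feature map *M*, thresholded strictly at τ = 0.5 into a
  binary map *T*, and refined into a soft decision map *D* by
  guided-filter consistency verification (r = 8, ε = 0.1). Subbands fuse
  as the convex combination `F_H = D·A_H + (1−D)·B_H`.
* **Low-pass (anatomy):** SIFT keypoints and 128-d descriptors are
  extracted from both low-pass planes; descriptor matches (Lowe ratio test
  by default, the literal second-largest-distance criterion by flag) that
  are also **colocated** (≤ 2 px apart) mark regions where content and
  position agree, rasterized into a binary `match_map` of disks; the
  planes fuse as `F_L = match_map·A_L + (1−match_map)·B_L`.

The fused pyramid is inverted and clamped. Quality is scored with four
standard measurements: standard deviation (SD), entropy (En), fusion
mutual information MI = I(A;F) + I(B;F), and the Xydeas–Petrović edge
preservation measure Q^AB/F.

No clinical corpus ships with the package: the CNN trains at desk scale on
seeded synthetic sharp-vs-blurred patch pairs, and seeded phantom
generators (complementary-blur pairs with known ground truth, CT-like vs
MRI-like modality phantoms, shifted pairs) provide every benchmark input.
See `vignettes/fusion-methods.Rmd` for the full model description and
design decisions.

## Worked example

```r
library(sistfuse)

# train the scoring network on 2000 synthetic patch pairs (~1 min, 1 CPU)
pairs <- make_training_pairs(2000, seed = 7)
model <- train_model(build_model(cnn_config(seed = 3)), pairs,
                     epochs = 12, seed = 11)
model$meta$heldout_accuracy

# fuse a 256x256 complementary-blur phantom with known ground truth
cb  <- make_complementary_blur_pair(phantom_spec(seed = 2))
res <- fuse_pair(cb$a, cb$b, model)
print(res)

# compare against the naive per-pixel average
avg <- (cb$a + cb$b) / 2
print(quality_report(cb$a, cb$b, avg))
sqrt(mean((res$fused - cb$truth)^2))   # RMSE of the fusion
sqrt(mean((avg - cb$truth)^2))         # RMSE of the baseline
```

Output on this machine:

```
[1] 1
Fusion result: 256 x 256 image, 19 colocated low-pass matches
Fusion quality: SD = 25.03  En = 6.526 bits  MI = 5.213 bits  Q^AB/F = 0.7955
Fusion quality: SD = 21.97  En = 6.221 bits  MI = 3.632 bits  Q^AB/F = 0.5210
[1] 0.005239767
[1] 0.0245095
```

Reading the numbers: the network separates sharp from degraded patches
perfectly on held-out pairs (accuracy 1); the fused image reconstructs the
ground truth about 4–5× more accurately than pixel averaging, transfers
substantially more source information (MI 5.2 vs 3.6 bits) and preserves
far more edge structure (Q^AB/F 0.80 vs 0.52).

A command-line interface wrapping the same functions lives at
`inst/cli/sistfuse.R`:

```sh
Rscript inst/cli/sistfuse.R train-cnn --n-pairs 2000 --seed 1 -o model.rds
Rscript inst/cli/sistfuse.R fuse A.png B.png -o fused.png --model model.rds --json report.json
Rscript inst/cli/sistfuse.R evaluate fused.png A.png B.png
Rscript inst/cli/sistfuse.R make-fixtures --scenario complementary_blur --seed 1 -o fixtures/
```

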