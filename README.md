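# semreg — semantically guided two-step deformable registration

`semreg` estimates dense non-rigid deformations between pairs of 2D
greyscale images with **large initial misalignment** — inter-subject face
part alignment, end-diastolic vs end-systolic cardiac MRI frames — where
intensity-driven registration fails. It is aimed at researchers in medical
image analysis and computer vision who have segmentation labels for their
*training* images and want a registration model that needs **no labels at
inference**.

## Method

Training is weakly supervised and end-to-end:

* a compact **U-Net** (11 3×3 convolutions, ~186k parameters, shared
  weights for both images) turns each image into softmax class
  probabilities `f ∈ [0,1]^{L×H/2×W/2}` — semantic features — supervised by
  weighted cross-entropy with square-root inverse-frequency class weights
  `w`:

  `L_semantic = −(1/N) Σ_j w_{f̂(x_j)} · log f_{f̂(x_j)}(x_j)`

* two cascaded **registration networks** (~1.9M parameters total) read the
  concatenated features and each predict a coarse B-spline control grid of
  displacements; step 2 sees the moving features already warped by step 1's
  field (`V1 ∘ fm`). Control grids are densified to per-pixel fields by
  nearest-neighbour replication plus three unit-stride average-pooling
  passes — the recursive cardinal construction of cubic B-spline
  interpolation — and combined as `V(x) = V2(x) + V1(x + V2(x))`
  (or additively; both exposed).

* the **objective** combines alignment of the warped one-hot moving
  segmentation, semantic supervision, and a smoothness penalty:

  `L = λ_s·L_semantic + (1/L) Σ_l w_l·mean|S_f(l) − T(V, S_m(l))| + λ_r·mean‖V − V_smooth‖²`

  with defaults `λ_s = 1.0`, `λ_r = 0.001`, Adam (lr 0.001, β₁ = 0.97).

A diffeomorphic variant reads the network outputs as stationary velocity
fields and exponentiates them by scaling and squaring. Evaluation reports
per-structure Dice overlap, symmetric contour distance, and
Jacobian-determinant summaries (std; fraction of pixels with det ≤ 0,
i.e. folding). A synthetic-scene generator (cardiac-like rings, face-like
part layouts) with known ground-truth B-spline deformations makes the whole
pipeline testable without external data.

## Worked example

```r
library(semreg)

# a synthetic cardiac-like study: 64x64 images, 4 labels,
# ground-truth B-spline deformations up to 10 px
spec <- scene_spec(c(64, 64), scene_type = "cardiac", max_displacement = 10)
train_pairs <- lapply(1:48, function(s) generate_pair(spec, 100 + s))
test_pairs  <- lapply(1:5,  function(s) generate_pair(spec, 900 + s))

cfg <- train_config(epochs = 24L, batch_size = 4L, seed = 1L)
ck  <- train_registration(train_pairs, cfg)

reg   <- evaluate_manifest(test_pairs, ck)
unreg <- evaluate_manifest(test_pairs, zero_field = TRUE)
cat(sprintf("mean Dice    %.3f (registered) vs %.3f (unregistered)\n",
            reg$summary$mean_dice, unreg$summary$mean_dice))
cat(sprintf("Jacobian     std %.3f, negative fraction %.5f\n",
            reg$summary$mean_jacobian_std,
            reg$summary$mean_jacobian_negative_fraction))

# register one pair (inference needs no labels; they are used here only
# to score the result)
p   <- test_pairs[[1]]
res <- register_pair(p$fixed, p$moving, ck,
                     fixed_labels = p$fixed_labels,
                     moving_labels = p$moving_labels)
cat(sprintf("pair 1: mean Dice %.3f\n", res$report$mean_dice))
```

Output from this exact script (seeds included):

```
mean Dice    0.832 (registered) vs 0.619 (unregistered)
Jacobian     std 0.059, negative fraction 0.00000
pair 1: mean Dice 0.830
```

The registered Dice rises well above the unregistered baseline — the model
has recovered most of the synthetic deformation from images alone — while
the field stays smooth (small Jacobian std) and fold-free (no negative
determinants). `register_pair()` also returns the fields `v1`, `v2`, `v`
and the warped moving image; `res$report` holds per-structure Dice and
contour distances.

A command-line front end mirroring these functions is installed at
`inst/cli/semreg.R` (`synth`, `train`, `register`, `evaluate` subcommands).

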