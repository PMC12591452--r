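# frunet

Ultra-high-field (7T) brain MRI offers markedly better contrast and
resolution than standard 3T imaging, but 7T scanners are scarce and
expensive. `frunet` implements a patch-based deep-learning pipeline that
synthesizes 7T-like T1-weighted volumes from co-registered 3T inputs, and —
just as importantly — the evaluation framework needed to judge whether such
synthetic volumes are anatomically trustworthy: per-orientation image-quality
metrics and segmentation-consistency metrics computed from multi-class label
volumes. It is aimed at neuroimaging researchers studying cross-field-strength
image translation in small-data settings.

## The model

The synthesizer is a 3D multi-scale fusion residual U-Net (FR-U-Net): a
four-level encoder–decoder over 64³ patches (stride 32) with, per encoder
level, 3×3×3 convolutions + PReLU + layer normalization and 2×2×2 max
pooling (widths 32/64/128, bottleneck 256 at 8³), and, per decoder stage, a
stride-2 transposed convolution, concatenation with the encoder skip, a
residual block (two 3×3×3 convolutions with a projected identity skip) and a
multi-scale fusion block (parallel 1³/3³/5³ convolutions fused by a 1×1×1
reduction). A 1×1×1 convolution + sigmoid maps back to one channel.

Training minimizes a hybrid objective on paired patches,

    L_hybrid = MSE(y, ŷ) + λ · (1 − SSIM(y, ŷ)),      λ = 0.7,

optionally augmented with unpaired real 7T patches through a consistency
loss that pushes the network toward the identity on genuine 7T input,

    L_cons = ‖x₇T − f(x₇T)‖₁ + α · (1 − SSIM(x₇T, f(x₇T))),
    L_total = L_hybrid + λ_semi · L_cons,

drawn 1:1 with paired batches. Optimization is Adam with early stopping on a
held-out supervised validation split. Full volumes are synthesized by
running every overlapping patch through the network and mean-blending the
overlaps.

Anatomical fidelity is assessed per region from co-registered label
volumes: Dice overlap `2|A∩B|/(|A|+|B|)`, the symmetric 95th-percentile
Hausdorff boundary distance in mm, regional volumes in cm³ and as % of the
intracranial cavity, signed percent errors, and left/right asymmetry
indices `100·(R−L)/((L+R)/2)`.

The network and its gradients are implemented natively (an R
reverse-mode tape over RcppArmadillo im2col/GEMM convolution kernels), so
everything runs on a single CPU at reduced scale; seeded geometric phantom
generators provide paired 3T/7T-like volumes and label maps with known
ground truth for testing and demonstration.

## Worked example

```r
library(frunet)

# three paired phantom "subjects" plus two unpaired 7T volumes
ds   <- make_paired_dataset(3, phantom_config(seed = 11), n_unpaired = 2)
spec <- patch_spec(32, 16)                      # desk-scale patches
xp <- yp <- list()
for (s in ds$paired[1:2]) {                     # subject 3 stays held out
  xp <- c(xp, extract_patches(s$v3t, spec)$patches)
  yp <- c(yp, extract_patches(s$v7t, spec)$patches)
}

model <- build_model(model_config(base_channels = 4, patch_size = 32, seed = 7))
fit <- train_supervised(model, xp, yp,
                        train_config(learning_rate = 1e-3, batch_size = 2,
                                     max_epochs = 2, patience = 2,
                                     max_steps = 200, seed = 5))
fit$history
#>   epoch steps train_loss  val_loss
#> 1     0     0         NA 0.8993698
#> 2     1   162  0.3961043 0.2598640
#> 3     2   200  0.2481054 0.2299848

ho  <- ds$paired[[3]]
syn <- synthesize_volume(fit$model, ho$v3t, spec)
c(baseline = ssim(ho$v7t$data, ho$v3t$data),
  synthetic = ssim(ho$v7t$data, syn$data))
#>  baseline synthetic
#> 0.2963817 0.7724783
```

After 200 optimizer steps the validation hybrid loss has dropped by ~74%,
and on the fully held-out subject the synthesized volume is far closer to
the 7T target (SSIM 0.77) than the 3T input was (SSIM 0.30) — the network
has learned to undo the blur/contrast/noise degradation that separates the
phantom field strengths.

Label-volume evaluation works the same way from files or in memory:

```r
lp  <- make_label_phantom()
rv  <- region_volume(lp$labels, lp$regions, "Intracranial Cavity")
head(rv, 3)
#>         region    cm3  pct_icv
#> 1          CSF 49.024 38.70886
#> 2  Grey Matter 56.536 44.64026
#> 3 White Matter 19.944 15.74758
```

A command-line interface wrapping the same functions is installed at
`inst/cli/frunet.R` with subcommands `make-fixtures`, `extract-patches`,
`train`, `synthesize`, `eval-image`, and `eval-seg`; every run writes a JSON
manifest so it can be replayed exactly.

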