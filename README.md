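# grainray

Non-destructive estimation of paddy-rice grain quality traits from a single
2D X-ray radiograph.

Rice breeding programs score three physical grain traits at scale:
**chaffiness** (the count of empty or aborted grains), the **chalky rice
kernel percentage** (CRK%, the share of kernels with > 20% opaque,
chalk-like area) and the **head rice recovery percentage** (HRR%, the mass
fraction of unbroken polished kernels recovered after milling,
HRR% = 100 · W_pg / W_op). Conventional protocols require de-husking,
milling and several optical instruments — destructive, slow and
error-prone. A transmission radiograph of a gridded sample holder captures
the internal mass distribution of every grain at once, so all three traits
can be inferred from one image, per grain, without touching the sample.

`grainray` implements that inference pipeline for R, plus an analytic
phantom simulator so the whole chain is testable without scanner data:

1. **Normalization** — counts to attenuation line integrals,
   `I_corr = −ln(I / I₀)`, with `I₀` taken as the mode of the grey-value
   histogram (the holder leaves most of the detector uncovered).
2. **Segmentation** — dual watershed "blob analysis": marker watershed on
   the gradient magnitude separates grain matter from background, then a
   watershed on the negated Euclidean distance transform splits touching
   blobs; a morphological opening removes noise pixels.
3. **Features** — eight descriptors per segment: size `f1`, mean grey value
   `f2`, virtual weight `f3 = Σ I_corr`, grey-value SD `f4`, sphere radius
   `f5 = √(f1/π)`, average weight `f6 = f2·f5`, minimum-covering-circle
   radius `f7`, and sphere ratio `f8 = f5/f7`.
4. **Embedding** — per-feature z-transform `f′ = (f − µ)/σ` and a
   three-component PCA.
5. **Trait models** —
   * chaffiness: Mahalanobis distance from the non-chaffy cluster,
     `d(x) = √((x−µ)ᵀ Σ⁻¹ (x−µ))`, grain flagged chaffy when `d > θ`
     (θ = 17 in normalized PCA units);
   * CRK%: linear soft-margin SVM hyperplane in PC space of
     (f2, f3, f4, f6), applied to whole grains after a "virtual de-husking"
     feature-space shift `x + (µ_kernel − µ_grain)`;
   * HRR%: five classes (100/80/60/40/20%), one-vs-rest calibrated linear
     SVMs over (f1, f3, f4, f5, f7); each grain gets the class of maximal
     probability, with that probability reported as the reliability.

## Worked example

Simulate a 100-grain holder with 12% chaffy grains, train the chaffiness
model on phantom scenes, and predict:

```r
library(grainray)
report <- run_pipeline(list(
  phantom = list(n_grains = 100L, trait_mix = list(chaffy = 0.12),
                 seed = 11L, detector = c(660L, 2304L),
                 noise_sd_frac = 0.005),
  traits = "chaffiness", train_seed = 1L,
  out_dir = "demo_run"))
report$n_grains      # 100
report$chaffy_count  # 10
head(report$per_grain, 5)
#>   label chaffy mahalanobis
#> 1     1   TRUE  25.2293006
#> 2     2  FALSE   2.3655754
#> 3     3  FALSE   2.4878216
#> 4     4  FALSE   2.4442201
#> 5     5  FALSE   0.9810807
```

The truth table written next to the report has 12 chaffy grains; the model
recovers 10 of them at the fixed threshold θ = 17 (non-chaffy grains sit at
distances ~1–4, chaffy grains far outside the cluster, e.g. grain 1 at
25.2). `demo_run/` also holds the radiograph (ASCII PGM), the attenuation
map, label image, feature table, per-grain CSV and the JSON report.

The max-probability HRR rule on five class probabilities
(21%, 18%, 66%, 75%, 35%) for classes (100, 80, 60, 40, 20)%:

```r
predict_grain_hrr(c(21, 18, 66, 75, 35))
#>   class_value reliability
#> 1          40          75
```

## Command line

`grainray_cli()` exposes subcommands `simulate`, `normalize`, `segment`,
`features`, `fit-embedding`, `train`, `predict`, `evaluate`, `run-all`,
`make-fixtures`, e.g.

```sh
Rscript -e 'grainray::grainray_cli()' simulate --seed 3 --n-grains 100 --out scene.pgm
```

See `vignettes/grainray-methods.Rmd` for the model assumptions, phantom
design and numerical choices.
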