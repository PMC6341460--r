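# swarmseg

Tumor extraction from 2-D lung-CT slices by intensity clustering, with the
cluster centers found either by Lloyd iterations (k-means, k-median) or by
particle-swarm search (plain PSO, inertia-weighted PSO, and
guaranteed-convergence PSO). The package covers the whole pipeline a
segmentation study needs: speckle filtering, contrast enhancement,
segmentation, brightest-cluster tumor extraction, filter-quality indices
(SSI, SMPI), pixelwise confusion metrics, and a seeded synthetic lung
phantom generator with known ground truth so everything is testable without
any imaging download.

## The method

A CT slice is rescaled to intensities in [0, 1] and passed through four
stages: noise filter → contrast enhancement → k-class intensity clustering →
tumor mask extraction. The default configuration is adaptive median filter
(window 3, cap 7), CLAHE (8×8 tiles, clip 0.01), GCPSO with k = 3, and
brightest-cluster extraction with 30-pixel minimum component area.

The swarm segmenters optimize a k-vector of cluster centers
x ∈ [0, 1]^k. Per particle and dimension, with fresh uniform draws r₁, r₂:

    v ← w·v + c₁ r₁ (pbest − x) + c₂ r₂ (gbest − x)
    x ← x + v

(w = 1 for plain PSO; constant w = 0.7 or random w = 0.5 + U(0,1)/2 for the
inertia-weighted variant; velocities clamped to ±0.2, positions clipped to
the bounds). In GCPSO the particle holding the global best instead performs
a guarded local search around it,

    x_τ ← gbest + w·v_τ + ρ (1 − 2r),

with the search radius ρ doubling after more than sc = 15 consecutive
global-best improvements and halving after more than fc = 5 consecutive
failures. The swarm maximizes a cluster-validity fitness — occupancy-
weighted center separation over the worst within-cluster scatter,

    f(x) = Σᵢ (nᵢ/n) · interᵢ / maxⱼ intraⱼ,

where interᵢ is the mean distance from center i to the other centers and
intraⱼ the mean absolute member–center distance of cluster j. Five seeded
restarts are run and the best final global best wins. The methods vignette
(`vignettes/tumor-segmentation.Rmd`) derives and motivates every piece,
including why the fitness is weighted this way.

Segmentation quality is reported as sensitivity/specificity style
percentages (TPR, TNR, FPR, FNR) and their balanced accuracy
(TPR + TNR)/2; filter quality as SSI (coefficient-of-variation ratio,
< 1 = speckle suppressed) and SMPI (σ ratio penalized by mean shift).

## Worked example

```r
library(swarmseg)

ph <- make_phantom(phantom_spec(seed = 7))      # 128×128, speckle var 0.05
report <- run_pipeline(ph$image, ph$truth, pipeline_config(seed = 7))
report
#> <run_report> adaptive_median -> clahe -> gcpso (k = 3)
#>   SSI 0.9729  SMPI 0.9729  tumor pixels 465
#>   TPR 93.9086  TNR 98.2702  balanced accuracy 96.0894
report$model
#> <cluster_model> gcpso, k = 3
#>   centers:   0.037683, 0.43506, 0.6625
#>   objective:99.7061 (100 iterations)
```

Reading: the filter left the image's coefficient of variation at 0.97 of
the noisy input (mild smoothing — the adaptive median preserves non-impulse
pixels exactly); the swarm placed three centers on the background, lung,
and tumor intensity modes; the extracted 465-pixel mask catches 93.9% of
true tumor pixels (TPR) while keeping 98.3% of background correctly
excluded (TNR), a balanced accuracy of 96.1 against the phantom's exact
ground truth.

The same pipeline is scriptable from a shell:

```sh
Rscript exec/lungct phantom --seed 7 --out-image ph.png --out-mask truth.png
Rscript exec/lungct run --in ph.png --truth truth.png --seed 7 \
    --out-mask pred.png --csv metrics.csv --log run.json
```

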