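# aggropig

Automatic recognition of aggressive behavior among group-housed pigs from
**top-view depth video**. Aggression after mixing — head/body knocking and
chasing — is a persistent welfare and productivity problem in commercial
pens, and continuous human observation is impossible. A ceiling-mounted
depth camera sees each standing pig as a raised blob over a flat floor,
independent of lighting, and that is enough to measure who is interacting
with whom, how fast, and for how long.

The package implements the complete measurement and classification chain
for depth-frame sequences (16-bit PGM frames + JSON metadata sidecar), plus
a synthetic depth-video simulator so every stage is testable without farm
recordings:

1. **Segmentation** — height above floor `h(p) = d_floor − d(p)`,
   thresholded at a standing height; 8-connected components become pig
   regions with barycenters, tight bounding rectangles and posture flags
   (lying animals are excluded).
2. **Tracking** — greedy one-to-one matching of region barycenters by
   ascending Euclidean distance under a per-frame threshold; merged blobs
   of two pigs in full contact are carried through with a `merged` flag.
3. **Episode detection** — an interaction is a maximal run of close
   physical contact (barycenter distance ≤ 1.2 body lengths, or a shared
   merged blob) lasting **at least 1 s**.
4. **Features** — per episode, the 5-vector
   (v_min, v_max, v_mean, v_std, inter-pig distance), pooling both pigs'
   per-step speeds; v_std is the population standard deviation.
5. **Hierarchical SVM** — stage 1 (polynomial kernel `(x·y + 1)^3`,
   C = 4.5) separates *aggressive* from *normal*; stage 2 (RBF kernel
   `exp(−γ‖x−y‖²)`, C = 4.5, γ = 3.5) separates *knocking* from *chasing*.
   Evaluation is stratified 10-fold cross-validation with pooled
   out-of-fold confusion counts: ADR = TP/(TP+FN)·100,
   FPR = FP/(FP+TN)·100, FNR = FN/(TP+FN)·100, and per-class
   precision/recall with unweighted macro averages.

## Worked example

Simulate a small labelled corpus, push every episode through the full
pipeline (render → segment → track → detect episodes → extract features),
and cross-validate both classifier stages:

```r
library(aggropig)

cfg <- sim_config(counts = c(normal = 20, knocking = 10, chasing = 10), seed = 42)
features <- measure_corpus(cfg, source = "rendered")
head(features[, c("episode_id", "v_mean", "v_std", "v_max", "dist", "label")], 4)
#>   episode_id v_mean v_std v_max dist  label
#> 1          1   30.6 13.44  91.4 75.5 normal
#> 2          2   44.0  9.39  86.3 75.4 normal
#> 3          3   38.2 13.62  82.4 75.6 normal
#> 4          4   43.4 12.66 103.8 75.4 normal

metrics <- evaluate_corpus(features, k = 10, seed = 42)
metrics$stage1
#> Aggression detection (out-of-fold pooled counts)
#>   TP 20  FP 0  TN 20  FN 0
#>   ADR 100.0%  FPR 0.0%  FNR 0.0%
metrics$stage2
#> Aggression classification (out-of-fold pooled counts)
#>   knocking                 precision 100.0%  recall 100.0%
#>   chasing                  precision 100.0%  recall 100.0%
#>   macro average            precision 100.0%  recall 100.0%
```

All 40 simulated episodes are recovered with interval overlap 1.0, and the
three behavior classes are fully separable in the 5-feature space: speeds
in the tens of px/s for calm walking pairs, bursty spikes (high v_max,
v_std) for knocking, sustained high v_mean for chasing. The simulator's
class separations are deliberately generous — see the methods vignette
(`vignettes/aggression-recognition.Rmd`) for what such results do and do
not say about real pens.

A thin command-line front end covers the same pipeline from a shell:

```sh
Rscript inst/cli/aggropig.R simulate --out corpus --config cfg.yaml
Rscript inst/cli/aggropig.R process  --in corpus/ep_0001 --out proc
Rscript inst/cli/aggropig.R extract  --in corpus --out features.csv
Rscript inst/cli/aggropig.R train    --features features.csv --out model.rds
Rscript inst/cli/aggropig.R predict  --features features.csv --model model.rds --out pred.csv
Rscript inst/cli/aggropig.R evaluate --out eval --config cfg.yaml
```

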