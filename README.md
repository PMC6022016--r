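# fallvar

Per-frame human fall detection from surveillance video, for researchers and
engineers building camera-based health-monitoring systems. The package
implements the complete chain — person segmentation, temporal-variance
feature extraction, boosted gain-ratio decision-tree classification and a
cross-validation/ROC evaluation layer — together with a synthetic
fall-video simulator, so every stage is testable without downloading any
external video corpus.

## The method

A fall is a *rapid* change of body geometry; walking and sitting down
change the same geometry slowly. fallvar therefore classifies each frame by
how fast the silhouette is changing, not by what it currently looks like:

1. **Segmentation.** The person blob is extracted by background
   subtraction with a per-pixel relative threshold (a pixel is foreground
   when it differs from the background by more than 15% of that pixel's
   background value), followed by a distance-transform noise filter,
   erosion, hole filling, and connected-component filtering at a minimum
   person size.
2. **Features.** Six raw measurements per frame: bounding-box aspect ratio
   `ar`, fitted-ellipse person angle `pa` (90° upright → 0° lying) and axis
   ratio `er`, upper-half bounding-box area `sd`, boundary geometric centre
   `(gcx, gcy)`, and centroid motion magnitude `mv`. The classifier input
   is the population variance of each over the trailing window of k = 30
   frames (1 s at 30 fps),

   σ²ₓ(t) = (1/k) Σᵢ₌₁ᵏ (x(t−k+i) − μₓ)²,

   giving seven features: `var_ar, var_pa, var_mv, var_sd, var_gcx,
   var_gcy, var_er`.
3. **Classification.** Discrete AdaBoost over C4.5-style trees whose splits
   maximise the gain ratio `Gain(X,T) / SplitInfo(X,T)`. The two-class
   decision is `sign(Σₖ αₖ φₖ(x))` with `αₖ = ½ ln((1−εₖ)/εₖ)`; three-class
   problems use SAMME stage weights and an argmax vote. `base = "tree"`
   gives the boosted-J48 configuration, `base = "stump"` classic AdaBoost.
4. **Evaluation.** Stratified 10-fold cross-validation, sensitivity
   `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and ROC curves built from the
   ensemble margins.

See `vignettes/fall-detection-methods.Rmd` for the full model description,
parameter rationale, and limitations.

## Worked example

```r
library(fallvar)

# simulate one fall: 45 walking frames, a 10-frame fall, 20 still frames
sim <- simulate_sequence(scenario_spec("fall", seed = 1))
features <- extract_features(sim$sequence, sim$truth)
features[c(1, 18, 22, 30), c("var_ar", "var_pa", "var_mv", "var_gcy",
                             "frame_index", "label")]
```

```
   var_ar  var_pa var_mv var_gcy frame_index   label
1    0.00    0.00   0.00    0.00          30 no_fall
18   0.00   13.16   0.41    0.03          47    fall
22   0.06  206.05   1.07    5.17          51    fall
30   1.74 1301.63   1.99   91.03          59    fall
```

While the person walks (window ending at frame 30) every variance is near
zero; as the fall enters the window the angle variance `var_pa` explodes by
orders of magnitude, with the other features following — this is the
signature the trees split on.

```r
# end to end: 24 sequences, balanced fall/walk, 10-fold cross-validation
report <- run_pipeline(pipeline_config(
  data = list(n_sequences = 24L, class_mix = c(fall = 0.5, walk = 0.5),
              seed = 1L)))
report
```

```
10-fold cross-validation (tree, 10 round(s))
  accuracy:    1.0000
  sensitivity: 1.0000
  specificity: 1.0000
  ROC AUC:     1.0000
  confusion (true rows x predicted columns):

          fall no_fall
  fall     348       0
  no_fall    0     756
```

On clean simulated data the task is fully separable; the number to read is
not the 1.0 itself but that it is achieved by 10-fold cross-validation over
1104 windows with the full segmentation → features → boosting chain in the
loop.

A command-line interface over the same functions ships in
`inst/cli/fallvar.R` (verbs `simulate`, `segment`, `extract`, `train`,
`predict`, `evaluate`, `run`; every verb takes `--seed`).

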