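# ovisense

Behaviour and lameness classification from tri-axial accelerometers on
sheep.

Lameness is among the most common and costly health problems in extensive
sheep production, and it is still mostly found by a person watching animals
walk. Animal-borne accelerometers (ear tag, neck collar or foreleg mount,
sampling at 12 Hz) offer an automatic alternative: lame locomotion produces
a larger, asymmetrically distorted stride-frequency oscillation — the "head
bobbing" of a quadruped refusing weight on one limb — that separates it from
sound walking, grazing, standing and lying in feature space.

`ovisense` is a tested, reusable implementation of the epoch-based
classification pipeline used for this problem, for researchers in precision
livestock sensing and biologging:

1. **Segmentation** — annotated records are cut into mutually exclusive
   10 s epochs (120 samples at 12 Hz); windows touching more than one
   behaviour or a reserved label (`unknown`, `transition`) are excluded.
2. **Features** — fourteen movement metrics per epoch: per-axis means
   `Ax, Ay, Az` and extrema; movement variation
   `MV = (1/T) Σ (|Δx| + |Δy| + |Δz|)`; signal magnitude area
   `SMA = (1/T) (Σ|x| + Σ|y| + Σ|z|)`; average intensity
   `AI = (1/T) Σ √(x²+y²+z²)`; entropy
   `S = (1/T) Σ (1+Ts)ln(1+Ts)`, `Ts = x+y+z`; and energy
   `E = (1/T) Σ (x²+y²+z²)²`.
3. **Feature ranking** — a seeded random forest (500 trees, `mtry = 4`,
   compiled core) ranks the fourteen metrics by mean decrease in Gini
   impurity; the top three feed the classifier.
4. **Classification** — quadratic discriminant analysis: per class
   `δ_k(v) = -½ ln det Σ_k - ½ (v-μ_k)ᵀ Σ_k⁻¹ (v-μ_k) + ln π_k`, evaluated
   in the log domain through Cholesky factors, with trace-scaled diagonal
   shrinkage for near-degenerate classes.
5. **Validation** — leave-one-epoch-out cross-validation, confusion matrix
   (rows predicted, columns observed), and per-class sensitivity,
   specificity, accuracy, precision and prediction accuracy.

Two configurations are built in: **Analysis I** (all sound behaviours plus
lame walking and lame grazing) and **Analysis II** (lame grazing dropped —
it collapses into sound grazing). A seeded synthetic gait-signal generator
(gravity + two-harmonic oscillation + Gaussian noise, with per-animal
variation) emulates all the behaviour regimes so the whole pipeline runs and
is tested without any field recording. The package also bundles the
published reference confusion matrices for ear, collar and leg deployments
as plain-text fixtures.

## Worked example

Performance arithmetic on the bundled ear-deployment reference matrix
(Analysis II):

```r
library(ovisense)
cm <- ref_confusion("ear", "II")
cm
#> <confusion_matrix> rows = predicted, columns = observed
#>                sound_grazing sound_standing sound_walking lame_walking
#> sound_grazing            321             26             1            6
#> sound_standing            15            830             1            3
#> sound_walking              2              5           262            9
#> lame_walking               4              0             9           80

perf <- performance(cm)
perf[, c("class", "sensitivity_pct", "specificity_pct",
         "accuracy_pct", "precision_pct")]
#>           class sensitivity_pct specificity_pct accuracy_pct precision_pct
#>   sound_grazing              94              97           97            91
#>  sound_standing              96              97           97            98
#>   sound_walking              96              99           98            94
#>    lame_walking              82              99           98            86
```

The lame-walking sensitivity of 82% is the ear deployment's headline
lame-locomotion prediction accuracy: 80 of 98 observed lame-walking epochs
were predicted correctly. The corresponding numbers for the collar and leg
matrices are 35% and 87%.

End to end on synthetic data — simulate a balanced 5-animal ear study
(110 epochs per class), extract features, rank, classify, cross-validate:

```r
counts <- setNames(rep(110L, 6),
                   c("sound_grazing", "sound_standing", "sound_walking",
                     "sound_lying", "lame_walking", "lame_grazing"))
cfg <- study_config(animals = 5, epoch_counts = counts,
                    deployments = "ear", seed = 42)
fm <- build_feature_matrix(study_epochs(generate_study(cfg), "ear"))
rep <- run_analysis(fm, "II", ranking = ranking_config(seed = 42))
rep
#> <analysis_report> Analysis II, 5 classes, features: MinX, MV, MaxX
#> <confusion_matrix> rows = predicted, columns = observed
#>                sound_grazing sound_standing sound_walking sound_lying lame_walking
#> sound_grazing            110              0             0           0            0
#> sound_standing             0            110             0           0            0
#> sound_walking              0              0           110           0            0
#> sound_lying                0              0             0         110            0
#> lame_walking               0              0             0           0          110
#> ...
```

Under the generator's well-separated defaults the five Analysis-II classes
are recovered perfectly (all sensitivities 100%). Setting the lame-grazing
parameters equal to sound grazing instead reproduces the known Analysis-I
failure mode: roughly half of lame-grazing epochs are predicted as sound
grazing.

See `vignette("ovisense-methods")` for the model, the generator's
assumptions, and what synthetic results do and do not show.

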