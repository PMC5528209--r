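# foragescales

Do two animals that share a landscape forage at the same spatial scales?
`foragescales` answers that question from GPS telemetry alone. It measures
each individual's *foraging patches* — the spatial clusters of relocations
where search effort is concentrated — and compares the resulting patch-size
distributions between species (or any groups), without ever measuring the
food itself.

The pipeline chains four well-established movement-ecology methods:

1. **First-passage time (FPT).** For a circle of radius *r* centred on a
   fix, FPT is the time the (piecewise-linearly interpolated) path spends
   between entering and leaving that circle. The radius at which
   var(log FPT) peaks — averaged over individuals — is the population-level
   scale *r*<sub>pop</sub> at which movements are clustered
   (area-restricted search).
2. **Penalized-contrast segmentation (Lavielle).** Each individual's FPT
   series at *r*<sub>pop</sub> is partitioned into K homogeneous movement
   bouts by exact dynamic programming, minimising the within-segment sum of
   squares with a minimum bout length L<sub>min</sub>; K is chosen where
   the second derivative of the standardized contrast J̃(K) last exceeds
   S = 0.75.
3. **Movement-based kernel density estimation (biased random bridge).**
   The fixes of each bout yield a utilization distribution built from
   Gaussian kernels laid along interpolated movement steps, with bridge
   variance h²(p) = h²ₘᵢₙ + 4p(1−p)DT (largest mid-step); the 8-connected
   components of the 95% isopleth are the foraging patches, and their
   areas are the sampling units.
4. **Distribution comparison.** Log patch areas are compared between groups
   with the two-sample Kolmogorov–Smirnov test, screened for multimodality
   with Silverman's smoothed-bootstrap critical-bandwidth test over
   1–30 modes (support m = 1 − p against a 0.95 cut-off), and probed with
   a shift-sensitivity analysis (smallest mean log-area shift the KS test
   can detect; smallest shift at which a pooled original + shifted sample
   becomes detectably bimodal).

A two-mode correlated-random-walk simulator (`simulate_forager()`)
generates tracks with known patch geometry and behavioural states, so every
stage is testable against ground truth.

## Worked example

Two synthetic "species" foraging on the same landscape (500-m patches,
6-km spacing, ~2-day patch residences), tagged with different duty cycles —
2-h fixes with L<sub>min</sub> = 12 versus 4-h fixes with
L<sub>min</sub> = 6, both a 24-h minimum bout:

```r
library(foragescales)

tracks <- unlist(lapply(list(c("EG", 7200), c("RBT", 14400)), function(sp) {
  lapply(1:3, function(b)
    simulate_forager(forager_config(fix_interval = as.numeric(sp[2]),
                                    residence_fixes = round(48*3600/as.numeric(sp[2])),
                                    n_fixes = 500, seed = 100 + b),
                     id = sprintf("%s%02d", sp[1], b), species = sp[1])$track)
}), recursive = FALSE)

cfg <- framework_config(k_max = 10, B = 499)   # defaults: k_max 30, B 999
fs  <- forage_scales(tracks, cfg, seed = 1)
fs
#> <forage_scales> foraging-scale comparison
#>   EG: 3 track piece(s), r_pop = 340 m, 30 patches (median 0.170 km^2)
#>   RBT: 3 track piece(s), r_pop = 180 m, 50 patches (median 0.338 km^2)
#>   KS EG_vs_RBT: D = 0.2000, p = 0.4413
#>   modality EG: max support m = 0.994 at k = 3 (multimodal)
#>   modality RBT: max support m = 0.988 at k = 2 (multimodal)
```

Reading the output: both groups' var(log FPT) curves peak at a few hundred
metres — the same order as the 500-m patches they were simulated on — and
the KS test finds no difference between their log patch-area distributions
(D = 0.20, p = 0.44), exactly what should happen for two species foraging
at identical scales. (With only ~30–50 patches the high-k modality scan is
noisy; see the vignette for why small samples inflate multimodality
support.) `summary(fs)` tabulates per-track deployment statistics,
`plot(fs)` draws the scale-diagnostic curves and log-area densities, and
`write_report(fs, dir)` writes all artifacts (CSV/JSON, deterministic for
a given seed) to a directory.

Individual stages are exported on their own: `load_tracks()`,
`split_on_gaps()`, `project_planar()`, `compute_fpt()`, `var_log_fpt()`,
`population_peak()`, `optimal_segmentation()`, `choose_Kopt()`,
`segment_path()`, `build_ud()`, `extract_patches()`, `ks_compare()`,
`silverman_test()`, `modality_scan()`, `ks_shift_threshold()`,
`pooled_bimodality_threshold()`. A thin command-line front end with
`simulate`, `summarize`, `fpt`, `run`, `compare`, `modality` and
`sensitivity` subcommands is installed at `inst/cli/foragescales.R`.

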