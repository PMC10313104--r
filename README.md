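# myoatlas

Standardized, pixel-wise analysis of myocardial injury from segmented
delayed-enhancement cardiac MRI.

Clinical assessment of infarct and microvascular obstruction (MVO) after
acute myocardial infarction is usually reduced to a few global numbers —
lesion size, transmurality, endocardial surface area — which discard the
spatial structure of the lesion. myoatlas implements a statistical-atlas
pipeline that compares lesion *patterns* between cohort subgroups at every
myocardial location. It is aimed at cardiac-imaging researchers analyzing
segmented short-axis studies (endocardium, epicardium, infarct, early/late
MVO contours plus LV-RV junction and apex/mitral annotations), for example
across the arms of a reperfusion trial.

## The method

1. **Coordinates.** Each subject's myocardium is parameterized per pixel by
   normalized coordinates: radial `r = d_endo/(d_endo + d_epi)` ∈ [0,1]
   (endocardium → epicardium), circumferential `c` ∈ [0,1) (anticlockwise
   polar angle about the cavity center, zeroed at the LV-RV junction), and
   long-axis `z = (k − apex)/(base − apex)` (apex → base), estimated on
   4× oversampled grids, with LV-outflow-tract exclusion.
2. **Standardization.** Lesion channels are transported onto a common
   semi-ellipsoid reference (maximal endo/epi radii 30/50 px, 21 slices of
   80×80 px) by piecewise-linear interpolation in (r, c, z) space, with no
   extrapolation beyond the acquired slices. Binary masks become soft
   values in [0,1].
3. **Per-location statistics.** On a 24×21×20 (circumferential × slice ×
   radial) lattice: group-average patterns, location (radial max),
   transmurality (radial mean), variability, and per-location two-sample
   Hotelling T² p-values between treatment arms (feature vector = the
   radial profile; pseudo-inverse regularization;
   `F = (n−q−1)/((n−2)q)·T²` on (q, n−q−1) df), summarized as Bull's eye
   maps (21 rings × 24 segments) and the fraction of locations with
   p < 0.05.
4. **Global descriptors.** Infarct/early-MVO/late-MVO area (% myocardium),
   transmurality (% over infarcted columns only), endocardial surface area
   (%), computed identically before and after standardization, compared
   between arms with Mann-Whitney / Fisher tests.
5. **Population embedding.** Patterns are circumferentially realigned to
   the LAD territory's average infarct center and embedded in 2D with
   t-SNE (perplexity 10, PCA initialization), colored by clinical
   covariates.

Trial data of this kind are not publicly redistributable, so the package
includes a synthetic cohort generator with known ground truth (anatomies of
~17±2 slices, territory-specific wedge lesions with nested MVO cores,
configurable arm effects) that drives all tests.

## Worked example

Generate a two-arm synthetic cohort with a known regional treatment effect
(+0.3 transmural depth for the delayed arm over inferior/inferoseptal
segments), run the full pipeline, and inspect the per-location comparison:

```r
library(myoatlas)

spec <- cohort_spec(
  n_arms = c(immediate = 20, delayed = 20),
  territory_mix = c(RCA = 1),
  effects = list(arm = "delayed", depth_delta = 0.3,
                 c_range = c(0.625, 0.917), z_range = c(0.2, 0.8)),
  seed = 42)
cohort <- generate_cohort(spec)

res <- run_pipeline(cohort, run_config(oversample = 2, seed = 42),
                    out_dir = "demo_run")

res$pmaps$RCA
#> <myo_pmap> 24x21 locations, 504 tested, 14.5% with p < 0.05

glance(res$pmaps$RCA)
#> # A tibble: 1 × 5
#>   n_locations n_tested significant_pct    min_p mode
#>         <int>    <int>           <dbl>    <dbl> <chr>
#> 1         504      504            14.5 3.73e-27 profile

dplyr::filter(res$descriptor_table, descriptor == "transmurality_pct")
#>       geometry territory          delayed        immediate      p_value
#> 1       native       RCA 60.8 (58.1-65.9) 42.0 (36.7-48.0) 1.234635e-07
#> 2 standardized       RCA 61.3 (56.9-65.1) 39.1 (33.7-46.7) 1.234635e-07
```

14.5% of myocardial locations differ at p < 0.05, concentrated in the
injected segments (the Bull's eye CSV/plots in `demo_run/` show where),
and the global transmurality comparison recovers the injected arm
difference — median 60.8% (delayed) vs 42.0% (immediate) in native
geometry, with consistent values after standardization. Per-subject
descriptors are in `res$globals`; `autoplot()` renders Bull's eyes and
embeddings; `tidy()`/`glance()` convert results to tibbles.

A thin command-line front end over the same functions is installed at
`inst/cli/myoatlas.R` (subcommands `simulate`, `run`, `globals`,
`reproducibility`).

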