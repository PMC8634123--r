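# saltatr

Quantitative analysis of saltatory cell migration from 2D time-lapse
tracks.

Migrating neurons move in a stop-and-go pattern: bouts of locomotion
separated by pauses. Given tracks — tables of `(track_id, frame, x, y)`
positions in micrometres at a known frame interval (20 min by default) —
`saltatr` turns each track into a 48-descriptor feature vector, separates
pauses from locomotion, summarises population dynamics, groups cells into
migration modes, and screens treatment effects. It is aimed at
live-imaging screens of neuronal migration (e.g. organoid slice cultures),
but applies to any 2D centroid tracking data with run-and-pause structure.

The core pieces:

* **48 per-track descriptors** covering speed, shape, pausing and
  direction: path length, net displacement, pairwise-diameter statistics,
  instantaneous-speed statistics, turning-angle statistics and threshold
  counts, the time-averaged velocity vector, the gyration tensor
  (radius $\sqrt{\lambda_1+\lambda_2}$, axes $2\sqrt{\lambda_i}$,
  asphericity $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$), confinement
  ratio (net/path), mean straight-line speed, dwell/moving partition
  statistics, and Ramer–Douglas–Peucker simplification statistics at
  ε = 0.5 and 3 µm.
* **Dwell/moving partitioning** by DBSCAN on points embedded as
  $(x, y, 1.1\cdot\mathrm{frame})$ with ε = 3.3 µm: dense spatiotemporal
  neighbourhoods are pause episodes ("dwell states"), the rest are
  "moving tracklets".
* **Filtering**: tracks shorter than 12 frames (240 min) are excluded, and
  tracks failing the non-moving thresholds (track diameter ≥ 15 µm and
  gyration major axis ≥ 5 µm) are removed before clustering.
* **Population curves**: time-averaged mean-squared displacement
  $\mathrm{MSD}(\tau)=\langle |r(t+\tau)-r(t)|^2\rangle_t$ and per-track
  normalised velocity autocorrelation
  $\mathrm{VAC}(\tau)=\langle v(t)\!\cdot\!v(t+\tau)\rangle_t/\langle|v|^2\rangle_t$,
  averaged per cluster; log–log MSD exponent ≈ 2 ballistic, ≈ 1 diffusive.
* **Migration modes**: z-score on the control group, PCA to ≥ 95%
  explained variance, K-means (k = 10 default, 20 restarts); all tracks
  assigned to the nearest control-defined centre; clusters speed-ordered
  and grouped into Directed / Exploratory / Confined; composition fold
  changes vs control.
* **Screening statistics**: per descriptor, Kruskal–Wallis across groups,
  then two-sided Mann–Whitney U vs control with Bonferroni correction;
  effects as log2 median ratios with a significance mask.
* **A simulator** (`simulate_track()`, `simulate_cohort()`) of ballistic,
  random-walk, persistent-walk, saltatory, confined and stationary motion
  with per-track ground truth, so the whole pipeline is testable.

## Worked example

Simulate a screen where the treatment shifts cells from the Directed into
the Confined mode, then run the standard pipeline:

```r
library(saltatr)

spec <- tibble::tibble(
  group  = rep(c("control", "drug"), each = 3),
  model  = rep(c("ballistic", "saltatory", "confined"), 2),
  n      = c(40, 40, 40, 20, 40, 60),
  n_frames = rep(c(60, 72, 66), 2),
  speed = 0.5, step_sd = 2, tether_sd = 8, jitter_sd = 0.3)
cohort <- simulate_cohort(spec, seed = 1)

res <- run_pipeline(cohort, pipeline_config(k = 3, seed = 1))
res
#> Migration screen
#>   tracks: 240 in, 240 after length filter, 239 moving
#>   model: k = 3, 6 PCs (95.6% variance)
#>   screening: 39 significant (feature, group) effects

res$composition
#> # A tibble: 6 × 5
#>   group   mode            n  prop fold_change
#>   <chr>   <chr>       <int> <dbl>       <dbl>
#> 1 control Confined       39 0.328       1
#> 2 control Directed       40 0.336       1
#> 3 control Exploratory    40 0.336       1
#> 4 drug    Confined       60 0.5         1.53
#> 5 drug    Directed       20 0.167       0.496
#> 6 drug    Exploratory    40 0.333       0.992
```

One stationary-looking confined track was removed by the non-moving
filter (240 → 239). The composition table reads: half of the drug-treated
cells migrate in the Confined mode versus a third of controls (fold change
1.53), at the expense of the Directed mode (0.496). The strongest
per-descriptor effects are exactly the planted ones — shorter paths,
slower speed, smaller net displacement:

```r
dplyr::filter(res$stats, significant) |> dplyr::arrange(p_bonferroni) |> head(5)
#>   feature                       group effect_log2 p_bonferroni stars
#> 1 moving_tracklet_duration_mean drug       -0.478     0.000277 ***
#> 2 total_path_length             drug       -0.856     0.000280 ***
#> 3 speed_mean                    drug       -0.798     0.000308 ***
#> 4 moving_tracklet_length_mean   drug       -1.36      0.000404 ***
#> 5 net_displacement              drug       -2.32      0.000452 ***
```

Plots: `plot_tracks()`, `autoplot(res$msd)`, `autoplot(res$vac)`,
`plot_mode_composition(res$composition)`, `plot_effect_heatmap(res$stats)`.

Real data come in through `read_tracks()` (generic CSV with a column map)
or `read_imaris_tracks()` (Imaris "Position" statistics CSV export). A
thin command-line wrapper over the same functions is in
`inst/cli/saltatr` (subcommands `simulate`, `features`, `pipeline`).

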