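---
title: "Quantifying saltatory cell migration from 2D tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying saltatory cell migration from 2D tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltatr)
library(dplyr)
```

## The problem

Migrating neurons — cortical interneurons in particular — do not glide
smoothly. They alternate bouts of nucleokinesis-driven locomotion with
pauses, a pattern called saltatory migration. Time-lapse imaging reduces
each cell to an ordered sequence of 2D centroid positions, typically one
frame every 20 minutes over one to three days. Classical single summary
statistics (mean speed, straightness) blur together cells that pause a lot
with cells that move slowly, and cells that wander with cells that commute.
`saltatr` addresses this by describing every track with a 48-dimensional
descriptor vector that covers four complementary views of the same path —
speed, shape, pausing and direction — and then letting the data define a
small number of migration modes.

A track table is just a tibble with `track_id`, `frame`, `x`, `y` (µm) and
an optional `group` label; time in minutes is `frame * frame_interval`.
Everything downstream consumes and returns data frames, so the analysis
chains with the pipe.

## The descriptor set

The registry (`feature_registry()`) fixes 48 descriptors, organised by
feature class:

* **Whole-track geometry** — total path length, duration, net displacement,
  the max/mean/median of all pairwise point distances (the max is the track
  diameter), the confinement ratio (net/path, 1 for straight monotone
  motion), and mean straight-line speed (net/duration).
* **Speed** — mean, median, population SD, min, max of instantaneous speed,
  where each step's speed uses the actual time difference between retained
  points, so frame gaps widen the time base instead of being interpolated.
* **Direction** — the unsigned turning angle (0–180°) at each interior
  point (zero-length steps skipped), summarised as mean/median/SD/max plus
  the proportions exceeding 20°, 45° and 90°; and the time-averaged
  velocity vector (magnitude and angle), which for any track equals net
  displacement over duration.
* **Shape** — the gyration tensor, i.e. the population second-moment tensor
  of the positions about their centroid. With eigenvalues
  $\lambda_1 \ge \lambda_2$ we report the radius of gyration
  $\sqrt{\lambda_1+\lambda_2}$, the full axis lengths $2\sqrt{\lambda_i}$,
  the asphericity $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$, and the
  principal-axis orientation. The $2\sqrt{\lambda}$ convention is a choice
  (the bare $\sqrt{\lambda}$ is equally defensible); the downstream
  non-moving threshold is configurable precisely so that users with a
  different convention can compensate.
* **Pausing** — eleven statistics of the dwell/moving partition described
  below.
* **Simplified-path structure** — five statistics of the
  Ramer–Douglas–Peucker (RDP) reduction of the path at ε = 0.5 µm and
  ε = 3 µm: node count, mean segment length and duration, mean turn angle
  at interior nodes, and the node/point compression ratio. The two scales
  probe small wiggles and major course changes separately.

Degenerate cases (a track with no nonzero step, no interior node, no
dwell state) are imputed as 0 under a documented rule per descriptor, never
`NA`, so the clustering input is always complete.

## Partitioning a track into dwell states and moving tracklets

The pausing descriptors need a per-frame segmentation. Each point is
embedded as $(x, y, t_\mathrm{scale} \cdot \mathrm{frame})$ and clustered
with DBSCAN (radius ε = 3.3 µm, minimum neighbourhood 4 points,
t_scale = 1.1 µm per frame). The intuition: during a pause, several
consecutive points sit within a small spatial neighbourhood, and the time
axis — converted to a spatial equivalent by t_scale — keeps points that
revisit a location at distant times from clustering together. Dense
neighbourhoods become dwell-state candidates; noise points are locomotion.

Three post-processing rules make the output biologically interpretable:
candidate clusters are split into temporally contiguous episodes (a dwell
state is a pause *episode*, not a place); single-point fragments are
returned to the moving pool; and a single moving point wedged between dwell
points is absorbed into the adjacent state. Moving tracklets are the
maximal remaining runs of at least two consecutive moving points. Every
point carries exactly one label, so dwell frames and moving frames always
sum to the track length.

Choices worth knowing: `min_pts = 4` means a pause must persist roughly
4 frames (80 min at the default sampling) to register — shorter pauses are
deliberately invisible, which is also why the simulator-based recovery
tests score detected dwell counts against planted episodes of at least
4 frames. Episode durations are point counts times the frame interval,
consistent with the point-count-based relative durations. With
t_scale = 1.1 and ε = 3.3, points more than 3 frames apart can never be
neighbours, which is what makes the dwell definition local in time.

## Filtering

Two stages precede feature analysis. Tracks with fewer than 12 recorded
frames (240 min at 20 min/frame) are removed: too short for stable
statistics. Then, after computing features, tracks are removed as
non-moving unless their track diameter reaches 15 µm **and** their
gyration-tensor major axis reaches 5 µm. Requiring both is the
conservative reading of a two-threshold rule; `combine = "either"` is
available for the permissive one. Both filters are idempotent and report
their bookkeeping (`filter_report()`), and the pipeline manifest carries
the counts at every stage so a screen's exclusions are auditable.

Smoothing (`smooth_tracks()`) is available but off by default in
`run_pipeline()`. It uses a centred moving average whose half-width
shrinks symmetrically at the ends, so endpoints are preserved and
collinear equidistant tracks are exact fixed points.

## Population curves

`msd_curve()` computes the time-averaged mean-squared displacement with
overlapping windows, `vac_curve()` the velocity autocorrelation normalised
per track by its mean squared step speed, so VAC(0) = 1 and a straight
run keeps VAC ≈ 1 while uncorrelated steps decay to 0. Per-track
normalisation (rather than a pooled ensemble normalisation) was chosen so
that fast and slow tracks contribute equally to a cluster's persistence
signature. Cluster curves are unweighted means across member tracks,
dropping lags supported by fewer than 3 tracks so one unusually long track
cannot dominate the tail; the default lag window is 24 h.
`fit_msd_exponent()` gives the log-log slope — near 2 for ballistic, near
1 for diffusive motion — as a compact scaling readout.

## Migration modes

Mode discovery is anchored on the control group: descriptors are z-scored
with the control means and SDs (population form, so duplicating rows is a
no-op), projected by PCA onto the smallest number of components reaching
95% cumulative explained variance, and clustered with K-means (Lloyd,
squared Euclidean, best of 20 restarts, k = 10 by default). All tracks —
control and treated — are then normalised and projected with those same
control parameters and assigned to the nearest centre. Anchoring means a
treatment changes *how many* cells do each behaviour, not what the
behaviours are; the unanchored variant (`reference_group = NULL`) exists
as a consistency check and agrees with the anchored one when treatment has
no effect.

Cluster ids are then reordered by descending mean reference speed and
grouped into three modes — Directed, Exploratory, Confined. The default
map sends the fastest ~40% of clusters to Directed and splits the rest;
this boundary is a manual modelling decision, exposed as an editable
`mode_map`, because no algorithmic criterion defines where "exploratory"
ends and "confined" begins. Composition shifts are reported as per-group
mode proportions and fold changes against control, without a hypothesis
test. `elbow_scan()` reports the inertia profile for choosing k but never
chooses it automatically. Zero-variance descriptors in the reference are
dropped before z-scoring. Ward clustering of the z-scored descriptor
profiles (`feature_dendrogram_groups()`, 9 groups) organises the 48
descriptors into correlated families for display.

## Screening statistics

For each descriptor, a Kruskal–Wallis test across all groups is followed
by two-sided Mann–Whitney U tests of each treatment against control, with
Bonferroni correction over the treatments compared for that feature (the
per-feature family; a global family is a stricter alternative users can
apply themselves). `wilcox.test()` supplies the U test: exact for small
untied samples, normal approximation with tie and continuity correction
otherwise (R switches at n = 50). The reported effect is
$\log_2(\mathrm{median}_\mathrm{treatment}/\mathrm{median}_\mathrm{control})$;
the median is the default centre because speed and pause distributions are
right-skewed, with the mean available by argument. Circular descriptors
(average velocity angle, gyration orientation) and non-positive centres
have no meaningful log-ratio and are masked as undefined rather than
given a number. Simulation places the empirical type-I error of both tests
at the nominal 5% level (the acceptance script recomputes this over 2,000
null replicates).

## The simulator

`simulate_track()` provides six centroid motion models: ballistic
(constant velocity plus localisation jitter), random walk (iid Gaussian
steps), persistent walk (AR(1) steps), saltatory (alternating ballistic
runs with a fresh heading and jitter-about-a-point dwells, episode lengths
geometric — the memoryless two-state caricature of run-and-pause
locomotion), confined (mean-reverting walk with a set stationary spatial
scale) and stationary (pure jitter). Defaults emulate the target regime:
20 min frames, 24 h tracks, locomotion of order 0.5 µm/min,
sub-micrometre jitter. One cohort seed deterministically spawns per-track
child seeds, so cohorts are reproducible and every track records its
ground truth (model, and per-frame run/dwell state for saltatory tracks).

What the simulator does *not* emulate: leading-process morphology,
directional bias from chemotactic gradients, cell–cell interactions,
segmentation/tracking errors other than isotropic jitter, and frame drops.
Passing the recovery tests therefore shows the pipeline identifies
cleanly separated kinematic classes and honest pause structure; it does
not certify performance on the messier class boundaries of real imaging
data, where mode composition is a continuum.

## Numerical choices and scale of validation

Population (1/n) variance is used in all SD-type descriptors and in
z-scoring. K-means runs Lloyd iterations to machine convergence
(`iter.max = 1000`) keeping the lowest-inertia restart; restarts that
collapse a cluster are discarded and redrawn. Nearest-centre ties go to
the lowest cluster id. RDP uses the perpendicular distance to the infinite
chord line with endpoints always retained. DBSCAN neighbourhoods use
closed balls (≤ ε) including the point itself.

The packaged validation uses sizes a desk machine handles comfortably:
500-track ensembles for MSD scaling and dwell recovery, a 300-track
three-mode cohort for end-to-end mode recovery (adjusted Rand index ≥ 0.8
required; in practice recovery is exact), and 2,000 replicates for test
calibration. A real screen of several thousand tracks runs through the
same code paths unchanged.

## A worked example

```{r example, eval = FALSE}
spec <- tibble::tibble(
  group = rep(c("control", "drug"), each = 3),
  model = rep(c("ballistic", "saltatory", "confined"), 2),
  n = c(40, 40, 40, 20, 40, 60),    # the drug shifts cells out of Directed
  n_frames = rep(c(60, 72, 66), 2),
  speed = 0.5, step_sd = 2, tether_sd = 8, jitter_sd = 0.3)
cohort <- simulate_cohort(spec, seed = 1)

res <- run_pipeline(cohort, pipeline_config(k = 3, seed = 1))
res$composition
plot_mode_composition(res$composition)
plot_effect_heatmap(res$stats)
autoplot(res$msd)
```

## Known limitations

Tracks are strictly 2D (projected); any z-information is discarded at
import. The dwell partition's sensitivity is bounded by `min_pts` frames;
the exact correspondence between descriptor names here and other
implementations of similar descriptor sets should be checked by unit and
definition, not by name. The Directed/Exploratory/Confined boundaries are
a display convention, not an inference. Bonferroni correction is the only
multiplicity scheme offered in the default screen.
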