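# cortexkymo

Quantifies clathrin-mediated endocytosis (CME) dynamics separately on
the **mother** and **daughter (bud)** cortex of budded yeast cells from
live-cell fluorescence movies — and ships a fully ground-truthed
synthetic-movie generator used to validate every stage of the pipeline.

## The science

CME events appear in cortical movies as diffraction-limited spots that
persist for tens of seconds. Two quantities summarize a tagged
protein's dynamics: the **lifetime** of each event and the
**initiation frequency** of new events. In budded cells these must be
measured per compartment, and raw counts are not comparable between a
large mother and a small bud.

The pipeline solves this with **circumferential kymographs**: each
compartment's cortex is traced as a closed sub-pixel contour (bud neck
excluded), the movie is sampled in a short band along the outward
normal at every contour position and frame, and the result is an
S × T image (cortex arclength × time) in which every endocytic event is
a near-vertical streak. Trace detection is then connected-component
analysis with circular row adjacency — a seam-straddling event is one
trace, and no trace can cross the excluded neck. Lifetime is the streak
extent, `(t_end − t_start + 1) × Δt`; traces touching the first or
last frame are flagged **censored** and excluded from lifetime moments
by default. Frequencies are normalized **per retained micrometer of
cortex per minute**, correcting for the difference in surface distance
sampled between compartments.

Whole-cell statistics complete the toolbox: cytoplasmic puncta
classification (LoG maxima inside the eroded cell interior),
daughter/mother cortical intensity ratios on maximum intensity
projections, Pearson colocalization over the cell mask, exact
Mann–Whitney comparisons, and two-stage (low/high) trace change-point
splitting.

Because raw reference movies for this kind of analysis are rarely
available, the package treats its **simulator** as first-class code:
budded-cell geometry, per-compartment Poisson initiation, configurable
lifetime distributions, two-channel timing offsets, PSF blur, Poisson +
read noise, and photobleaching — with full per-event ground truth.
Validation experiments (`lifetime_recovery_experiment()` and friends)
simulate, analyze, and score recovery end to end.

## Worked example

Simulate one budded cell with a 5-fold daughter/mother initiation-rate
asymmetry, then analyze the movie end to end using the simulation's
ground-truth mask as the (external) segmentation:

```r
library(cortexkymo)

cfg <- sim_config(rate_mother = 0.09, rate_daughter = 0.45,
                  lifetime_mean_s = 30, lifetime_cv = 0.2, seed = 1)
sim <- simulate_movie(cfg)
table(sim$events$compartment)
#>
#> daughter   mother
#>       11        3

res <- analyze_movie(sim$stacks, mask = sim$mask)
res$report[, c("compartment", "n_events", "n_censored",
               "mean_s", "cv_percent", "frequency_per_um_min")]
#>   compartment n_events n_censored   mean_s cv_percent frequency_per_um_min
#> 1      mother        3          1 32.50000   32.63570           0.09157509
#> 2    daughter       11          0 26.27273   53.31685           0.54767239
```

All 14 ground-truth events are recovered. The normalized frequencies
(0.548 vs 0.092 events/µm/min, ratio ≈ 6 against a configured 5) show
the asymmetry even though the bud's circumference is much smaller —
the per-micrometer normalization is doing the work. Lifetime moments
from a single 3-minute movie are necessarily noisy (3 mother events!),
and at this daughter density occasional trace merges inflate the CV;
the validation experiments therefore pool replicates in a sparser
regime and apply the physics-based single-patch filter
(`filter_traces()`), recovering mean 30 ± 2 s and CV 20 ± 5 points
(see `?lifetime_recovery_experiment`).

A command-line driver covering simulate / segment / kymo / trace /
puncta / coloc / run lives in `inst/scripts/cme-kymo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/cme-kymo.R", package="cortexkymo"))')" \
    simulate --out /tmp/demo --seed 1
```

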