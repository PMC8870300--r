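# flimtrack

Simulation and trajectory lifetime analysis for rapid fluorescence
lifetime imaging (rapid FLIM) of diffusing particles.

## The problem

Time-correlated single photon counting (TCSPC) FLIM measures, per pixel,
how long a fluorophore stays excited. Classic TCSPC electronics impose a
~50 ns dead time per detected photon, so count rates must be attenuated to
below ~10% of the laser repetition rate to avoid photon pileup skewing the
decay — which makes frames slow and fast intracellular transport
invisible. Rapid-FLIM hardware cuts the dead time to single nanoseconds,
sustains count rates near the repetition rate, and makes it possible to
*track* individual sub-resolution particles (e.g. nanoparticles being
taken up by live cells) while reading out their lifetime frame by frame.

The analysis this package implements asks, per trajectory: did the
particle's lifetime change by more than the frame-to-frame variation of
inert controls? Concretely:

1. **Control threshold.** For particles embedded in an inert gel, pool the
   absolute frame-to-frame lifetime differences |Δτ| over all tracks; the
   mean is the threshold *x* (the published control value is
   *x* = 0.39 ns).
2. **Smoothing.** Each biological track's lifetime series is smoothed with
   a centered 3-frame moving median, so a single-frame jump cannot inflate
   its range.
3. **Classification.** A track is *above threshold* iff
   max − min of its smoothed series > *x* — a lifetime range larger than
   the control variation, indicating a genuine change of molecular
   environment (e.g. crossing the extracellular or nuclear membrane).

Around that statistic the package provides every stage needed to validate
it end to end without external data: a pulse-by-pulse TCSPC photon
simulator with configurable detector dead time (classic ~50 ns vs rapid
~2 ns), fast-lifetime estimation with period-truncation correction,
first-harmonic phasor analysis (G = ∫I(t)cos ωt dt / ∫I(t)dt,
S = ∫I(t)sin ωt dt / ∫I(t)dt at ω = 2πf, with monoexponentials on the
universal semicircle at G = 1/(1+(ωτ)²), S = ωτG), band-pass spot
detection with sub-pixel Gaussian refinement, optimal frame-to-frame
linking under a maximum-jump gate, and a reproducible pipeline with
two-channel (intensity, lifetime) 32-bit float TIFF interchange.

## Worked example

Simulate a cell scene (12 particles confined in an elliptical cell, 5 of
them scripted to cross the nuclear envelope, where their lifetime steps
from 3.0 to 3.8 ns), render the FLIM movie photon by photon, track, and
classify:

```r
library(flimtrack)

cfg <- run_config("cell", seed = 42,
                  acquisition = acq_config(frame_shape = c(64L, 64L),
                                           frame_interval_s = 2.62),
                  scene = list(n_particles = 12L, n_crossers = 5L,
                               n_frames = 20L, nucleus_radii = 12))
res <- run_pipeline(cfg, "flimtrack_run")
res$classified
#> classified tracks (threshold 0.390 ns):
#>
#> above_threshold below_threshold
#>               5               7
```

All 12 particles are recovered as tracks; exactly the 5
boundary-crossing particles exceed the 0.39 ns control threshold, and the
run's `summary.json` reports their enrichment at the nuclear boundary
(odds ratio 10 for this seed) along with photon totals. The run directory
also contains the ground truth (CSV), the two-channel TIFF stack, phasor
cloud and track tables, and a manifest of MD5 checksums — rerunning with
the same seed reproduces every file byte for byte.

For control data, `run_config("agarose")` simulates freely diffusing
particles in a heterogeneous gel and the pipeline recomputes the
threshold from its own tracks via `delta_stats()`; `predict()` on that
fit classifies any track table. A thin command-line front end with
`simulate` / `flim` / `phasor` / `track` / `classify` / `run-all`
subcommands is installed at `inst/scripts/flimtrack.R`, and each stage
reads the previous stage's files so real two-channel TIFFs or externally
produced track CSVs can enter at any boundary.

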