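# mumri — muscle twitch dynamics and fatigue recovery from dynamic MRI

`mumri` is an R package for analysing stimulated dynamic muscle MRI of the
kind acquired with in-scanner peripheral nerve stimulation synchronised to
fast imaging. It targets two acquisitions:

* **PGSE latency series** (magnitude): a pulsed-gradient spin-echo frame is
  acquired at each of a ladder of stimulus-to-readout latencies (by default
  −45 … +400 ms in 5 ms steps, 90 frames). Where muscle fibres move during
  the motion-encoding gradients the signal drops, so each voxel's
  signal-vs-latency trace shows a characteristic **biphasic dip**: one
  minimum during contraction, a return towards baseline at peak tension,
  and a second minimum during relaxation.
* **Cyclic phase-contrast series** (velocity): after fatiguing exercise,
  the latency of peak twitch velocity is sampled cyclically at five
  offsets (−10 … +10 ms), and the per-cycle peak of the mean in-muscle
  speed traces the recovery of the twitch over ~20 minutes.

## What it computes

For each in-mask voxel of a registered PGSE latency series, the trace is
smoothed (moving average), resampled to a 0.5 ms grid, and four landmarks
are detected:

* `T_start` — first time the signal falls below (baseline mean − 3·SD);
* `T_min1`, `T_min2` — the first two prominent signal minima;
* `T_middle` — the point between them closest to the baseline level.

From these, the twitch timing metrics

```
T_rise       = T_min1  − T_start
T_contract   = T_middle − T_start
T_half-relax = T_min2  − T_min1        (all in ms)
```

are assembled into parametric maps, 50-bin histograms with a Gaussian
kernel density, and four-class thresholded category maps (contraction-time
bands at 100/150/200 ms, or four equal spans of the observed range).

Post-fatigue recovery of the per-cycle peak velocity y against recovery
time x is modelled with a modified Gompertz curve

```
y(x) = a · exp(−b · exp(−c · x)) − d
```

(`a` asymptote, `b` translation, `c` growth-rate scale, `d` offset), fitted
by variable-projection nonlinear least squares, from which the
time-to-half-maximum is closed-form:

```
T_half-max = −(1/c) · ln( ln(2a / (a + d)) / b )
```

Companion utilities fit the mono-exponential phosphocreatine recovery
(`kPCr`), select the stimulation current from a setup ramp (67%
signal-reduction rule), compute test-retest repeatability (mean absolute
percentage difference), and run paired/unpaired Student's t-tests.

Because no public scanner data accompany the method, the package includes
a first-class forward-model phantom (`simulate_pgse_latency_series`,
`simulate_pc_recovery_series`, `simulate_current_ramp`) built on a
gamma-shaped twitch tension model with closed-form landmark times — every
synthetic voxel carries exact ground truth, which is what the test suite
checks the detectors against.

## Worked example

```r
library(mumri)

# simulate a 64x64 leg phantom with regional twitch speeds and 2% noise
cfg <- phantom_config(grid_size = c(64, 64), rng_seed = 1)
sim <- simulate_pgse_latency_series(cfg)

reg  <- register_series(sim$series)         # align frames to frame 1
maps <- map_metrics(reg$series, sim$mask)   # per-voxel landmark -> metric maps
print(maps)
#> Metric map 't_rise': 1303 valid voxels, mean 43.0 ms (SD 7.1)
#> Metric map 't_contract': 1303 valid voxels, mean 120.3 ms (SD 18.3)
#> Metric map 't_half_relax': 1303 valid voxels, mean 154.0 ms (SD 25.6)
#> Excluded: 0.1% of in-mask voxels

# fatigue recovery: cyclic PC series -> per-cycle peaks -> Gompertz fit
pc    <- simulate_pc_recovery_series(noise_sd = 0.25, rng_seed = 1)
curve <- extract_cycle_peaks(pc$series, pc$mask)
fit   <- fit_gompertz(curve)
print(fit)
#> Gompertz fit: a = 4.93 cm/s, b = 3.13, c = 0.0101 /s, d = -0.0706 cm/s
#>   T_half-max = 146.7 s, adjusted R^2 = 1.000 (n = 120)
```

The map means sit on the healthy-control scale (rise ≈ 40 ms, contraction
≈ 115 ms); the fitted `T_half-max` of 146.7 s recovers the generator's
true value of 146.5 s from 120 noisy cycle peaks. The superficial band of
the phantom contracts faster than the deep/peri-aponeurosis bands, which
the category map renders as the familiar light-to-dark banding.

## Command line

```sh
mumri simulate pgse --seed 1 --out sim/
mumri pgse-twitch run --series sim/pgse_series.nii \
      --latencies sim/pgse_series.csv --mask sim/mask.nii --out out/
mumri pc-recovery run --series pc.nii --frames pc.csv --mask m.nii --out out/
mumri preprocess select-current --series ramp.nii --frames ramp.csv \
      --mask m.nii --fraction 0.67
```

(`inst/cli/mumri` is a thin Rscript launcher; any `Rscript -e
'mumri::mumri_cli()' --args ...` invocation is equivalent.) Images travel
as single-file NIfTI-1 volumes (x, y, frame) with a CSV frame sidecar;
results are NIfTI maps, CSV tables, and JSON fit records under a run
manifest.

## Further reading

`vignettes/mumri-methods.Rmd` describes the forward model, the detection
and fitting algorithms, every tunable parameter with its default and
rationale, and the known limitations of phantom-based validation.
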