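---
title: "Methods: twitch-dynamics mapping and fatigue-recovery modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twitch-dynamics mapping and fatigue-recovery modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mumri)
```

## The measurement problem

Electrically stimulated dynamic muscle MRI probes the twitch — the
transient contraction/relaxation response of muscle to a single nerve
stimulus — at single-voxel resolution. Two sequences are involved. A
motion-sensitised magnitude sequence (pulsed-gradient spin echo, PGSE)
loses signal wherever fibres move during its encoding gradients; stepping
the stimulus-to-readout latency through a ladder of values turns each
voxel into a signal-vs-latency trace with a biphasic dip: a first minimum
while fibres accelerate into contraction, a return towards baseline at
peak tension (fibres momentarily stationary), and a second minimum during
relaxation. A phase-contrast (PC) sequence encodes tissue velocity into
phase (`v = phase/pi * VENC`) and is used post-exercise to track how the
peak twitch velocity recovers from fatigue.

`mumri` implements the analysis side of both paradigms plus a
forward-model phantom that supplies exact ground truth, since no public
scanner data exist for this class of acquisition.

## The phantom forward model

### Twitch kinetics

Tension follows a gamma-shaped impulse response

$$F(t) = A\,u^{k}e^{-u},\qquad u = (t - t_0)/\tau,\ t > t_0,$$

with onset delay $t_0$ (ms), shape $k \ge 2$, and timescale $\tau$ (ms).
Fibre velocity is $v = dF/dt$. This family was chosen because it is the
simplest unimodal tension model whose *speed* $|v|$ has two interior
maxima — exactly the biphasic structure the detector must find — and
because every landmark is closed-form:

* speed maxima at $t_0 + \tau(k \mp \sqrt{k})$ (the two signal minima),
* tension peak at $t_0 + k\tau$ (velocity zero; signal back at baseline).

The constraint $k \ge 2$ guarantees both interior speed maxima exist.

### Signal model

The PGSE magnitude signal is modelled as
$S(\ell) = S_0 \exp(-\beta\,|v(\ell)|)$ at latency $\ell$, plus noise;
frames whose stimulus falls after readout ($\ell < 0$) are pure baseline.
The real physics of motion-encoded signal loss is not published for this
sequence family, so this mono-exponential attenuation is a stand-in:
**absolute dip depths are not comparable to scanner data**, only the
timing structure is. The tension amplitude is calibrated per region
(`calibrate_twitch_amplitude`) so the first dip bottoms out near 45% of
baseline (attenuation exponent 0.8), matching the deep stimulated dips
seen in practice — an uncalibrated unit amplitude would make dips
shallower than the noise floor and test nothing.

### Stated-world defaults

| parameter | default | why |
|---|---|---|
| grid | 64 × 64 px, 1.5 mm | in-plane matrix/resolution of the protocol |
| latency axis | −45 … +400 ms, 5 ms | the printed gating; yields 90 frames |
| regions | 3 concentric elliptical bands | superficial fast, deep slower, peri-aponeurosis slowest |
| $k$ | 2.3 | sets rise/contraction ratio near the control value (≈ 0.34) |
| $\tau$ | 45 / 55 / 70 ms | contraction times ≈ 104/127/161 ms; muscle mean ≈ 118 ms, the control scale |
| $t_0$ | 10 ms | nerve conduction + electromechanical delay |
| noise | Gaussian, SD 2% of $S_0$ | typical magnitude-image SNR; Rician optional |
| PC kernel | Gaussian, 30 ms FWHM | a unimodal velocity twitch profile of realistic width |
| Gompertz truth | $a=5$ cm/s, $b=3$, $c=0.01$ s⁻¹, $d=0$ | plateau below VENC = 6 cm/s; start $ae^{-b}\approx0.25$ cm/s ("near zero"); half-max ≈ 147 s, the control scale |
| PC sampling | 600 frames, 2 s apart | 1200 s recovery window, 120 cycle peaks |

The offset was fixed at $d = 0$ (not a positive value) because the
extracted quantity is a speed: with $d > 0$ the model curve is negative
immediately post-exercise, which is unphysical and breaks the identity
that the noiseless cyclic maximum equals the curve value at the central
offset. The model retains $d$ as a free fit parameter.

These defaults are the package's stated world; they were chosen once from
the printed protocol and control-scale values and are not adjusted to test
outcomes. What a green phantom test establishes is that the estimators
recover the truth *of this model* — it does not establish robustness to
unmodelled scanner physics (fat suppression, through-plane motion,
partial-volume mixtures, non-Gaussian residuals of real registration).

## Landmark detection

Per voxel, the trace is smoothed with a centred moving average (default
window 3 frames; shrinking windows at the edges so no samples are
fabricated) and linearly resampled to a 0.5 ms grid spanning the native
latency range exactly.

* **Onset** `T_start`: first grid time (at non-negative latency) where the
  signal is below baseline mean − 3·SD, the baseline being all
  negative-latency samples. The printed rule ("three times less than the
  standard deviation") is ambiguous; 3σ below baseline is the standard
  onset convention and the reading adopted here.
* **Minima** `T_min1`, `T_min2`: the first two local minima after onset
  whose prominence is ≥ 3·baseline SD. If exactly one is found, a
  global-minimum fallback searches a 300 ms post-onset window.
* **Baseline return** `T_middle`: the sample strictly between the minima
  minimising |signal − baseline mean|, ties to the earlier time.
* **Sub-sample refinement**: each extremum is refined by a local
  least-squares *cubic* (stationary point of matching curvature). A cubic
  rather than a parabola because the dips are skewed: a parabola's vertex
  is biased on wide windows. The window is ±15 ms for the sharp first
  minimum and the baseline-return point, and widens to ±0.4× the
  inter-minima spacing for the second minimum, which is broad and shallow
  and needs more noise averaging. At 2% noise this keeps the median
  landmark error under 5 ms; noiselessly all landmarks are recovered to
  well under half the native 5 ms step.

Voxels violating `T_start < T_min1 < T_middle < T_min2`, or failing
onset/minima detection, are marked invalid with a reason
(`no_onset`, `lt_two_minima`, `order_violation`) and excluded from means,
histograms and category maps; the excluded fraction is always reported.
A centred moving average advances the apparent onset by roughly
(window − 1)/2 native steps, so oracle checks against noiseless truth run
with `window = 1`.

## Maps, histograms, categories

`map_metrics` applies the chain to every in-mask voxel and reports
muscle mean ± SD over valid voxels only (invalid voxels carry `NA`, never
zero). Histograms use 50 equal-width bins over the valid range (pooled
range when pooling across subjects; per-subject range otherwise — both
exposed) with a Gaussian kernel density at Silverman's bandwidth.
Category maps implement both threshold conventions: the fixed
contraction-time edges (min, 100], (100, 150], (150, 200], (200, max] ms,
and four equal spans of the observed range; intervals are half-open and
right-closed, and empty classes are permitted (with a warning) when edges
fall outside the data.

## Registration

The default engine estimates a per-frame translation by FFT
cross-correlation with parabolic sub-pixel refinement, then resamples
bilinearly. Classical phase correlation (full spectral whitening) was
evaluated and rejected: these images concentrate energy at low
frequencies, and whitening gives numerically-empty high-frequency bins an
equal vote, which in measurements degraded shift recovery from ~0.15 px
to several pixels. Frames whose estimated displacement exceeds a cap
(default 10 px) are flagged and left untouched for downstream exclusion.
The interface is pluggable (`method` argument) should a nonrigid engine be
added; published analyses used an unspecified nonrigid registration, so no
attempt is made to reproduce a specific one.

## Recovery-curve fitting

Per cycle of five latency offsets, the sample is the maximum over the
cycle of the mean in-mask speed (median selectable), timestamped at the
cycle midpoint; incomplete trailing cycles are dropped. The modified
Gompertz model $y = a\exp(-b\exp(-cx)) - d$ is linear in $(a, d)$ for
fixed $(b, c)$, so the fit profiles the residual sum of squares over
$(\log b, \log c)$ (Nelder–Mead then BFGS polish, deterministic start
from amplitude/time-range heuristics plus five seeded jittered restarts)
while solving $(a, d)$ exactly by linear least squares at every step.
This variable-projection scheme recovers noiseless generating parameters
to ~1e−7 relative, where a plain four-parameter optimiser stalls on the
$(a, d)$ ridge. An optional time shift $x_0$ can be fitted (the
"five-parameter" variant); it is off by default since the four printed
parameters define the canonical form. Reported: parameters, adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$, residual SD, and an honest
convergence flag (constant curves are refused as degenerate — $c$ is
unidentifiable).

`T_half-max` defaults to the **plateau-half** definition, the time at
which the curve reaches half its asymptotic plateau $(a-d)/2$ — apt
because post-fatigue velocity starts near zero — with the closed form
$T = -(1/c)\ln[\ln(2a/(a+d))/b]$, verified in tests against a numeric
root-finder to 1e−9 relative. A **range-half** definition (midpoint of
$y(0)$ and the plateau) is selectable.

Phosphocreatine recovery tables are fitted to
$y(t) = y_{end} - \Delta\,e^{-k_{PCr}t}$ by `nls` (port) with a
log-linear rate initialisation; `half_time = ln 2 / kPCr`.

## Statistics

Repeatability is the mean over subjects of
$100\,|s_1 - s_2| / \bar{s}$ with the symmetric pair-mean denominator
(scan-1 denominator selectable; the published definition does not state
one). Group comparisons use two-sided Student's t-tests — classical
pooled-variance for unpaired data, paired otherwise — with degenerate
zero-variance inputs flagged rather than silently propagated.

## Numerical and design choices

* All internal latencies are "time since stimulus at slice readout";
  negative latencies are baseline. This maps the gated acquisition onto a
  single monotone axis.
* The 67% stimulation-current rule interpolates linearly between tested
  currents by default; nearest-step is an option, as the published rule
  does not say which was used.
* Ties in peak finding resolve to the earlier latency, with a warning.
* NIfTI-1 input/output is implemented minimally in base R (little-endian
  single-file volumes, five datatypes) because no NIfTI package is
  available in the target environment; it is cross-validated against
  `nibabel` in the test suite.
* Seeded determinism: every stochastic component takes an explicit seed
  and restores the caller's RNG state.

## Known limitations

* The phantom's signal model is a stand-in; only timing structure, not
  signal depth, transfers to real data.
* Registration covers translations only; genuinely nonrigid motion is
  flagged at best, not corrected.
* Uniform kinetics within each phantom band understate real within-region
  heterogeneity; the noise-robustness results are therefore a lower bound
  on difficulty, not an upper one.
* Histogram/category analyses assume enough valid voxels to be
  meaningful; with < 50% valid voxels the pipeline warns and results
  should be treated as qualitative.
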