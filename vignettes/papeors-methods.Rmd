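---
title: "Estimating chiral-molecule concentration from photoacoustic signals"
author: "papeors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chiral-molecule concentration from photoacoustic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papeors)
```

## The measurement model

Optically active molecules such as D-glucose rotate the plane of incident
polarized light. Polarimetry exploits this through the specific-rotation
relation

$$ c = \frac{\theta}{[\theta]^{T}_{\lambda}\, l}, $$

where $\theta$ is the observed rotation, $[\theta]^{T}_{\lambda}$ the
specific rotation at wavelength $\lambda$ and temperature $T$, $l$ the path
length and $c$ the concentration. Purely optical polarimetry is limited to
roughly a millimetre of tissue because scattered photons dominate beyond
that. Photoacoustic (PA) detection sidesteps the problem: pulsed NIR-II
light absorbed at depth launches ultrasound, which scatters far less than
light, and the arrival time of the acoustic transient encodes the depth at
which it was generated.

The pressure generated at depth $z$ is proportional to the Grüneisen
parameter $\tau$, the absorption coefficient $\mu_a$ and the local fluence
$\phi(z)$. Holding $\tau$ constant, the PA amplitude read at a depth is a
proxy for the fluence there, and the fluence transmitted through a chiral
medium is modulated the way Malus' law modulates intensity through an
analyzer:

$$ P = P_0 \cos^2\theta
\qquad\Longrightarrow\qquad
\theta = \arccos\sqrt{P/P_0}. $$

`estimate_rotation()` implements exactly this inversion; $P_0$ is read
close to the illumination point (0.018 mm by default) and $P$ at the path
length of interest (1.5--3 mm). The estimate is *faithful* to the
measurement principle in that it conflates Beer--Lambert attenuation with
chiral rotation — the decay $e^{-\mu_a \Delta z}$ also reduces $P/P_0$.
`estimate_rotation_corrected()` exposes the confound: given a user-supplied
$\mu_a$ it divides the attenuation factor out first. The faithful mode is
the default because the calibration regression absorbs any monotone
distortion of $\theta$, and because that is how the measurement is actually
used.

Rotation maps to concentration through a piecewise quadratic calibration

$$ C_p(\theta) = \begin{cases}
a_1\theta^2 + b_1\theta + k_1, & \theta \le \theta_T\\
a_2\theta^2 + b_2\theta + k_2, & \theta > \theta_T
\end{cases} $$

with the two branches fitted by independent ordinary least squares — no
continuity constraint is imposed at $\theta_T$, because the model as
formulated is two free quadratics and forcing continuity would change it.
Serum-sample thresholds near the 200 mg/dl rotation magnitude are available
per polarization via `default_theta_threshold()` (0.88, 0.98 and 0.822 rad
for V, P and R incidence), and `theta_T = "auto"` selects the threshold
from the observed rotations by total residual sum of squares, breaking ties
toward the smaller value. For analytes whose rotation stays linear in
concentration over the working range (naproxen), `fit_linear()` provides the
single-line model.

## What the synthetic-data generator emulates

No laboratory recordings are distributed, so every stage is validated
against a forward model (`simulate_pa_signal()`) that generates traces with
the structure the estimator assumes:

* **Source profile.** One-dimensional ballistic propagation:
  $p(z) = A\, e^{-\mu_a z} \cos^2(r z)$ with $r$ the rotation per metre
  (specific rotation × concentration). This is deliberately *not* a
  polarized Monte Carlo — the pipeline only assumes the
  Grüneisen/Beer--Lambert/Malus structure, and that is what the generator
  provides.
* **Amplitude scale.** $A$ defaults to $\tau \mu_a \phi_0$, which is zero
  when $\mu_a = 0$. Attenuation-free studies (used to score rotation
  recovery without the Beer--Lambert confound) therefore set the scale
  explicitly through the `amplitude` field of `simulator_config()`; the
  default keeps the literal proportionality.
* **Acoustic carrier.** The depth profile is multiplied by a 5 MHz cosine
  before convolution with the transducer response. A smooth fluence profile
  alone has essentially no energy inside a 7.5 MHz detector's band; real
  traces carry in-band structure, and the carrier is the simplest
  deterministic stand-in that lets the analytic-signal envelope recover the
  profile exactly. Its frequency sits mid-band of the 1--9 MHz filter and is
  configurable.
* **Transducer.** `make_transducer_ir()` builds a Gaussian-modulated
  sinusoid whose −6 dB spectral width over centre frequency equals the
  requested fractional bandwidth (7.5 MHz, 60% by default), truncated at
  −60 dB and normalized to unit energy.
* **Nuisance processes.** Additive white Gaussian sample noise (set
  directly or via a target SNR, defined as
  $20\log_{10}(\mathrm{rms_{signal}}/\mathrm{rms_{noise}})$), and
  multiplicative pulse-energy jitter (truncated normal, CV configurable,
  default 2% — typical shot-to-shot stability of a nanosecond OPO). The
  jitter scales the recorded pulse energy too, so `energy_normalize()`
  removes it the way real-time energy monitoring does.
* **Boundary convention.** All stages treat the acquisition window with
  mirror (even-reflection) boundary conditions — generator convolution,
  bandpass filtering, deconvolution and the envelope all extend the trace
  symmetrically and crop afterwards. The absorbing medium therefore does
  not terminate abruptly at the first sample, mimicking windows that open
  inside the illuminated medium rather than at a vacuum interface, and the
  $P_0$ reference (13 samples into a 1 GS/s trace at 0.018 mm) can be read
  without edge transients.

What the generator does **not** emulate: polarized photon transport and
depolarization, scattering phase functions, frequency-dependent acoustic
attenuation, speckle-like absorber microstructure, layered or heterogeneous
speed of sound, and interfering chromophores (water/albumin baselines enter
only through the spectrum blank-correction path). Passing tests therefore
demonstrate that the *pipeline* recovers what the *assumed physics* put in;
they do not certify performance on tissue data.

### Default study conditions

The defaults of `pipeline_config()` are the package's standing study
design: 10 concentrations, 90--400 mg/dl (the clinically relevant glucose
range), 3 replicates each, 20 dB SNR, 2% energy jitter, readings at a 2 mm
path with the P0 reference at 0.018 mm, speed of sound 1420 m/s
(solution-filled holder). The rotation coefficient of 1.75 rad/(m·mg/dl)
maps that range onto roughly 0.31--1.40 rad at 2 mm: about 0.7 rad near
200 mg/dl — the same order as the reported serum thresholds — while keeping
the top of the range below $\pi/2$, where the Malus inversion becomes
ambiguous. Traces are 2048 samples at 1 GS/s so the 2 mm reading sits well
inside the mapped window.

## Signal-processing choices

**Chebyshev bandpass.** Type I, order 4, 0.5 dB passband ripple, 1--9 MHz,
applied forward-backward so it is zero-phase: time-of-flight, and hence
depth, must not shift. Type and order are conventional for PA
band-limiting. The filter is *implemented* as four cascaded biquads derived
from the closed-form analog prototype poles (lowpass-to-bandpass transform
and bilinear mapping on the zero-pole form): at 1 GS/s the band occupies
0.2--1.8% of Nyquist and the expanded order-8 transfer function is
numerically unstable (poles round to outside the unit circle), while the
factored form reproduces the textbook response to three decimals. A
single-pass (causal) option is available behind `zero_phase = FALSE`.

**Wiener deconvolution.** The recorded trace is the PA signal convolved
with the band-limited transducer response; `deconvolve()` inverts this in
the frequency domain with the regularizer
$\mathrm{conj}(H) / (|H|^2 + \mathrm{nsr}\cdot\max|H|^2)$, nsr defaulting
to $10^{-3}$. With `nsr = 0` a pseudo-inverse is used instead: exact
inversion wherever $|H|$ exceeds $10^{-3}$ of its peak (−60 dB), zero
elsewhere. A plain inverse would amplify rounding-level content at
out-of-band frequencies by many orders of magnitude; the −60 dB floor keeps
the noiseless round trip exact to Pearson $r > 0.999$ while staying a true
inverse over the entire band that carries signal. Before the FFT the
mirror padding's outer half is Hann-tapered so the truncated convolution
tails do not alias into the inversion.

**Envelope.** The magnitude of the analytic signal (FFT Hilbert
transform), again under mirror boundary conditions. It is non-negative and
bounds the trace pointwise, which guarantees the extracted $P/P_0$ ratio is
a ratio of non-negative envelope values — the deconvolved trace itself is
bipolar and the measurement principle never specifies whether amplitudes
are signed peaks; the envelope choice makes the Malus ratio well defined.

**Speed-of-sound calibration.** `calibrate_sos()` sweeps 1400--1550 m/s in
5 m/s steps and picks the value whose product with the landmark arrival
time best matches the known 40 mm illumination-to-transducer distance, ties
toward the lower speed. The landmark is the envelope peak by default; a
10%-of-peak onset detector is available, which is preferable when the peak
is broad. Typical calibrated values are 1420 m/s for solution-filled
holders and 1490 m/s for ex vivo tissue.

**Amplitude extraction.** Mean of 5 samples centred on the grid point
nearest the requested depth. At 1 GS/s and 1420 m/s a sample is 1.42 µm of
depth, so the window spans ~7 µm — small against the millimetre-scale
fluence variation but enough to average bin-level noise.

## Outliers, evaluation and detection limit

`remove_outliers()` makes the "about three outliers per calibration set"
policy deterministic: iterate a provisional quadratic fit, drop the largest
absolute externally studentized residual while it exceeds 2.5, at most
three times. Two numerical guards matter: an essentially perfect fit stops
the iteration (studentized residuals of pure rounding noise are
meaningless), and a non-finite studentized residual — which arises when
deleting the point leaves a perfect fit — is treated as infinitely large,
i.e. the strongest possible outlier signal.

Clarke Error Grid Analysis (`cega_zone()`) encodes the published zone
boundaries explicitly. Zone A (within 20% of reference, or both values
below 70 mg/dl) is inclusive of its boundary; zones C, D and E are encoded
as open regions, so a point exactly on one of their boundary lines falls to
the alphabetically earlier zone; B is the residual region. Published
implementations differ precisely on these boundary conventions, which is
why the package pins them down and tests them explicitly against an
independently coded oracle.

The limit of detection follows the zone-A reading of the grid: the
smallest reference concentration from which every tested concentration
upward keeps **all** replicate predictions in zone A (`membership =
"replicate"`, the stricter reading; `"mean"` uses the mean prediction per
concentration). When no concentration qualifies the LOD is reported as
absent, never extrapolated. A conventional calibration-curve LOD
($3.3\,\sigma_{\mathrm{resid}}/\mathrm{slope}$) is available behind
`rule = "calibration"` for comparison.

## Worked example

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 7))
report
#> <papeors_report> 30 records, theta_T = 1.155 rad
#>   zone A: 96.7%   LOD: 124 mg/dl   outliers removed: 2
#>   mean |theta error|: 1.458 deg
```

Thirty simulated records at the default study conditions: 96.7% of
predictions land in zone A and the rotation is recovered to within ~1.5
degrees on average. The LOD of 124 mg/dl here reflects the strictness of
the replicate rule — a single near-miss replicate at the lowest
concentration pushes the LOD to the next level up.

## Numerical conventions and degenerate inputs

* Angles are radians everywhere internally; degrees appear only in
  reports. Reported rotation *thresholds* for this measurement are of
  order 1 rad even though classical polarimetric rotations are
  millidegrees--degrees; the package stores what the calibration uses and
  leaves unit interpretation to the calibration itself.
* `estimate_rotation()` clamps $P/P_0$ into $[0,1]$ with a warning by
  default — noisy data routinely produce $P$ slightly above $P_0$, and
  erroring out would make real traces unusable. `clamp = FALSE` restores
  strict behaviour.
* Negative concentration predictions are floored at zero with a warning.
* Ties in the automatic $\theta_T$ search, the SOS sweep and zone
  assignment are broken deterministically (smaller threshold, lower speed,
  better zone).
* Every stochastic component flows from one master seed through a
  counter-based per-record derivation, so any single record can be
  regenerated without simulating the rest.

## Problem sizes used in the test suite

The shipped tests simulate 2048-sample traces at 1 GS/s (30 records for
the end-to-end study), use 20 random profiles for deconvolution fidelity,
a 500×500 grid for the Clarke-zone equivalence check, 100 seeds for the
SNR calibration check, and 1000-point grids for the Malus inversion. These
sizes make the whole suite run in well under a minute while leaving the
statistical checks comfortably away from their thresholds.

## Known limitations

The faithful estimator's attenuation confound means absolute rotations are
only accurate when $\mu_a \Delta z$ is small or corrected for; the
calibration regression hides this for concentration prediction but not for
physical interpretation of $\theta$. The forward model's carrier is a
modelling convention, not physics — quantitative envelope recovery on real
data depends on the actual in-band content of the PA emission. Rotations
beyond $\pi/2$ alias under the Malus inversion, bounding the usable
concentration × path-length product. Heterogeneous speed of sound,
polarization memory effects and multi-analyte interference are out of
scope.
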