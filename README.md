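# papeors

Photoacoustic polarization-enhanced optical rotation sensing: estimate the
optical rotation of chiral molecules (glucose, naproxen) from photoacoustic
(PA) time-series signals, and calibrate rotation against concentration with
clinical-accuracy evaluation.

## Who this is for

Biophotonics and biomedical-optics researchers working on deep-tissue
chiral sensing. Optical polarimetry is limited to ~1 mm in tissue by light
scattering; PA detection reads the fluence at depth through ultrasound
arrival times instead, extending chiral sensing to several millimetres.
The package implements the complete signal-processing chain for such a
system and a synthetic forward model so the chain can be developed and
validated without laboratory recordings.

## The method

A trans-illumination PA trace is a fluence-weighted pressure record:
`p ∝ τ μₐ φ(z)` with constant Grüneisen parameter τ. A chiral medium
modulates the transmitted fluence the way Malus' law modulates intensity,

    P = P₀ cos²θ        ⇒        θ = arccos √(P/P₀)

where `P₀` is the PA envelope amplitude near the illumination point
(0.018 mm) and `P` the amplitude at the path length of interest (1.5–3 mm).
Rotation links to concentration through the specific rotation
`c = θ / ([θ]·l)`, or empirically through a piecewise quadratic calibration

    Cp(θ) = a₁θ² + b₁θ + k₁  (θ ≤ θ_T)
            a₂θ² + b₂θ + k₂  (θ > θ_T)

(or a single line for linearly responding analytes such as naproxen).
Predictions are scored with Clarke Error Grid Analysis (CEGA) and a
zone-A-based limit of detection.

Processing order: Chebyshev 1–9 MHz bandpass (zero-phase) → pulse-energy
normalization → Wiener deconvolution of the 7.5 MHz / 60%-bandwidth
transducer response → analytic-signal envelope → speed-of-sound calibrated
time-to-depth mapping → amplitude extraction → Malus inversion → calibration
fit → prediction → CEGA/LOD.

## Worked example

```r
library(papeors)
report <- run_pipeline(pipeline_config(seed = 7))
report
#> <papeors_report> 30 records, theta_T = 1.155 rad
#>   zone A: 96.7%   LOD: 124 mg/dl   outliers removed: 2
#>   mean |theta error|: 1.458 deg
```

This simulates the default study: 10 glucose concentrations from 90 to
400 mg/dl, 3 replicates each, at 20 dB SNR with 2% pulse-energy jitter,
runs every stage, fits the piecewise quadratic calibration (threshold
found automatically at 1.155 rad) and evaluates the predictions. 96.7% of
the 30 predictions fall in Clarke zone A (clinically accurate); the
rotation at the 2 mm reading depth is recovered to 1.46° on average; the
strict replicate-wise LOD lands at 124 mg/dl because one replicate at the
lowest level misses zone A.

Individual stages are plain functions:

```r
ir  <- make_transducer_ir()                      # 7.5 MHz, 60% bandwidth
cfg <- simulator_config(mu_a = 0, amplitude = 1,
                        rotation_per_depth = 1.75 * 200)
sig <- simulate_pa_signal(ground_truth(200, cfg),
                          acquisition_geometry(sos = 1420), ir)
sig  <- envelope(deconvolve(energy_normalize(bandpass_filter(sig)), ir))
prof <- to_depth_profile(sig, sos = 1420)
amps <- extract_amplitudes(prof, target_depth = 2e-3)
estimate_rotation(amps$P, amps$P0)               # 0.692 rad (truth 0.700)
```

A command-line front end with `simulate`, `run`, `fit`, `predict` and
`evaluate` subcommands ships in `inst/cli/papeors.R`.

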