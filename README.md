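# headstats

Statistics of natural head orientation, and what they predict about tilt
perception.

Humans sample gravity through the vestibular system of a head that is
rarely upright and rarely still. This package is for researchers in
vestibular/sensory neuroscience who work with head-mounted 6-DOF odometry
(e.g. visual-inertial trackers) and want to go from raw orientation +
acceleration streams to the quantities that constrain models of verticality
perception and tilt/translation processing:

* **calibrated head-frame kinematics** — the rotation from the arbitrary
  sensor mounting to an anatomically defined head frame, estimated from a
  nod/shake/static calibration protocol (nods and shakes pin the interaural
  and dorsoventral axes; a static segment with Reid's baseline horizontal
  pins the pitch offset to gravity), with periodic recalibration for strap
  slippage;
* **screened data** — tracking-confidence and velocity-artifact exclusion
  rules, and a low/high linear-velocity partition (0.75 m/s) separating
  stationary from locomotor behavior;
* **orientation statistics** — moments through excess kurtosis, the
  one-sided variability ratio about the distribution peak, and
  kernel-density estimates on a whole-degree grid;
* **gravitoinertial spectra** — per-axis Welch power spectra of the
  gravitational (`R(q) g`) and inertial (`a_total − R(q) g`) components of
  head acceleration, and the crossing frequency where inertial power
  overtakes gravitational power (the empirical anchor for
  frequency-segregation models of the otolith ambiguity);
* **a Bayesian perception model** — the measured orientation KDE as prior,
  a Gaussian likelihood whose sd grows with eccentricity (linearly, or with
  |sin θ| following utricular-shear geometry), the posterior mean as
  percept. The single free parameter σ (multiplicative likelihood noise) is
  fitted to psychophysical bias tables by minimizing the residual standard
  error `RSE = sqrt(Σ(yᵢ − ŷᵢ)² / (n − 2))`, returning a standard R model
  object (`print`/`summary`/`coef`/`predict`/`residuals`/`plot`/`simulate`);
* **a synthetic generator** — `simulate_recording()` produces odometry with
  the distributional, activity, spectral, calibration and artifact
  structure of natural recordings (downward-biased asymmetric pitch,
  heavy-tailed roll, ~92% low-velocity time, a 2 Hz locomotor peak), so the
  whole pipeline is testable without field data.

Conventions: world Z up, gravity (0, 0, −9.81) m/s²; head X forward,
Y left, Z up; positive pitch = extension (so natural downward pitch has a
negative mean); positive roll = left-ear-down; quaternions Hamilton
scalar-first, passive world→frame.

## A worked example

```r
library(headstats)

cfg <- run_config(out_dir = "demo_run",
                  sim = sim_config(duration_s = 3600), seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
<headstats_run>
headstats run (seed 1)
retained 0.978 h; low/high fraction 0.9156/0.0844
pitch: mean -1.7498 sd 16.7691 skew -0.4101 exkurt 1.6821
roll:  mean -0.0094 sd 6.2071 skew -0.0132 exkurt 7.1914
pitch asymmetry ratio 1.3737 (below side larger)
crossings (all): X 0.7119, Y 0.5901, Z 0.6961 Hz
crossings (low): X 2.096, Y 1.511, Z 2.119 Hz
crossings (high): X 0.5438, Y 0.3259, Z 0.4258 Hz
fit stage skipped
```

Reading this: of the simulated hour, 0.978 h survives calibration excision
and artifact screening, 91.6% of it below 0.75 m/s. Pitch is biased
downward (−1.75°) and wide (SD 16.8°), with 1.37× more one-sided
variability on the forward/downward flank of the peak; roll is centered,
narrower (SD 6.2°) and strongly leptokurtic (excess kurtosis 7.2). On each
axis, gravitational acceleration dominates below ~0.6–0.7 Hz and inertial
acceleration above; restricted to quiet (low-velocity) epochs the crossing
moves up (self-motion power is weak), and in locomotor epochs it moves
down. Fitting the perception model to a bias table then takes one call:

```r
prior <- res$priors$all$pitch
tab <- simulate_psych_bias(prior, noise_model("shear", 0.10), seq(-80, 80, 10),
                           obs_noise_sd_deg = 0.5, seed = 2)
fit <- fit_tilt_perception(tab, prior, kind = "shear")
print(fit)
#> Bayesian tilt-perception fit (shear noise)
#>   sigma = 0.1002, RSE = 0.589 deg over 17 points (additive sd 2.30 deg)
plot(fit)
```

With an asymmetric pitch prior the fitted curve shows larger maximum bias
for backward than forward pitch — the structural signature of the
heavier forward flank. Digitized bias tables from the psychophysics
literature can be supplied as CSV (`angle_deg, bias_deg`) through
`run_config(psych = ...)`.

## Command-line use

A thin wrapper ships in `inst/scripts/`:

```sh
Rscript inst/scripts/headstats simulate --seed 1 --duration 3600 --out rec.tsv
Rscript inst/scripts/headstats run --rec rec.tsv --out results/
```

`run_pipeline()` writes every intermediate artifact (retention report,
moment and asymmetry summaries, per-class priors and spectra, crossing
points, fits) plus a manifest with MD5 content hashes; rerunning an
identical configuration reproduces identical artifacts.
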