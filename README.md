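# gaitcast

Short-horizon (≈ 1 s) prediction of a walking person's position from the
sampled planar position of a waist-level landmark, with gait-biomechanics
compensation of the state estimates.

## The problem

Robots sharing space with people need to know where a walker will be about a
second from now. At that horizon, kinematic dead-reckoning is the right tool:
seed a motion model with the current state `(x, y, φ, v, a, w)` and apply its
discrete update recursively. The package implements the four classical planar
models — exact discretisations of the unicycle kinematics
`ẋ = v cos φ, ẏ = v sin φ, φ̇ = w, v̇ = a`:

| model | assumption |
|-------|------------|
| CV    | constant velocity (`w = a = 0`) |
| CA    | constant acceleration (`w = 0`) |
| CTRV  | constant turn rate and velocity (`a = 0`) |
| CTRA  | constant turn rate and acceleration |

Human gait breaks these models' assumptions: the waist landmark sways once
per stride and the speed pulses with each step, so states estimated by
finite differences (the *raw* trajectory) carry large oscillations that the
models extrapolate into error. `gaitcast` adds two causal, real-time
compensations driven by gait biomechanics:

* **velocity hold** — the raw speed at foot-contact instants approximately
  equals the stride mean; contacts are detected as extrema of `dv/dt` and the
  event-sampled speed is held (zero-order hold) between them;
* **orientation blend** — pelvis yaw `φʰ` and the position-derived heading
  `φʳ` oscillate in counter-phase, so `φ̃ = K φʰ + (1 − K) φʳ` cancels the
  oscillation; the per-subject gain `K` is calibrated in closed form against
  an offline polynomial-regression baseline.

An acausal whole-signal baseline (degree-1 fits for straight segments,
degree-8 for single turns) serves as the instrumental upper bound, and a
horizon-error protocol sweeps predictions from every start sample, reporting
RMS Euclidean error per horizon step against the measured positions. Because
the reference motion-capture recordings are private, a synthetic gait
generator with analytic ground truth (true contact instants, true blend
gain) stands in for them; see the methods vignette
(`vignettes/gait-aware-prediction.Rmd`) for the generative model and what a
green test does and does not establish.

## Worked example

Simulate one curved walk (1.5 m radius, accelerating, 100 Hz), run the full
stack, and compare models and variants at a 1 s horizon:

```r
library(gaitcast)
syn <- synthesize(synth_config("circle", mean_speed = 1.0, mean_accel = 0.04,
                               stride_hz = 1.05, seed = 42))
syn
#> <synthetic walk> circle, 1.00 m/s, stride 1.05 Hz, 812 samples, K_truth=0.673, 17 true events

traj <- lowpass_prefilter(syn$traj)            # 3rd-order Butterworth, 6 Hz
raw  <- estimate_raw_states(traj)              # finite-difference states
off  <- estimate_offline_states(fit_baseline(traj))   # degree-8 baseline
pars <- calibrate_K(raw, off, traj)            # per-subject blend gain
pars
#> <compensation params> K=0.6253, min interval=0.25 s, prominence frac=0.1, smoothing=5 samples, pelvis offset=0.002893 rad

rt <- build_realtime_states(traj, pars)        # causal compensated states
profs <- list()
for (m in c("CV", "CTRV")) for (s in list(raw, off, rt))
  profs[[length(profs) + 1]] <- horizon_sweep(s, traj, m)
summarize_profiles(profs)
#>  model  variant path_type horizon_s rms_mm n_starts
#>   CTRV  offline    curved         1  37.72      710
#>     CV  offline    curved         1 445.69      710
#>   CTRV      raw    curved         1 482.15      710
#>     CV      raw    curved         1 466.88      710
#>   CTRV realtime    curved         1 152.20      710
#>     CV realtime    curved         1 459.02      710
```

Reading the table: predicting this curved walk one second ahead with CTRV
costs 482 mm RMS from the raw oscillating states, 38 mm from the acausal
baseline, and 152 mm from the causal real-time compensation — the
compensation recovers most of the gap while remaining deployable. CV cannot
follow the turn at all (~450 mm everywhere). The calibrated gain 0.625 sits
close to the generator's analytic truth 0.673.

The same pipeline runs from a YAML config (`run_pipeline("cfg.yaml")`) or
from the command line via the installed script:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gaitcast", package="gaitcast"))')" \
    simulate --path circle --radius 1.5 --speed 1.0 --stride-hz 1.0 --seed 7 --out walk.csv
```

Subcommands: `simulate`, `estimate`, `baseline`, `calibrate`, `predict`,
`evaluate`. Trajectory CSVs use the header `t_s,x_m,y_m,pelvis_yaw_rad`
(metres, radians); CLI indices are 0-based.

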