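# lapfc

Frame connection for single-molecule localization microscopy (SMLM) via a
linear assignment problem.

## The problem

SMLM techniques ((d)STORM, PALM, DNA-PAINT) localize sparse blinking
fluorophores frame by frame. One blinking event typically yields several
localizations in consecutive or near-consecutive frames — repeats that
clutter downstream analysis and waste photons. *Frame connection* merges
the repeats of each blinking event into a single localization of higher
precision. The danger is over-clustering: merging localizations of
*different* emitters destroys real structure irreversibly.

`lapfc` is for SMLM analysts who want a frame connector that is effectively
parameter-free and conservative about over-clustering, and for method
developers who want the standard baselines, a ground-truth simulator, and a
quantitative evaluation statistic in one toolbox.

## The method

Connection decisions are posed as a minimum-cost linear assignment problem
(LAP). Localizations are first grouped into spatiotemporal preclusters
(nearest neighbor within 5 frames and 5× the localization error). From the
preclustered data the package self-calibrates a three-state blinking model —
on rate *k*<sub>on</sub>, off rate *k*<sub>off</sub>, bleach rate
*k*<sub>bleach</sub> (frame⁻¹), per-frame miss probability
*p*<sub>miss</sub> — and local emitter densities ρ<sub>on</sub>(**x**, f),
ρ<sub>off</sub>(**x**, f). Within each precluster of n<sub>c</sub>
localizations a 2n<sub>c</sub> × 2n<sub>c</sub> block cost matrix holds
−log-probability costs:

* **connection** of two localizations Δf frames apart:
  −Σᵢ log N(Δxᵢ; 0, σ²ᵢ) − log[(1−p<sub>miss</sub>)p<sub>miss</sub>^(Δf−1)]
  + (k<sub>off</sub>+k<sub>bleach</sub>)Δf, with σ²ᵢ the summed per-axis
  variances of the pair;
* **birth** of a new emitter after N<sub>p</sub> candidate frames, from the
  local off-state density switching on or the on-state density being
  missed;
* **death**: no further observations for the remaining N<sub>f</sub>
  frames.

A Jonker–Volgenant solver finds the exact minimum-cost assignment; chains
of selected connections are each combined by the maximum-likelihood
position estimate x̂ = Σ(xᵢ/σᵢ²)/Σ(1/σᵢ²) with variance
σ̂² = 1/Σ(1/σᵢ²) (inverse Fisher information).

Also included: the classical (0.2 px / 1 frame), revised classical
(2σ / 5 frames) and chi-square hypothesis-test (α = 0.05) connectors; a
blinking simulator (Gillespie or discrete-frame kinetics, CRLB-calibrated
noise); and evaluation via the deviation δ = F − F<sub>ideal</sub> of the
nearest-neighbor-distance CDF from the ground-truth ideal result
(δ < 0: over-clustering, δ > 0: under-clustering).

## Worked example

```r
library(lapfc)

sim <- simulate_smlm(rho0 = 10, roi_size = 8, n_frames = 10000,
                     kinetics_mode = "discrete", seed = 42)
sim
#> SMLM simulation (uniform, discrete kinetics): 674 emitters, 10000 frames, 4597 localizations

estimate_kinetics(sim$localizations)
#> Kinetic self-calibration from 4597 localizations in 2372 preclusters
#> Blinking kinetic model (rates in frame^-1):
#>   k_on = 0.0064459  k_off = 0.51599  k_bleach = 0.15495  p_miss = 0.01883
#>   duty cycle tau = 0.009516  lambda1 = 0.0014745  lambda2 = 0.67591
#>   N_emitters = 726.2, f_end = 4954
```

The generative rates were k_on = 0.005, k_off = 0.5, k_bleach = 0.2 with
p_miss = 0.01: the off rate is recovered within a few percent; the bleach
rate (a difference of two estimates) and on rate carry the estimators'
known small-sample biases. The connector itself is robust to errors of this
size.

```r
connected <- frame_connect(sim$localizations, "lapfc")
nrow(connected)
#> [1] 2662
```

4597 raw localizations merge into 2662 (mean blink ≈ 2 frames). Comparing
all four connectors against the ground-truth ideal result on a Gillespie
simulation:

```r
sim_g <- simulate_smlm(rho0 = 10, roi_size = 8, n_frames = 10000,
                       kinetics_mode = "gillespie", seed = 42)
ev <- evaluate_methods(sim_g)
ev
#> Frame-connection evaluation against the ideal result:
#>             method max_abs_delta     min_delta
#>          classical     0.3247590  0.0000000000
#>    hypothesis_test     0.3505487 -0.0072294170
#>              lapfc     0.2450143  0.0007173601
#>  revised_classical     0.4762987 -0.0055816797
```

LAP-FC tracks the ideal CDF most closely (smallest max |δ|) with no
over-clustering dip (min δ ≥ 0), while the hypothesis test shows a negative
dip — over-clustering — that deepens at higher emitter densities.
`autoplot(ev)` draws the δ curves; `plot_duration_histogram(ev, model)`
compares blink-duration histograms against the geometric expectation.

A thin command-line wrapper over these functions ships in `inst/cli/lapfc`
(`simulate`, `connect`, `evaluate`, `render` subcommands; YAML configs with
flag overrides).

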