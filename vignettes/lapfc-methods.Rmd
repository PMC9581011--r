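---
title: "Frame connection by linear assignment: models and methods"
author: "lapfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame connection by linear assignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapfc)
```

## The frame-connection problem

Single-molecule localization microscopy (SMLM) reduces raw camera frames to
a table of localizations: fitted emitter positions with per-axis standard
errors. A fluorophore that stays "on" for several frames produces one
localization per frame, all from the same blinking event. Frame connection
is the pre-processing step that merges these repeats into one localization
of higher precision, without destroying the temporal structure of blinking
and, critically, without merging localizations that came from *different*
emitters (over-clustering), which would erase real structure.

`lapfc` implements a frame connector that formulates the merge decisions as
a linear assignment problem (LAP) with statistically motivated costs,
alongside three reference connectors (classical hard-threshold, revised
classical, and a chi-square hypothesis test), a ground-truth blinking
simulator, and an evaluation statistic based on nearest-neighbor distance
CDFs.

## Blinking model

Each emitter follows a three-state chain, with all rates in frame$^{-1}$:

* dark $\to$ on at rate $k_{on}$ (emitters start dark at frame 1),
* on $\to$ dark at rate $k_{off}$ (reversible),
* on $\to$ bleached at rate $k_{bleach}$ (absorbing),

and a visible emitter fails to be localized with probability $p_{miss}$ per
frame. Derived quantities: the duty cycle
$\tau = k_{on}/(k_{on}+k_{off}+k_{bleach})$ and the on-density decay
constants $\lambda_1 = k_{bleach}\tau$ and
$\lambda_2 = k_{on}+k_{off}+k_{bleach}-\lambda_1$. The expected cumulative
localization count by frame $f$ from $N_{emitters}$ emitters is

$$\langle n \rangle_f = N_{emitters}(1-p_{miss})\,\tau\left[
\frac{1-e^{-\lambda_1 (f-1)}}{\lambda_1} -
\frac{1-e^{-\lambda_2 (f-1)}}{\lambda_2}\right],$$

implemented with the analytic $\lambda_1 \to 0$ limit $(f-1)$ so a
zero-bleach model is still well defined.

## The three pipeline stages

### 1. Preclustering

A global LAP over $\sim 10^6$ localizations is infeasible, so localizations
are first grouped into small spatiotemporal *preclusters* and the LAP is
solved inside each. Visiting localizations in (frame, id) order, each one
searches past frames within `max_frame_gap` (default 5) for its spatial
nearest neighbor within `n_sigma` (default 5) times *its own* localization
error $\bar\sigma = \sqrt{(\sigma_x^2+\sigma_y^2)/2}$ and joins that
neighbor's cluster; otherwise it founds a new cluster. Same-frame
localizations can share a precluster only through chains via other frames.

Two details here were genuinely open and are package decisions:

* **Query-only radius.** The search radius is a multiple of the *query's*
  error, not of a pair-combined error. Besides being the literal reading of
  "its localization error", the pair-combined alternative enlarges the
  search area twofold, and at the densities used for validation
  (10 emitters/px$^2$) that measurably contaminates preclusters with
  second emitters, which biases every downstream kinetic estimate (the
  duration-based total rate by $\sim -20\%$ rather than $\sim -5\%$).
  Preclustering errs on the generous side by design — the LAP stage can
  split an over-merged precluster, but a split precluster can never be
  rejoined — and the query-only radius is already generous at 5$\bar\sigma$.
* **Deterministic order.** Processing is by ascending (frame, id), with
  equidistant-neighbor ties broken toward the smaller id, so the partition
  is reproducible. Joining follows the nearest eligible neighbor only;
  clusters are never merged retroactively.

### 2. Self-calibrating kinetics and densities

Assuming preclusters are on average single blinking events:

* Durations $N$ (frame span) of a blink are geometric with per-frame stop
  probability $1-e^{-(k_{off}+k_{bleach})}$, giving
  $\widehat{k_{off}+k_{bleach}} = -\log(1 - 1/\bar N)$.
* $\hat p_{miss} = 1 - \overline{n_c/N}$, one minus the mean cluster fill
  fraction.
* $\hat k_{off} = n_{clusters}/n$, the precluster/localization count ratio.
* $\hat k_{bleach}$ is the difference of the first and third estimates,
  floored at the rate lower bound.
* $\hat k_{on}$ and $\hat N_{emitters}$ come from least-squares fitting the
  cumulative-count model above to the observed per-frame cumulative curve
  with the other three parameters fixed.

Local density: each precluster's density is
$\rho_c = (k+1)/(\pi r_k^2)$ from the distance $r_k$ to its $k$-th nearest
precluster centroid ($k = 2$; with fewer than $k+1$ preclusters, the global
count/area density is used). The initial emitter density is recovered by
inverting the forward relation
$\rho_c = \rho_0\, k_{off} (1-p_{miss}) \tau [\cdot]$ evaluated at the last
frame with data; the on/off-state densities at frame $f$ follow as
$\rho_{on}(f) = \rho_0 \tau (e^{-\lambda_1(f-1)} - e^{-\lambda_2(f-1)})$
and $\rho_{off}(f) = \rho_{on}(f)\,k_{off}/k_{on}$.

Numerical guard rails: rates are clamped to $[10^{-5}, 5]$ frame$^{-1}$ and
$p_{miss}$ to $[0, 0.5]$ — values outside these are physically meaningless
at one-frame resolution — and the $k_{on}$ fit is initialized by a
log-spaced grid over $[10^{-4}, 1]$ frame$^{-1}$ (the model is linear in
$N_{emitters}$, so the emitter count has a closed form per candidate rate)
before local refinement. The default ROI for the global density fallback is
the whole-pixel bounding box of the data: coordinates are pixel units, and
a sub-pixel bounding box around a tiny cluster would produce an absurd
density estimate.

These estimators carry known small biases at high density: preclusters
occasionally span a re-activation of the same emitter (within the 5-frame
gap) or capture a neighboring emitter, both of which inflate $\bar N$ and
deflate $n_{clusters}/n$. Under the validation conditions below the
recovered rates land within roughly 5% ($k_{off}$), 20% ($k_{bleach}$, the
difference of two estimates, which amplifies relative error) and 25%
($k_{on}$) of truth. The LAP costs are deliberately tolerant of estimate
errors of this size.

### 3. Assignment costs and the block LAP

For each precluster of $n_c$ localizations a $2n_c \times 2n_c$ cost matrix
is assembled from $-\log$ probabilities:

* **Connection** (upper-left, upper-triangular in time, halved): Gaussian
  probability of the observed separation given per-axis summed variances
  $\sigma_{x}^2 = \sigma_{x,1}^2 + \sigma_{x,2}^2$, times
  $(1-p_{miss})p_{miss}^{\Delta f - 1}$ for the skipped frames, times
  $e^{-(k_{off}+k_{bleach})\Delta f}$ for staying on. Same-frame pairs are
  prohibited.
* **Death** (upper-right diagonal): the emitter bleaches, turns off, or is
  missed for the $N_f$ remaining candidate frames:
  $-\log[(1-e^{-k_{bleach}}) + (1-e^{-k_{off}}) + p_{miss}^{N_f}]$. The
  argument can exceed 1, so death costs may be negative; the solver accepts
  arbitrary finite costs and no shifting is applied.
* **Birth** (lower-left diagonal): a new emitter appears after $N_p$
  candidate frames — either an off-state emitter (density
  $\rho_{off}$ at the localization's frame) switched on now, or an on-state
  emitter (density $\rho_{on}$ at the first candidate frame) was missed
  $N_p$ times.
* **Auxiliary** (lower-right): transpose of the connection block, so a
  selected connection and its mirror sum to exactly one full connection
  cost.

The candidate frame window of a precluster is its observed frame span
($N_p = f - f_{start}$, $N_f = f_{end} - f$); the algorithm has no other
window available. Since all emitters start dark, $\rho_{on}(1) =
\rho_{off}(1) = 0$ and a precluster starting at frame 1 has an infinite
birth cost for its first row; this and any other non-finite cost is
replaced by twice the summed *magnitude* of the finite costs in the matrix.
The magnitude matters: death costs are routinely negative, and substituting
twice a negative plain sum would make impossible events the cheapest
entries, inverting the substitution's purpose of keeping them as a last
resort.

The assignment is solved exactly with a Jonker–Volgenant-style shortest
augmenting path algorithm (dense, with the prohibition mask honored
structurally rather than by a numeric sentinel); upper-left selections form
directed links whose chains are the clusters. Each cluster is combined by
the maximum-likelihood position estimate — the inverse-variance weighted
mean per axis — with combined variance
$\hat\sigma^2 = 1/\sum_i \sigma_i^{-2}$ (the inverse Fisher information).
Photons are summed, background averaged, and the combined record keeps the
first member frame as its canonical frame so downstream kinetics retain the
blink start time.

## Baseline connectors

All three baselines share one greedy chaining engine (ascending frame, then
id; a chain's comparison point is its running inverse-variance centroid,
which is what mature implementations of the classical method use; ties go
to the best-scoring chain) and the same maximum-likelihood combiner as
LAP-FC, so differences between methods reflect their accept rules only:

* **classical**: accept within 0.2 px and 1 frame (hard thresholds);
* **revised classical**: accept within 2 combined errors and 5 frames;
* **hypothesis test**: prefilter at 1 px and 5 frames, then test the null
  hypothesis "same emitter" with
  $s = \Delta x^2/\sigma_x^2 + \Delta y^2/\sigma_y^2 \sim \chi^2_2$,
  accepting when the p-value is at least $\alpha = 0.05$.

Same-frame merges are prohibited in all connectors, for parity with the
assignment formulation. The hypothesis-test construction is a
reconstruction of the published description of that method, not a
re-implementation of any specific package.

## The simulator

`simulate_smlm()` generates ground-truth data: emitters placed uniformly at
density $\rho_0$ in a square ROI (or as dimer pairs at fixed separations on
a widely spaced grid), blinking simulated either by the exact Gillespie
algorithm in continuous time (default) or by a per-frame Markov chain
(`"discrete"`), photons reduced by $U(0,1)$ on frames where the emitter
switched, positional noise drawn at the Cramér–Rao lower bound (CRLB) of a
pixel-integrated symmetric Gaussian PSF with uniform background over a
7×7 px window, plus 0.05 px of residual noise emulating uncorrected drift,
and a fraction $p_{miss}$ of localizations removed.

Two reporting decisions matter:

* **Reported error excludes the residual noise.** The 0.05 px term models
  noise a localization fitter cannot know about, so `sigma_x`/`sigma_y`
  report the CRLB alone while positions scatter with the quadrature total.
  Connectors therefore operate — as on real data — with a slightly
  optimistic error estimate. The calibration tests verify both halves:
  with `extra_noise_sigma = 0` the normalized errors have unit standard
  deviation within 5%, and under the default the total scatter matches
  $\sqrt{\sigma_{reported}^2 + 0.05^2}$.
* **Two kinetics modes.** The discrete-frame mode makes blink durations
  exactly geometric, matching the duration estimator's model, and is used
  for quantitative parameter-recovery validation (it separates estimator
  model-mismatch from implementation error); the Gillespie mode is the
  faithful generative model and is used for method comparisons.

What the simulator does **not** emulate: PSF overlap and multi-emitter
fitting failures, spatially or temporally varying rates, structured
backgrounds, and drift beyond the constant isotropic residual term.
Passing tests on these simulations therefore demonstrate correctness of
the connectors under the assumed blinking and noise model, not performance
on arbitrary real data.

## Evaluation

With ground truth, the *ideal* connection combines same-emitter
localizations chained transitively at gaps of at most 5 frames (chaining,
because the connectors being scored also chain). The comparison statistic
is the binned CDF $F(r)$ of each localization's nearest-neighbor distance
among localizations 1–5 frames away (same-frame neighbors excluded), on a
fixed grid of 0.01 px bins up to 2 px, and its deviation
$\delta(r) = F(r) - F_{ideal}(r)$: $\delta > 0$ indicates under-connection
(unmerged repeats create small distances), $\delta < 0$ over-connection.
When ensembles of simulations are evaluated, nearest-neighbor distances are
pooled across simulations before binning, which weights simulations by
sample size. Duration histograms of connected results are compared against
the geometric law with stop probability $1 - e^{-(k_{off}+k_{bleach})}$.

## Validation problem sizes

The packaged tests validate on scaled study conditions chosen to exercise
the same densities as the original setting while keeping runtimes friendly:
kinetic recovery on three 16×16 px, 10,000-frame discrete-mode simulations
at 10 emitters/px$^2$ ($\sim$ 53,000 localizations total); method
comparisons on five 8×8 px Gillespie simulations at the same density, with
the density trend checked at 5 and 20 emitters/px$^2$; solver correctness
against exhaustive permutation search on 1,000 random small cost matrices;
and all cost formulas against independent hand evaluations.

## Known limitations

* Rates are global: no spatial or temporal variation within a dataset
  (densities vary spatially only through the per-precluster $\rho_c$).
* Two-dimensional only; no axial (z) coordinate.
* Assignment is solved per precluster; localizations in different
  preclusters can never be merged, so preclustering errors of the
  too-conservative kind are unrecoverable downstream.
* The k-nearest-neighbor density estimator is biased high for sparse
  configurations; the LAP costs tolerate this, but the reported
  `rho0_local` values inherit the bias.
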