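---
title: "Counting engaged dynein motors and dissecting their stepping kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting engaged dynein motors and dissecting their stepping kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cargodyn)
```

## The scientific problem

Cytoplasmic dynein carries endosomes and other cargo retrogradely along
axonal microtubules. Two questions about this transport are hard to answer
from a position trace alone: *how many motors* are actively engaged at any
moment, and *what limits the rate* of each individual mechanical step?
`cargodyn` implements a statistical route to both, built for long,
high-rate (10 ms and faster) single-particle tracks of the kind produced by
non-bleaching luminescent probes, together with a synthetic-data generator
that produces tracks with exactly the statistical structure the analysis
assumes, so every estimator in the package can be validated against known
ground truth.

## Motor counting from displacement fluctuations

For a segment of roughly constant velocity, form all displacements
$\Delta x(t,\tau) = x(t+\tau) - x(t)$ at delay $\tau$ and summarize them by
their mean $\mu(\tau)$ and variance $s^2(\tau)$. The working statistic is

$$\phi(\tau) \;=\; \frac{2\mu(\tau)}{s^2(\tau)}.$$

If a single motor steps as a Poisson process at rate $\lambda$ with
per-step displacement mean $\bar d$ and variance $v$, then
$\mu = \lambda\tau\bar d$ and $s^2 = \lambda\tau(\bar d^2 + v) + 2\sigma^2$
(the $2\sigma^2$ is static localization noise), so

$$\phi(\tau) = \frac{2\lambda\tau\bar d}{\lambda\tau(\bar d^2+v) + 2\sigma^2}
\;\xrightarrow{\tau\to\infty}\; \frac{2\bar d}{\bar d^2+v} \equiv \phi_1 .$$

With $n$ motors rigidly sharing one cargo (cargo at the arithmetic mean of
the motor positions), each motor step moves the cargo by $1/n$ of the step:
the drift is unchanged but the variance is divided by $n$, so the asymptote
is $n\,\phi_1$ — *quantized* in integer multiples of the single-motor
value, while the mean velocity $\lambda\bar d$ does not depend on $n$ at
all. Counting motors reduces to reading off which multiple of $\phi_1$ a
segment's asymptote sits at:

```{r phi-demo}
tr <- simulate_cargo_trajectory(
  step_model(),                       # dbar = 8 nm, v = 96 nm^2, 150 steps/s
  cargo_config(n_motors = 2, duration = 60, seed = 7))
pp <- phi_pipeline(project_to_axis(tr), noise_sd = 2, dt = 0.01)
pp$asymptote$phi_inf     # ~0.2 nm^-1: twice the single-motor quantum
```

### Calibration choices

* **Single-motor step model.** The default is $\bar d = 8$ nm and
  $v = 96$ nm$^2$, which makes $\phi_1 = 2\bar d/(\bar d^2+v) = 0.1$
  nm$^{-1}$. The 8-nm mean matches the dominant mode of measured step-size
  histograms; the variance is not directly measurable in vivo and is
  *derived* from the observed quantum and the mean — it is a calibration,
  not a measurement. Step sizes live on the $\pm\{4, 8, 16, 24\}$ nm
  lattice (half multiples of the 8-nm tubulin repeat, since a single head
  displacement moves the motor's center of mass by half of it); mixture
  probabilities are solved by non-negative least squares to hit
  $(\bar d, v)$ exactly and infeasible pairs are rejected.
* **Stepping rate.** The in vivo multi-motor stepping rate is not
  measurable directly at 37 °C; the default 150 steps/s reproduces the
  observed ~1.2 µm/s segment velocities with the 8-nm mean step.
* **Coupling.** Rigid averaging over motor positions. The half-step
  argument that motivates it is exact for two motors; we extend it to all
  $n \le 10$. Elastic linkages are out of scope; with compliant linkers
  the variance division would be only approximate and the quantization
  correspondingly blurred.
* **Noise correction.** When $\sigma$ is known (always true for synthetic
  data), $\phi = 2\mu/(s^2 - 2\sigma^2)$; otherwise the uncorrected ratio
  is used. With the defaults the tail bias from skipping the correction is
  under 2%.
* **Delay grid and asymptote.** 10-ms steps from 10 to 200 ms; the
  asymptote is the mean of $\phi(\tau)$ over $\tau \ge 120$ ms, where the
  relaxation above has leveled off. A segment counts as *converged* only
  when the fitted relative trend across that window is below 10%;
  non-converged segments carry no asymptote and are reported separately.
  About 60% of segments converge under the default synthetic conditions,
  matching what long in vivo tracks show.
* **Overlapping pairs.** All overlapping $(t, t+\tau)$ pairs are used.
  This maximizes data but correlates neighboring entries, so standard
  errors for $\phi_\infty$ come from a block bootstrap over 0.5-s time
  blocks (`phi_boot_se`), not from naive pair counts.
* **Cluster count.** Pooled asymptotes are clustered by k-means
  (50 restarts) over $k = 1..6$; $k$ is chosen by the largest relative
  drop in within-cluster sum of squares, with two safeguards: solutions
  containing a singleton cluster are rejected (an outlier split, not
  structure), and a flat WSS profile falls back to one cluster. Cluster
  centers are then regressed onto integer multiples of a fitted quantum
  (least squares through the origin, iterated), which makes the
  motor-number assignment automatic rather than by inspection.

## Stepping kinetics from dwell times

At slow stepping rates individual ~8-nm steps are resolvable. Steps are
detected by iterative chi-square staircase fitting: repeatedly insert the
step that maximally reduces the residual sum of squares, and choose the
number of steps where the *counter-fit* quality ratio peaks — a counter-fit
places steps at the midpoints of the fitted plateaus, and the ratio
$\chi^2_{\rm counter}/\chi^2_{\rm fit}$ is largest when the fit captures
real steps rather than noise. Because that ratio can dip locally before
every true step has been placed, the search continues to twice the current
peak (at least 100 steps) before stopping. Steps smaller than 4 nm — the
elementary lattice spacing, and the practical noise floor — are merged
away.

Dwell times between steps are fit by maximum likelihood on the *raw*
dwells; prebinned histogram fitting is provided only as a comparison mode
(`fit_dwell_histogram`) because its result depends on the bin width. The
central model is the convolution of two equal-rate exponentials
(Erlang-2), $P(t) = k^2 t e^{-kt}$, with closed-form MLE
$\hat k = 2/\overline{t}$ and Fisher standard error $\hat k/\sqrt{2n}$.
Model adequacy is judged by AIC against a single exponential and a free
two-parameter gamma (a gamma shape near 2 supports two equal sequential
rate-limiting transitions), plus an unconstrained two-rate convolution
whose fitted rates coincide on equal-rate data.

The *randomness parameter*
$r = (\langle t^2\rangle - \langle t\rangle^2)/\langle t\rangle^2$
summarizes dwell shape: $n_{\min} = 1/r$ lower-bounds the number of
rate-limiting transitions per cycle ($r = 1/m$ for Erlang-$m$).
Temperature dependence of the fitted rates is summarized by an Arrhenius
fit of $\ln k$ on $1/T$ ($T$ in kelvin, $E_a = -\mathrm{slope}\cdot R$,
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$). The default fit is
unweighted; an SE-weighted mode is available. On the published
temperature–rate triple (13.9, 56.1, 97.1 s$^{-1}$ at 22, 30, 37 °C) the
unweighted recomputation gives $E_a \approx 23.8$ kcal/mol and the
weighted one $\approx 22.2$; both sit comfortably inside the broad
reported interval, and the package asserts containment rather than
equality because the original weighting scheme is not recoverable.

### Numerical notes

* Dwells shorter than 2 camera frames are excluded (a step cannot be
  resolved within the dead time) and the censored count is logged.
  Exclusion lengthens the sample mean, so $\hat k$ shifts slightly
  *down*; the bias stays under 3% while the frame interval is at most 5%
  of the mean dwell.
* The two-rate convolution density is evaluated through
  `log1p(-exp(-(k_hi-k_lo) t))` and reduces analytically to the Erlang-2
  form when the rates are within $10^{-6}$ of each other, avoiding the
  $k_1 \to k_2$ singularity.
* The step finder works on prefix sums throughout, so one search over a
  20,000-frame trace costs about a second.

## Chemomechanical cycle models

Each step consumes ATP through an ordered chain
Apo → ATP → ADP·Pi → ADP → Apo per hydrolysis site: binding at
$k_{\rm MT}\cdot S$ ($S$ = [ATP] in µM, $k_{\rm MT} = 0.29$ µM$^{-1}$
s$^{-1}$), hydrolysis and ADP release fast (defaults 5,000 s$^{-1}$,
i.e. sub-millisecond; an `instantaneous` flag removes them for exact
Erlang limits), and Pi release at $k_{\rm Pi} = 97.1$ s$^{-1}$. The
`one_ATP` scheme runs the chain once per step; the `two_ATP` scheme runs
it twice sequentially (primary then secondary site). Because a dwell is a
sum of independent exponential waits, its statistics are exact:
mean $\sum 1/k_i$, variance $\sum 1/k_i^2$, and
$n_{\min} = (\sum 1/k_i)^2 / \sum 1/k_i^2$.

Two consequences matter:

* **Michaelis–Menten with Hill coefficient 1.** For the reduced two-ATP
  chain, $v(S) = \bar d/(2/(k_{\rm MT}S) + 2/k_{\rm Pi})$ is *exactly*
  MM with $V_{\max} = \bar d k_{\rm Pi}/2$ and $K = k_{\rm Pi}/k_{\rm MT}$
  — hydrolyzing two ATPs per step does **not** produce a sigmoidal ATP
  dependence when the transitions are sequential and irreversible, so a
  Hill coefficient of 1 cannot rule the two-ATP scheme out.
* **A discriminating prediction.** $n_{\min}(S)$ for the two-ATP scheme
  is 2 at both low and high ATP and peaks at 4 exactly where
  $k_{\rm MT}S = k_{\rm Pi}$, whereas the one-ATP scheme tends to 1 at
  saturating ATP. Measuring $n_{\min}$ versus ATP would separate the
  models cleanly.

```{r cycle-demo}
two <- build_cycle("two_ATP", instantaneous = TRUE)
fit_hill(velocity_vs_atp(two))          # n = 1 although two ATPs are used
nmin_vs_atp(two, c(10, 97.1 / 0.29, 1e5))  # 2 ... 4 ... 2
```

One unit subtlety: the source literature prints the binding constant as
"0.29 µm$^{-1}$ s$^{-1}$", but its own arithmetic (0.29 × 3 mM = 870
s$^{-1}$) fixes the unit as µM$^{-1}$ s$^{-1}$, which is what the package
uses. The exact in vivo values of the fast rates are only bounded
(≤ 1 ms); results quoted here are insensitive to that choice because the
fast transitions contribute under 2% of the dwell mean at the defaults,
and the `instantaneous` flag makes the sensitivity checkable.

## Localization and tracking layer

The imaging model is background-free and shot-noise limited. The
theoretical localization precision is
$\delta x = (\lambda/2\mathrm{NA})/\sqrt{n}$ for $n$ detected photons;
the renderer's default effective Gaussian spot SD is therefore
$\lambda/2\mathrm{NA}$ itself, which makes that formula exact for an
efficient estimator (a `width_factor` knob switches to the FWHM
convention if preferred — the photon-scaling laws, a $\sqrt 5$ precision
ratio between 1,000 and 5,000 photons and a $n^{-1/2}$ log–log slope,
hold under either convention). Spots are localized by fitting a
pixel-integrated 2-D Gaussian by *Poisson maximum likelihood*: plain
least squares on Poisson counts carries a known ~40% excess standard
deviation over the shot-noise bound, which MLE removes at no extra
complexity. The emission wavelength behind published precision numbers is
not stated in the source (the probes emit in more than one band), so
`wavelength` is an explicit parameter (default 605 nm) and only the
photon-scaling ratios are treated as anchored.

Detections are linked by greedy nearest-neighbour association gated at a
maximum jump — adequate for the one-spot-per-channel regime this package
targets; it is not a multi-hypothesis tracker and will not survive dense
fields or long occlusions.

## Motion-state segmentation

Trajectories are projected onto their principal axis (transport in
microchannels is quasi-1-D) and frame displacements are modeled by a
hidden Markov model with Gaussian emissions: state mean $v\Delta t$
(pinned to zero for the diffusive state) and free variance, which absorbs
$2D\Delta t$ plus localization noise rather than modeling the noise with
a Kalman filter. Models with $K = 1..3$ states are fit by EM from
velocity-quantile initializations with multiple restarts, $K$ is chosen
by minimum BIC, and the state path by Viterbi with ties broken toward
the lowest state index. This is a deliberately simplified stand-in for
variational-Bayes HMM model selection: BIC approximates the model
evidence well at these data sizes and keeps the implementation small and
testable. Segments are contiguous runs of one directed state, trimmed by
two frames at each boundary, and gated on the coefficient of variation of
block velocities (default 0.3) — the delimitation convention is ours, as
published analyses rarely state one.

## What the synthetic generator does and does not emulate

The generator reproduces the statistical structure the estimators assume:
Poisson stepping on a lattice step mixture, rigid cargo coupling,
continuous-time Markov switching among diffusive/retrograde/anterograde
states (mean state durations of seconds — "stop-and-go"), i.i.d. Gaussian
localization noise, Erlang dwell laws, and shot-noise-limited spot
images. It does **not** emulate: elastic motor–cargo linkages, load
sharing or tug-of-war force balance, microtubule geometry and obstacles,
heterogeneous vesicle sizes, autofluorescence background, or detector
gain noise. Passing tests therefore demonstrate estimator correctness
under the stated model, not robustness to everything real data can do;
the quantization law in particular assumes near-independent motors, which
compliant in vitro assays support but which stiff coupling would break.

## Problem sizes used in the shipped checks

Test and acceptance runs use 60-s segments at 10-ms frames for the phi
pipeline (around 6,000 frames, averaging over up to 20 replicate
segments), dwell samples of $10^5$ for moment-level checks, 1,000
replicates of the published 22 °C sample size (283 dwells) for the
estimator-spread check, and stepping traces of 100–920 steps for the
step-finder benchmarks. These sizes put Monte-Carlo error comfortably
below the tolerances being asserted while keeping a full run in the order
of a minute.

## Known limitations

* Motor counting assumes the single-motor quantum $\phi_1$ is shared
  across segments; slow modulation of stepping rate or step size between
  cargos would smear the clusters.
* The BIC segmenter considers at most one diffusive plus two directed
  states and folds noise into the emission variance; it will mislabel
  data whose states differ mainly in noise rather than drift.
* The dwell MLE treats censoring by exclusion (with the truncation bias
  quantified, not corrected, at the default settings).
* Cycle models are purely kinetic — no spatial force generation, gating
  of microtubule affinity, or backward stepping.
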