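# cargodyn

Statistical analysis of dynein-driven retrograde cargo transport from
high-rate single-particle tracking, for researchers studying molecular
motors in live cells.

Long, millisecond-resolution trajectories of motor-carried cargo contain
two kinds of information that a velocity trace alone hides: **how many
motors are actively engaged** and **what rate-limits each mechanical
step**. `cargodyn` extracts both.

* **Motor counting.** For a constant-velocity segment, the displacements
  Δx(t, τ) = x(t+τ) − x(t) have mean μ(τ) and variance s²(τ), and the
  statistic **φ(τ) = 2μ/s²** relaxes to an asymptote that is *quantized*:
  a cargo carried by n independent motors (cargo at the mean of the motor
  positions) has φ∞ = n·2d̄/(d̄² + v), an integer multiple of the
  single-motor quantum (0.1 nm⁻¹ at the default calibration d̄ = 8 nm,
  v = 96 nm²) — while the mean velocity λd̄ is independent of n. The
  package computes φ curves, extracts asymptotes with a convergence gate,
  clusters them by k-means, and reads off per-segment motor numbers.
* **Stepping kinetics.** Single steps are detected by iterative
  chi-square staircase fitting with a counter-fit stopping rule; dwell
  times between steps are fit by maximum likelihood on the raw dwells.
  The central dwell law is the convolution of two equal-rate exponentials
  (Erlang-2, P(t) = k²t e^(−kt), mean 2/k, MLE k̂ = 2/mean with Fisher SE
  k̂/√(2n)). The randomness parameter r = (⟨t²⟩−⟨t⟩²)/⟨t⟩² gives
  n_min = 1/r, a lower bound on the number of rate-limiting transitions
  per cycle; Arrhenius analysis of temperature-dependent rates yields the
  activation energy.
* **Cycle models.** One-ATP and sequential two-ATP chemomechanical cycles
  with exact dwell statistics, velocity-vs-ATP curves (exactly
  Michaelis–Menten with Hill n = 1 for the reduced two-ATP chain), and
  the discriminating prediction n_min(S): 2 at low and high ATP, peaking
  at 4 where the ATP on-rate equals the Pi desorption rate.
* **Synthetic data.** A first-class generator for multi-motor cargo
  trajectories (Poisson stepping on a ±{4,8,16,24} nm lattice mixture,
  Markov state switching, Gaussian localization noise), 1-D stepping
  traces, dwell samples, and shot-noise-limited spot images with 2-D
  Gaussian Poisson-MLE localization and gated nearest-neighbour linking —
  every estimator is validated against this ground truth.

## Worked example

```r
library(cargodyn)

# --- how many motors? -------------------------------------------------
tr <- simulate_cargo_trajectory(step_model(),        # 8 nm, 96 nm^2, 150 steps/s
        cargo_config(n_motors = 2, duration = 60, seed = 7))
pp <- phi_pipeline(project_to_axis(tr), noise_sd = 2, dt = 0.01)
pp$asymptote$phi_inf
#> [1] 0.2171871          # ~0.2 nm^-1 = 2 x the single-motor quantum -> 2 motors

# --- what limits each step? ------------------------------------------
d <- simulate_dwells("erlang2", list(k = 97.1), 920, seed = 37)
fit_dwell_mle(d, "erlang2")
#> Dwell fit [erlang2]: k = 98.44 (SE 2.29) /s; n = 920, logLik = 2762, AIC = -5521.4
randomness(d, seed = 1)
#> Randomness r = 0.5039, n_min = 1/r = 1.98 (95% CI 1.8-2.22), n = 920
#                         ^ two rate-limiting transitions per stepping cycle

arrhenius_fit(c(22, 30, 37), c(13.9, 56.1, 97.1))
#> Arrhenius fit (unweighted): Ea = 23.8 kcal/mol (SE 4.7), A = 6.68e+18 /s

# --- is Hill n = 1 evidence against two ATPs per step? No: -----------
fit_hill(velocity_vs_atp(build_cycle("two_ATP", instantaneous = TRUE)))
#> Hill fit: Vmax = 388.4 nm/s, K = 334.8 uM, n = 1 (SE 1.2e-16)
```

Reading the numbers: the two-motor simulation yields φ∞ ≈ 0.2 nm⁻¹,
twice the 0.1 nm⁻¹ single-motor quantum, so the motor count is read off
as 2. The dwell fit recovers the generating rate (97.1 s⁻¹) within its
standard error, and n_min ≈ 2 says at least two sequential transitions
of comparable rate limit each step. The Arrhenius fit of the three
published rates gives an activation energy near 24 kcal/mol. The
sequential two-ATP cycle still yields a perfect Hill coefficient of 1 —
so Michaelis–Menten ATP dependence cannot exclude two hydrolyses per
step; measuring n_min versus ATP (`nmin_vs_atp`) can.

An end-to-end run over all stages (simulation cohort → φ clustering →
step detection → dwell fits → Arrhenius → cycle predictions) is one
call: `run_pipeline(default_config(seed = 1))`, with text/JSON reports
via `render_report()`.

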