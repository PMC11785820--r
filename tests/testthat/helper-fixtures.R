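# Fixture builders shared across test files.

# Bare 2-D trajectory from position vectors (bypasses the simulator).
make_traj <- function(x, y = rep(0, length(x)), dt = 0.01,
                      photons = rep(1000L, length(x)), meta = list()) {
  meta$dt_s <- dt
  cargodyn:::new_trajectory(seq_along(x) - 1L, (seq_along(x) - 1L) * dt,
                            x, y, photons, meta)
}

# Single-transport-state cargo run with the default calibration.
sim_transport <- function(n_motors, seed, duration = 60, sigma = 2,
                          rate = 150) {
  simulate_cargo_trajectory(
    step_model(step_rate = rate),
    cargo_config(n_motors = n_motors, localization_sd = sigma,
                 duration = duration, states = "retrograde", seed = seed))
}

# Closed-form compound-Poisson phi relaxation for n independent motors:
# mu(tau) = lambda*tau*dbar, s2(tau) = lambda*tau*(dbar^2+v)/n + 2*sigma^2.
phi_closed_form <- function(tau, n, dbar = 8, v = 96, lambda = 150,
                            sigma = 2) {
  2 * lambda * tau * dbar / (lambda * tau * (dbar^2 + v) / n + 2 * sigma^2)
}
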