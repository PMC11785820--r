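#' Motor step-size model on the microtubule lattice
#'
#' Defines the per-step displacement distribution of a single motor as a
#' finite mixture over signed multiples of the 4-nm elementary spacing
#' (half the 8-nm tubulin binding-site period, since a single head moving
#' 8 nm advances the motor's center of mass by 4 nm). Given a target mean
#' and variance, mixture probabilities are solved by non-negative least
#' squares on the lattice; infeasible (mean, variance) pairs are rejected.
#'
#' The default calibration (`step_mean = 8` nm, `step_variance = 96` nm^2)
#' makes the single-motor displacement-fluctuation quantum
#' `phi_1 = 2*mean/(mean^2 + variance) = 0.1` per nm.
#'
#' @param step_mean Signed mean step (nm); retrograde is positive.
#' @param step_variance Per-step variance (nm^2).
#' @param step_rate Stepping rate per motor (steps/s); must be >= 0.
#' @param lattice Positive lattice multiples (nm) used for the signed
#'   mixture support.
#' @param prob Optional explicit probabilities over `c(-rev(lattice), lattice)`;
#'   if supplied they must reproduce `step_mean` and `step_variance`.
#' @return An object of class `step_model` with the mixture support,
#'   probabilities and rate.
#' @examples
#' m <- step_model()
#' sum(m$prob * m$support)      # 8 nm
#' phi1 <- 2 * m$step_mean / (m$step_mean^2 + m$step_variance)  # 0.1 nm^-1
#' @export
step_model <- function(step_mean = 8, step_variance = 96, step_rate = 150,
                       lattice = c(4, 8, 16, 24), prob = NULL) {
  stopifnot(step_variance >= 0, step_rate >= 0, all(lattice > 0))
  support <- c(-rev(lattice), lattice)
  m2 <- step_variance + step_mean^2
  if (is.null(prob)) {
    A <- rbind(rep(1, length(support)), support, support^2)
    # scale rows to comparable magnitude so the NNLS residual is balanced
    sc <- c(1, max(abs(support)), max(support^2))
    fit <- pracma::lsqnonneg(A / sc, c(1, step_mean, m2) / sc)
    prob <- fit$x
  }
  if (length(prob) != length(support)) {
    stop("prob must have one entry per signed lattice point")
  }
  if (any(prob < -1e-12) || abs(sum(prob) - 1) > 1e-9) {
    stop("infeasible (step_mean, step_variance) pair on this lattice")
  }
  prob <- pmax(prob, 0)
  prob <- prob / sum(prob)
  mu <- sum(prob * support)
  v <- sum(prob * support^2) - mu^2
  if (abs(mu - step_mean) > 1e-9 || abs(v - step_variance) > 1e-6) {
    stop(sprintf(
      "infeasible (step_mean, step_variance) = (%g, %g): lattice mixture reaches (%g, %g)",
      step_mean, step_variance, mu, v))
  }
  structure(list(step_mean = step_mean, step_variance = step_variance,
                 step_rate = step_rate, support = support, prob = prob),
            class = "step_model")
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("Motor step model: mean %.3g nm, variance %.4g nm^2, rate %.4g steps/s\n",
              x$step_mean, x$step_variance, x$step_rate))
  keep <- x$prob > 1e-12
  cat("  mixture:", paste(sprintf("%g nm (p=%.4g)", x$support[keep], x$prob[keep]),
                          collapse = ", "), "\n")
  invisible(x)
}

draw_steps <- function(model, n) {
  if (n == 0L) return(numeric(0))
  sample(model$support, n, replace = TRUE, prob = model$prob)
}

#' Cargo simulation configuration
#'
#' Parameters of the simulated cargo: number of independently engaged
#' motors (cargo sits at the arithmetic mean of the motor positions, so a
#' single motor step of size d moves the cargo d/n), localization noise,
#' frame interval, motion-state set with a continuous-time Markov
#' switching process, and run duration.
#'
#' @param n_motors Number of engaged motors (1..10).
#' @param localization_sd Gaussian localization noise SD per frame (nm).
#' @param dt Frame interval (s).
#' @param duration Total simulated time (s).
#' @param states Character subset of `c("retrograde","anterograde","diffusive")`.
#' @param D Diffusion coefficient of the diffusive state (nm^2/s).
#' @param switch_rates Square matrix of off-diagonal transition rates (1/s)
#'   among `states` (rows = from); ignored when a single state is given.
#'   Defaults give mean state durations of a few seconds ("stop-and-go").
#' @param temperature Temperature label carried in metadata (deg C).
#' @param photons Mean detected photons per frame.
#' @param seed Optional RNG seed recorded in the output.
#' @return An object of class `cargo_config`.
#' @export
cargo_config <- function(n_motors = 1, localization_sd = 2, dt = 0.01,
                         duration = 60, states = "retrograde",
                         D = 1e4, switch_rates = NULL, temperature = 37,
                         photons = 1000, seed = NULL) {
  stopifnot(n_motors >= 1, n_motors <= 10, dt > 0)
  if (duration <= 0) stop("duration must be positive")
  allowed <- c("retrograde", "anterograde", "diffusive")
  if (length(states) == 0) stop("empty state set")
  if (!all(states %in% allowed)) {
    stop("states must be a subset of: ", paste(allowed, collapse = ", "))
  }
  k <- length(states)
  if (is.null(switch_rates)) {
    switch_rates <- matrix(0.2, k, k)
    diag(switch_rates) <- 0
  }
  switch_rates <- as.matrix(switch_rates)
  if (!all(dim(switch_rates) == c(k, k)) ||
      any(switch_rates[row(switch_rates) != col(switch_rates)] < 0)) {
    stop("switch_rates must be a k x k matrix with nonnegative off-diagonal rates")
  }
  structure(list(n_motors = as.integer(n_motors),
                 localization_sd = localization_sd, dt = dt,
                 duration = duration, states = states, D = D,
                 switch_rates = switch_rates, temperature = temperature,
                 photons = photons, seed = seed),
            class = "cargo_config")
}

# Continuous-time Markov chain state index per frame.
sample_state_path <- function(config, n_frames) {
  k <- length(config$states)
  if (k == 1L) return(rep(1L, n_frames))
  Q <- config$switch_rates
  exit <- rowSums(Q)
  t_now <- 0
  s <- sample.int(k, 1)
  times <- numeric(0); states <- integer(0)
  total <- n_frames * config$dt
  while (t_now < total) {
    times <- c(times, t_now); states <- c(states, s)
    if (exit[s] <= 0) break
    t_now <- t_now + stats::rexp(1, exit[s])
    s <- sample.int(k, 1, prob = Q[s, ] / exit[s])
  }
  idx <- findInterval((seq_len(n_frames) - 1) * config$dt, times)
  states[pmax(idx, 1L)]
}

new_trajectory <- function(frame, t, x, y, photons, meta) {
  structure(data.frame(frame = frame, t_s = t, x_nm = x, y_nm = y,
                       photons = photons),
            metadata = meta, class = c("cargo_trajectory", "data.frame"))
}

#' Metadata of a trajectory
#' @param traj A `cargo_trajectory`.
#' @return The metadata list (frame interval, temperature, seed, ground
#'   truth for synthetic data).
#' @export
trajectory_meta <- function(traj) attr(traj, "metadata")

#' Simulate a multi-motor cargo trajectory
#'
#' Cargo carried by `n` independently stepping motors: during transport
#' states each motor steps as a Poisson process at the model's rate with
#' step sizes drawn from the lattice mixture, and the cargo (arithmetic
#' mean of motor positions) moves by step/n per motor step. The diffusive
#' state is Brownian in both coordinates. Motion states switch as a
#' continuous-time Markov chain sampled at the frame interval. Gaussian
#' localization noise is added independently per frame; the ground-truth
#' state path and noise-free positions are stored in the metadata.
#'
#' @param model A [step_model()].
#' @param config A [cargo_config()].
#' @return A `cargo_trajectory` data frame (`frame`, `t_s`, `x_nm`,
#'   `y_nm`, `photons`) with metadata attribute.
#' @examples
#' tr <- simulate_cargo_trajectory(step_model(), cargo_config(duration = 2, seed = 1))
#' head(tr)
#' @export
simulate_cargo_trajectory <- function(model, config) {
  stopifnot(inherits(model, "step_model"), inherits(config, "cargo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_frames <- floor(config$duration / config$dt)
  if (n_frames < 2) stop("duration too short for the frame interval")
  path <- sample_state_path(config, n_frames)
  state_names <- config$states
  dirn <- c(retrograde = 1, anterograde = -1, diffusive = 0)[state_names]
  n <- config$n_motors
  dx <- numeric(n_frames); dy <- numeric(n_frames)
  for (si in seq_along(state_names)) {
    idx <- which(path == si)
    if (!length(idx)) next
    if (state_names[si] == "diffusive") {
      sd_b <- sqrt(2 * config$D * config$dt)
      dx[idx] <- stats::rnorm(length(idx), 0, sd_b)
      dy[idx] <- stats::rnorm(length(idx), 0, sd_b)
    } else {
      # pooled step count over n motors; cargo moves (sum of steps)/n
      counts <- stats::rpois(length(idx), n * model$step_rate * config$dt)
      tot <- sum(counts)
      if (tot > 0) {
        sizes <- draw_steps(model, tot) * dirn[si]
        frame_of <- rep.int(seq_along(idx), counts)
        sums <- rowsum(sizes, frame_of)
        dx[idx[as.integer(rownames(sums))]] <- sums[, 1] / n
      }
    }
  }
  x_true <- cumsum(dx); y_true <- cumsum(dy)
  sig <- config$localization_sd
  x <- x_true + stats::rnorm(n_frames, 0, sig)
  y <- y_true + stats::rnorm(n_frames, 0, sig)
  ph <- stats::rpois(n_frames, config$photons)
  meta <- list(dt_s = config$dt, temperature_C = config$temperature,
               seed = config$seed, n_motors = n,
               localization_sd = sig,
               truth = list(state = state_names[path], x = x_true, y = y_true))
  new_trajectory(seq_len(n_frames) - 1L, (seq_len(n_frames) - 1L) * config$dt,
                 x, y, ph, meta)
}

#' Simulate a 1-D stepping trace with Erlang-2 dwells
#'
#' Staircase trace for step-detection benchmarks: dwell times between
#' steps are drawn from the convolution of two equal-rate exponentials
#' (density `k^2 t exp(-k t)`, mean `2/k`), plateau jumps from the step
#' model, and the trace is sampled at the camera frame interval with
#' additive Gaussian noise. Ground-truth step times, sizes and levels are
#' stored in the metadata.
#'
#' @param model A [step_model()].
#' @param dwell_rate Rate constant k of each of the two sequential
#'   transitions (1/s); mean dwell is 2/k.
#' @param n_steps Number of steps to generate.
#' @param noise_sd Additive Gaussian noise SD (nm).
#' @param frame_interval Camera frame interval (s).
#' @param seed Optional RNG seed.
#' @return A 1-D `cargo_trajectory` (`y_nm` = 0).
#' @export
simulate_step_trace <- function(model, dwell_rate, n_steps, noise_sd = 2,
                                frame_interval = 0.001, seed = NULL) {
  stopifnot(dwell_rate > 0, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  mean_dwell <- 2 / dwell_rate
  if (frame_interval >= mean_dwell) {
    warning("frame_interval >= mean dwell: steps will be unresolvable")
  }
  dwells <- stats::rgamma(n_steps + 1, shape = 2, rate = dwell_rate)
  step_times <- cumsum(dwells[seq_len(n_steps)])
  sizes <- draw_steps(model, n_steps)
  total <- sum(dwells)
  tt <- seq(0, total, by = frame_interval)
  levels <- c(0, cumsum(sizes))
  x_true <- levels[findInterval(tt, step_times) + 1L]
  x <- x_true + stats::rnorm(length(tt), 0, noise_sd)
  meta <- list(dt_s = frame_interval, temperature_C = NA_real_, seed = seed,
               truth = list(step_times = step_times, step_sizes = sizes,
                            levels = levels, x = x_true))
  new_trajectory(seq_along(tt) - 1L, tt, x, rep(0, length(tt)),
                 rep(0L, length(tt)), meta)
}

#' Container for dwell-time samples
#'
#' @param times Dwell times in seconds, all positive.
#' @param temperature Temperature label (deg C).
#' @param censor_threshold Acquisition dead time below which dwells are
#'   unobservable (s).
#' @return An object of class `dwell_sample`.
#' @export
dwell_sample <- function(times, temperature = NA_real_, censor_threshold = 0) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all dwell times must be finite and positive")
  }
  structure(list(times = times, temperature = temperature,
                 censor_threshold = censor_threshold, n = length(times)),
            class = "dwell_sample")
}

#' @export
print.dwell_sample <- function(x, ...) {
  cat(sprintf("Dwell sample: n = %d, mean %.4g s", x$n, mean(x$times)))
  if (!is.na(x$temperature)) cat(sprintf(" (%g degC)", x$temperature))
  cat("\n")
  invisible(x)
}

#' Simulate dwell times from a kinetic law
#'
#' @param model_id One of `"erlang2"` (two equal sequential rates, density
#'   `k^2 t exp(-kt)`), `"single_exp"`, or `"cycle"` (an explicit
#'   chemomechanical cycle; see [build_cycle()]).
#' @param params For `erlang2`/`single_exp`: list with rate `k` (1/s).
#'   For `cycle`: a `cycle_model`.
#' @param n Number of dwells.
#' @param seed Optional RNG seed.
#' @param temperature Temperature label (deg C).
#' @return A [dwell_sample()].
#' @examples
#' d <- simulate_dwells("erlang2", list(k = 97.1), 1000, seed = 1)
#' mean(d$times)  # ~ 2/97.1 = 20.6 ms
#' @export
simulate_dwells <- function(model_id, params, n, seed = NULL,
                            temperature = NA_real_) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  times <- switch(model_id,
    erlang2 = {
      stopifnot(params$k > 0)
      stats::rgamma(n, shape = 2, rate = params$k)
    },
    single_exp = {
      stopifnot(params$k > 0)
      stats::rexp(n, rate = params$k)
    },
    cycle = sample_cycle_dwells(params, n)$times,
    stop("unknown model_id: ", model_id))
  dwell_sample(times, temperature = temperature)
}
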