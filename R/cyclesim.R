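#' Build a chemomechanical stepping-cycle model
#'
#' Ordered reaction scheme for one motor step. Per hydrolysis site the
#' cycle is Apo -> ATP -> ADP.Pi -> ADP -> Apo, i.e. ATP binding at rate
#' `k_MT * S`, hydrolysis at `k_hyd`, Pi release at `k_Pi`, ADP release
#' at `k_ADP`. The `one_ATP` scheme runs this cycle once per step (only
#' the primary site cycles); the `two_ATP` scheme runs it twice
#' sequentially (primary then secondary site), making the two Pi
#' desorptions the equal rate-limiting transitions at cellular ATP.
#' Hydrolysis and ADP release are fast (sub-millisecond); with
#' `instantaneous = TRUE` they are removed, reducing the chain to its
#' rate-limiting transitions (exact Erlang limits).
#'
#' @param scheme `"two_ATP"` or `"one_ATP"`.
#' @param k_MT ATP binding rate constant (per uM per s).
#' @param S ATP concentration (uM).
#' @param k_Pi Pi release rate (1/s).
#' @param k_hyd Hydrolysis rate (1/s).
#' @param k_ADP ADP release rate (1/s).
#' @param d Step displacement (nm).
#' @param instantaneous Drop the fast transitions.
#' @return Object of class `cycle_model` with the ordered transition
#'   table (`name`, `rate`).
#' @examples
#' m <- build_cycle("two_ATP", S = 3000)
#' m$transitions$rate[1]  # 0.29 * 3000 = 870 /s ATP binding
#' @export
build_cycle <- function(scheme = c("two_ATP", "one_ATP"), k_MT = 0.29,
                        S = 3000, k_Pi = 97.1, k_hyd = 5000, k_ADP = 5000,
                        d = 8, instantaneous = FALSE) {
  scheme <- match.arg(scheme)
  rates <- c(k_MT, S, k_Pi, k_hyd, k_ADP)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates and the ATP concentration must be positive")
  }
  site_block <- function(site) {
    tr <- data.frame(
      name = paste0(c("ATP_binding_", "hydrolysis_", "Pi_release_",
                      "ADP_release_"), site),
      rate = c(k_MT * S, k_hyd, k_Pi, k_ADP))
    if (instantaneous) tr[c(1, 3), ] else tr
  }
  transitions <- if (scheme == "one_ATP") site_block("AAA1") else
    rbind(site_block("AAA1"), site_block("AAA3"))
  rownames(transitions) <- NULL
  structure(list(scheme = scheme, transitions = transitions,
                 k_MT = k_MT, S = S, k_Pi = k_Pi, k_hyd = k_hyd,
                 k_ADP = k_ADP, d = d, instantaneous = instantaneous),
            class = "cycle_model")
}

#' @export
print.cycle_model <- function(x, ...) {
  cat(sprintf("%s stepping cycle at [ATP] = %g uM (d = %g nm%s)\n",
              x$scheme, x$S, x$d,
              if (x$instantaneous) ", fast steps instantaneous" else ""))
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Exact dwell statistics of a sequential cycle
#'
#' For a dwell that is the sum of independent exponential waiting times
#' with rates k_i: mean = sum(1/k_i), variance = sum(1/k_i^2),
#' randomness r = variance/mean^2, and n_min = 1/r.
#'
#' @param model A [build_cycle()] model.
#' @return List: `mean`, `variance`, `r`, `n_min`.
#' @export
closed_form_dwell_stats <- function(model) {
  k <- model$transitions$rate
  m <- sum(1 / k); v <- sum(1 / k^2)
  r <- v / m^2
  list(mean = m, variance = v, r = r, n_min = 1 / r)
}

#' Sample dwell times from a cycle model
#'
#' Each dwell is the sum of the exponential waiting times of the ordered
#' transitions (direct sampling; equivalent to a Gillespie simulation of
#' a linear chain).
#'
#' @param model A [build_cycle()] model.
#' @param n Number of dwells.
#' @param seed Optional RNG seed.
#' @return A [dwell_sample()].
#' @export
sample_cycle_dwells <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- model$transitions$rate
  t <- rowSums(vapply(k, function(ki) stats::rexp(n, ki), numeric(n)))
  dwell_sample(t)
}

rebuild_at_S <- function(model, S) {
  build_cycle(model$scheme, k_MT = model$k_MT, S = S, k_Pi = model$k_Pi,
              k_hyd = model$k_hyd, k_ADP = model$k_ADP, d = model$d,
              instantaneous = model$instantaneous)
}

#' Velocity and n_min versus ATP concentration
#'
#' Per grid point, the mean dwell of the cycle at that ATP concentration
#' gives the velocity `v(S) = d / mean_dwell(S)` and the kinetic bound
#' `n_min(S)` from the closed-form dwell statistics. For the two-ATP
#' scheme with fast steps instantaneous,
#' `v(S) = d / (2/(k_MT S) + 2/k_Pi)` -- exactly Michaelis-Menten with
#' `Vmax = d k_Pi / 2` and `K = k_Pi / k_MT`.
#'
#' @param model A [build_cycle()] model.
#' @param S_grid ATP concentrations (uM), >= 8 points spanning >= 3
#'   decades recommended for Hill fitting.
#' @return Data frame of class `atp_response`: `S_uM`, `mean_dwell_s`,
#'   `v_nm_s`, `n_min`.
#' @export
velocity_vs_atp <- function(model, S_grid = 10^seq(0, 4, length.out = 25)) {
  stopifnot(all(S_grid > 0))
  rows <- lapply(S_grid, function(S) {
    st <- closed_form_dwell_stats(rebuild_at_S(model, S))
    data.frame(S_uM = S, mean_dwell_s = st$mean, v_nm_s = model$d / st$mean,
               n_min = st$n_min)
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  class(out) <- c("atp_response", "data.frame")
  out
}

#' n_min as a function of ATP concentration
#'
#' The discriminating prediction between the cycle schemes: for the
#' two-ATP scheme with fast steps instantaneous, n_min is 2 at both low
#' and high ATP and peaks at 4 where the ATP on-rate equals the Pi
#' desorption rate; for the one-ATP scheme the high-ATP limit is 1.
#'
#' @param model A [build_cycle()] model.
#' @param S_grid ATP concentrations (uM).
#' @return Data frame `S_uM`, `n_min`.
#' @export
nmin_vs_atp <- function(model, S_grid = 10^seq(0, 4, length.out = 25)) {
  data.frame(S_uM = S_grid,
             n_min = vapply(S_grid, function(S)
               closed_form_dwell_stats(rebuild_at_S(model, S))$n_min, 0))
}

#' Fit the Hill equation to a velocity-vs-ATP curve
#'
#' Least squares of `v = Vmax * S^n / (K^n + S^n)`, initialized at
#' `Vmax = max(v)`, `K = S` at half-max, `n = 1`. A Hill coefficient of 1
#' indicates Michaelis-Menten behaviour, which sequential cycles with
#' irreversible transitions satisfy even when two ATPs are hydrolyzed
#' per step.
#'
#' @param response An [velocity_vs_atp()] result (or data frame with
#'   `S_uM`, `v_nm_s`), >= 8 points.
#' @return Object of class `hill_fit`: `Vmax`, `K`, `n_hill`, `se_n`,
#'   and the `nls` fit.
#' @export
fit_hill <- function(response) {
  S <- response$S_uM; v <- response$v_nm_s
  if (length(S) < 8) stop("need at least 8 grid points")
  if (stats::sd(v) < 1e-12 * abs(mean(v))) {
    stop("degenerate response: velocity is constant, Hill fit rejected")
  }
  K0 <- S[which.min(abs(v - max(v) / 2))]
  fit <- minpack.lm::nlsLM(v ~ Vmax * S^n / (K^n + S^n),
                           start = list(Vmax = max(v), K = K0, n = 1),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["n", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(Vmax = unname(cf["Vmax"]), K = unname(cf["K"]),
                 n_hill = unname(cf["n"]), se_n = se, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Vmax = %.4g nm/s, K = %.4g uM, n = %.4g",
              x$Vmax, x$K, x$n_hill))
  if (is.finite(x$se_n)) cat(sprintf(" (SE %.2g)", x$se_n))
  cat("\n")
  invisible(x)
}
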