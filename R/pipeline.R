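# Polynomial rolling hash (mod 2^31 - 1) of a deparsed object;
# provenance stamp for run reports.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' A complete demo configuration: a cohort of 1-3-motor transport
#' segments for the displacement-fluctuation (phi) arm, stepping traces
#' at three temperatures for the dwell-kinetics arm, and a two-ATP cycle
#' for the model arm. All stochastic stages carry explicit seeds derived
#' from `seed`.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested configuration list (class `run_config`), serializable
#'   to YAML via [write_config()].
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    stages = c("phi", "steps", "arrhenius", "cycle"),
    simulate = list(
      n_motors = c(1, 2, 3), reps = 4,
      step_mean = 8, step_variance = 96, step_rate = 150,
      localization_sd = 2, dt = 0.01, duration = 60),
    tau_grid = seq(0.01, 0.2, by = 0.01),
    asymptote = list(tau_min = 0.12, flatness_tol = 0.1),
    steps = list(
      temperatures = c(22, 30, 37),
      k = c(13.9, 56.1, 97.1),
      n_steps = c(283, 278, 920),
      frame_interval = c(0.0025, 0.0025, 0.001),
      noise_sd = 2),
    cycle = list(scheme = "two_ATP", k_MT = 0.29, S = 3000, k_Pi = 97.1,
                 k_hyd = 5000, k_ADP = 5000, d = 8,
                 S_grid = 10^seq(0, 4, length.out = 25))
  ), class = c("run_config", "list"))
}

#' Write / read a pipeline configuration (YAML)
#' @param config A configuration list.
#' @param path File path.
#' @return `path` invisibly; [read_config()] returns the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$tau_grid <- as.numeric(cfg$tau_grid)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the selected stages on synthetic data (or, for the phi arm,
#' on trajectories supplied in `config$input_paths`):
#' * `phi`: simulate/ingest cargo trajectories, extract displacement
#'   statistics, phi curves and asymptotes, cluster the converged
#'   asymptotes and summarize motor numbers;
#' * `steps`: per temperature, simulate a stepping trace, detect steps,
#'   extract dwells, fit the equal-rate two-exponential model by MLE and
#'   compute the randomness parameter;
#' * `arrhenius`: Arrhenius fit over the per-temperature rates;
#' * `cycle`: closed-form dwell statistics, velocity-vs-ATP with Hill
#'   fit, and n_min-vs-ATP for the configured cycle scheme.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_config()].
#' @return Object of class `run_report` with per-stage results and
#'   provenance (`config_hash`, seeds, package version).
#' @export
run_pipeline <- function(config = default_config()) {
  stages <- config$stages
  report <- list(provenance = list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cargodyn")),
    stages = stages))
  if ("phi" %in% stages) {
    report$phi <- tryCatch(stage_phi(config), error = function(e)
      stop("stage phi failed: ", conditionMessage(e)))
  }
  if ("steps" %in% stages) {
    report$steps <- tryCatch(stage_steps(config), error = function(e)
      stop("stage steps failed: ", conditionMessage(e)))
  }
  if ("arrhenius" %in% stages) {
    if (is.null(report$steps)) stop("stage arrhenius requires stage steps")
    report$arrhenius <- tryCatch(stage_arrhenius(report$steps),
                                 error = function(e)
      stop("stage arrhenius failed: ", conditionMessage(e)))
  }
  if ("cycle" %in% stages) {
    report$cycle <- tryCatch(stage_cycle(config), error = function(e)
      stop("stage cycle failed: ", conditionMessage(e)))
  }
  class(report) <- "run_report"
  report
}

stage_phi <- function(config) {
  sim <- config$simulate
  model <- step_model(sim$step_mean, sim$step_variance, sim$step_rate)
  rows <- list(); phi_vals <- c(); seg_n <- c(); velocities <- c()
  n_nonconv <- 0L
  sub <- 0L
  for (n in sim$n_motors) for (r in seq_len(sim$reps)) {
    sub <- sub + 1L
    cfg <- cargo_config(n_motors = n, localization_sd = sim$localization_sd,
                        dt = sim$dt, duration = sim$duration,
                        states = "retrograde",
                        seed = (config$seed * 1000L + sub) %% 2147483647L)
    tr <- simulate_cargo_trajectory(model, cfg)
    x <- project_to_axis(tr)
    pp <- phi_pipeline(x, tau_grid = config$tau_grid,
                       noise_sd = sim$localization_sd,
                       tau_min = config$asymptote$tau_min,
                       flatness_tol = config$asymptote$flatness_tol,
                       dt = sim$dt)
    v <- (x[length(x)] - x[1]) / (sim$duration)
    if (pp$asymptote$converged) {
      phi_vals <- c(phi_vals, pp$asymptote$phi_inf)
      seg_n <- c(seg_n, n)
      velocities <- c(velocities, v)
    } else n_nonconv <- n_nonconv + 1L
    rows[[sub]] <- data.frame(n_motors = n, rep = r,
                              phi_inf = pp$asymptote$phi_inf,
                              converged = pp$asymptote$converged,
                              v_nm_s = v)
  }
  summary <- motor_count_summary(phi_vals, seed = config$seed)
  list(segments = do.call(rbind, rows), n_nonconverged = n_nonconv,
       summary = summary, true_n = seg_n, velocities = velocities)
}

stage_steps <- function(config) {
  sc <- config$steps
  model <- step_model(config$simulate$step_mean, config$simulate$step_variance,
                      config$simulate$step_rate)
  out <- list()
  for (i in seq_along(sc$temperatures)) {
    tr <- simulate_step_trace(model, dwell_rate = sc$k[i],
                              n_steps = sc$n_steps[i],
                              noise_sd = sc$noise_sd,
                              frame_interval = sc$frame_interval[i],
                              seed = (config$seed * 100L + i) %% 2147483647L)
    fit <- find_steps(tr)
    dw <- dwell_times(fit, sc$frame_interval[i])
    mle <- fit_dwell_mle(dw, "erlang2")
    rnd <- randomness(dw, seed = config$seed + i)
    out[[i]] <- list(temperature_C = sc$temperatures[i],
                     k_true = sc$k[i], n_steps_found = fit$n_steps,
                     n_dwells = dw$n, n_censored = attr(dw, "n_censored"),
                     k_hat = mle$k, se_k = mle$se,
                     r = rnd$r, n_min = rnd$n_min,
                     mean_dwell_s = mean(dw$times),
                     step_sizes = fit$step_sizes)
  }
  out
}

stage_arrhenius <- function(steps_result) {
  temps <- vapply(steps_result, function(s) s$temperature_C, 0)
  ks <- vapply(steps_result, function(s) s$k_hat, 0)
  ses <- vapply(steps_result, function(s) s$se_k, 0)
  arrhenius_fit(temps, ks, se = ses)
}

stage_cycle <- function(config) {
  cc <- config$cycle
  model <- build_cycle(cc$scheme, k_MT = cc$k_MT, S = cc$S, k_Pi = cc$k_Pi,
                       k_hyd = cc$k_hyd, k_ADP = cc$k_ADP, d = cc$d)
  resp <- velocity_vs_atp(model, as.numeric(cc$S_grid))
  list(model = model, closed_form = closed_form_dwell_stats(model),
       response = resp, hill = fit_hill(resp),
       nmin_curve = nmin_vs_atp(model, as.numeric(cc$S_grid)))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run", x$provenance$config_hash, "(seed", x$provenance$seed, ")\n")
  if (!is.null(x$phi)) {
    cat(sprintf("phi arm: %d converged / %d non-converged segments\n",
                length(x$phi$summary$n), x$phi$n_nonconverged))
    print(x$phi$summary)
  }
  if (!is.null(x$steps)) {
    for (s in x$steps) {
      cat(sprintf("steps %g degC: k_hat = %.3g +/- %.2g /s (true %.3g), n_min = %.3g, %d dwells\n",
                  s$temperature_C, s$k_hat, s$se_k, s$k_true, s$n_min, s$n_dwells))
    }
  }
  if (!is.null(x$arrhenius)) print(x$arrhenius)
  if (!is.null(x$cycle)) {
    cat(sprintf("cycle [%s]: mean dwell %.4g s, n_min %.3g; ",
                x$cycle$model$scheme, x$cycle$closed_form$mean,
                x$cycle$closed_form$n_min))
    print(x$cycle$hill)
  }
  invisible(x)
}

#' Render a run report to a file
#'
#' `format = "text"` writes a human-readable summary with units;
#' `format = "structured"` writes JSON that [read_report()] parses back.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output file path.
#' @param format `"text"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("text", "structured")) {
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    lines <- c(sprintf("pipeline run %s (seed %s, cargodyn %s)",
                       report$provenance$config_hash, report$provenance$seed,
                       report$provenance$package_version))
    if (!is.null(report$phi)) {
      s <- report$phi$summary
      lines <- c(lines,
        sprintf("phi quantum: %.4g nm^-1", s$quantum),
        sprintf("phi cluster centers [nm^-1]: %s",
                paste(signif(s$centers, 4), collapse = ", ")),
        sprintf("mean motor number: %.3f +/- %.3f (SE), %d segments",
                s$mean_n, s$se_n, length(s$n)),
        sprintf("non-converged phi segments (no asymptote reported): %d",
                report$phi$n_nonconverged))
    }
    if (!is.null(report$steps)) {
      for (s in report$steps) {
        lines <- c(lines, sprintf(
          "dwell fit at %g degC: k = %.4g +/- %.3g s^-1, mean dwell %.4g s, n_min = %.3g (%d dwells, %d censored)",
          s$temperature_C, s$k_hat, s$se_k, s$mean_dwell_s, s$n_min,
          s$n_dwells, s$n_censored))
      }
    }
    if (!is.null(report$arrhenius)) {
      lines <- c(lines, sprintf("activation energy: %.3g kcal mol^-1 (prefactor %.3g s^-1)",
                                report$arrhenius$Ea_kcal_mol,
                                report$arrhenius$prefactor))
    }
    if (!is.null(report$cycle)) {
      lines <- c(lines, sprintf(
        "cycle %s: mean dwell %.4g s, n_min %.3g, Hill n = %.3g, Vmax = %.4g nm s^-1, K = %.4g uM",
        report$cycle$model$scheme, report$cycle$closed_form$mean,
        report$cycle$closed_form$n_min, report$cycle$hill$n_hill,
        report$cycle$hill$Vmax, report$cycle$hill$K))
    }
    writeLines(lines, con)
  } else {
    slim <- report_to_list(report)
    jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

report_to_list <- function(report) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$phi)) {
    s <- report$phi$summary
    out$phi <- list(quantum_inv_nm = s$quantum, centers_inv_nm = s$centers,
                    mean_n = s$mean_n, se_n = s$se_n, n_per_segment = s$n,
                    n_nonconverged = report$phi$n_nonconverged)
  }
  if (!is.null(report$steps)) {
    out$steps <- lapply(report$steps, function(s)
      s[c("temperature_C", "k_true", "k_hat", "se_k", "r", "n_min",
          "n_dwells", "n_censored", "mean_dwell_s")])
  }
  if (!is.null(report$arrhenius)) {
    out$arrhenius <- list(Ea_kcal_mol = report$arrhenius$Ea_kcal_mol,
                          prefactor_s = report$arrhenius$prefactor)
  }
  if (!is.null(report$cycle)) {
    out$cycle <- list(scheme = report$cycle$model$scheme,
                      mean_dwell_s = report$cycle$closed_form$mean,
                      n_min = report$cycle$closed_form$n_min,
                      hill_n = report$cycle$hill$n_hill,
                      Vmax_nm_s = report$cycle$hill$Vmax,
                      K_uM = report$cycle$hill$K)
  }
  out
}

#' @rdname render_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
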