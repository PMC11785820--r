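# ---- chi-square staircase step finding ---------------------------------

# Best single split of x[a:b] into two plateaus; returns the split index
# (last index of the left plateau) and the SSE reduction. Prefix-sum based.
best_split <- function(x, a, b) {
  m <- b - a + 1L
  if (m < 2L) return(c(NA, 0))
  seg <- x[a:b]
  cs <- cumsum(seg); tot <- cs[m]
  i <- seq_len(m - 1L)
  # SSE reduction of splitting after position i (within-segment index)
  red <- cs[i]^2 / i + (tot - cs[i])^2 / (m - i) - tot^2 / m
  j <- which.max(red)
  c(a + j - 1L, red[j])
}

# SSE of a plateau partition from prefix sums: S1 = c(0, cumsum(x)),
# S2 = c(0, cumsum(x^2)); bounds = sorted plateau start indices (first = 1).
sse_of_plateaus <- function(S1, S2, bounds, n) {
  a <- bounds
  b <- c(bounds[-1] - 1L, n)
  len <- b - a + 1L
  s1 <- S1[b + 1L] - S1[a]
  s2 <- S2[b + 1L] - S2[a]
  sum(s2 - s1^2 / len)
}

#' Detect steps by iterative chi-square staircase fitting
#'
#' Kerssemakers-style step finder: starting from a single plateau,
#' repeatedly place the step that maximally reduces the residual
#' sum of squares. The number of steps is chosen where the counter-fit
#' quality ratio peaks: for each candidate staircase a counter-fit with
#' steps at the midpoints of its plateaus is evaluated, and the ratio
#' chi^2(counter)/chi^2(fit) is largest when the fit captures real steps
#' rather than noise. Finally, adjacent plateaus whose level difference
#' is below `min_step` are merged (sub-noise steps excluded).
#'
#' @param trace A 1-D `cargo_trajectory` or numeric position vector (nm).
#' @param max_steps Cap on the number of fitted steps (default `n/5`).
#' @param min_step Smallest retained step size (nm); 4 nm is the
#'   elementary lattice spacing and the experimental noise floor.
#' @return Object of class `step_fit`: plateau `bounds` (start indices),
#'   `levels` (nm), `step_sizes` (nm, signed), `step_frames` (index of
#'   the first frame of each new plateau), `residual_sd`, `quality`.
#' @export
find_steps <- function(trace, max_steps = NULL, min_step = 4) {
  x <- if (inherits(trace, "data.frame")) trace$x_nm else as.numeric(trace)
  n <- length(x)
  if (n < 20) stop("need at least 20 frames")
  if (is.null(max_steps)) max_steps <- max(1L, n %/% 5L)
  sse0 <- sum((x - mean(x))^2)
  if (sse0 < .Machine$double.eps * n) {
    return(new_step_fit(x, bounds = 1L, quality = NA_real_,
                        frame_times = step_trace_times(trace, n)))
  }
  S1 <- c(0, cumsum(x)); S2 <- c(0, cumsum(x^2))
  bounds <- 1L
  # per-plateau best splits, keyed by plateau start
  cand <- list(); cand[["1"]] <- best_split(x, 1L, n)
  sse <- sse0
  hist_bounds <- list(bounds)
  hist_quality <- numeric(0)
  for (s in seq_len(max_steps)) {
    reds <- vapply(cand, function(z) z[2], 0)
    if (!length(reds) || max(reds, na.rm = TRUE) <= 1e-12) break
    key <- names(which.max(reds))
    split_at <- cand[[key]][1]
    a <- as.integer(key)
    ends <- c(bounds[-1] - 1L, n)
    b <- ends[match(a, bounds)]
    newb <- as.integer(split_at + 1L)
    bounds <- sort(c(bounds, newb))
    sse <- sse - cand[[key]][2]
    cand[[key]] <- best_split(x, a, split_at)
    cand[[as.character(newb)]] <- best_split(x, newb, b)
    # counter-fit: steps at plateau midpoints
    ends2 <- c(bounds[-1] - 1L, n)
    mids <- unique(pmin(pmax(floor((bounds + ends2) / 2) + 1L, 2L), n))
    cbounds <- sort(unique(c(1L, mids)))
    sse_counter <- sse_of_plateaus(S1, S2, cbounds, n)
    hist_quality <- c(hist_quality, sse_counter / max(sse, 1e-300))
    hist_bounds <- c(hist_bounds, list(bounds))
    # stop once the quality ratio has clearly peaked (the curve can dip
    # locally before all true steps are placed, so the margin is generous)
    peak <- which.max(hist_quality)
    if (s > max(100L, 2L * peak)) break
  }
  if (!length(hist_quality)) {
    return(new_step_fit(x, bounds = 1L, quality = NA_real_,
                        frame_times = step_trace_times(trace, n)))
  }
  best_s <- which.max(hist_quality)
  bounds <- hist_bounds[[best_s + 1L]]
  # merge sub-threshold steps, smallest first
  repeat {
    if (length(bounds) == 1L) break
    ends <- c(bounds[-1] - 1L, n)
    lev <- vapply(seq_along(bounds),
                  function(i) mean(x[bounds[i]:ends[i]]), 0)
    d <- abs(diff(lev))
    if (!length(d) || min(d) >= min_step) break
    j <- which.min(d)
    bounds <- bounds[-(j + 1L)]
  }
  new_step_fit(x, bounds, quality = hist_quality[best_s],
               frame_times = step_trace_times(trace, n))
}

step_trace_times <- function(trace, n) {
  if (inherits(trace, "data.frame") && !is.null(trace$t_s)) trace$t_s
  else seq_len(n) - 1
}

new_step_fit <- function(x, bounds, quality, frame_times) {
  n <- length(x)
  ends <- c(bounds[-1] - 1L, n)
  levels <- vapply(seq_along(bounds), function(i) mean(x[bounds[i]:ends[i]]), 0)
  resid <- x
  for (i in seq_along(bounds)) resid[bounds[i]:ends[i]] <- resid[bounds[i]:ends[i]] - levels[i]
  structure(list(bounds = bounds, ends = ends, levels = levels,
                 step_sizes = diff(levels), step_frames = bounds[-1],
                 step_times = frame_times[bounds[-1]],
                 n_steps = length(bounds) - 1L,
                 residual_sd = stats::sd(resid), quality = quality),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Staircase fit: %d steps, residual SD %.3g nm", x$n_steps,
              x$residual_sd))
  if (is.finite(x$quality)) cat(sprintf(", counter-fit quality %.3g", x$quality))
  cat("\n")
  if (x$n_steps > 0) {
    cat("  step sizes (nm):", paste(signif(x$step_sizes, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fitted staircase as a position vector
#' @param fit A `step_fit`.
#' @return Numeric vector: the plateau level at each frame.
#' @export
staircase_of <- function(fit) {
  rep(fit$levels, fit$ends - fit$bounds + 1L)
}

#' Dwell times between detected steps
#'
#' Inter-step intervals in seconds. Dwells shorter than the censoring
#' threshold (2 frames: a step cannot be resolved within the camera
#' dead time) are excluded; the excluded count is recorded.
#'
#' @param fit A [find_steps()] result.
#' @param frame_interval Frame interval (s).
#' @return A [dwell_sample()] with `censor_threshold = 2 * frame_interval`
#'   and attribute `n_censored`.
#' @export
dwell_times <- function(fit, frame_interval) {
  if (fit$n_steps < 2) stop("need at least 2 steps for dwell times")
  dw <- diff(fit$step_frames) * frame_interval
  thr <- 2 * frame_interval
  keep <- dw >= thr
  out <- dwell_sample(dw[keep], censor_threshold = thr)
  attr(out, "n_censored") <- sum(!keep)
  out
}

# ---- dwell-time maximum likelihood -------------------------------------

# hypoexponential (two distinct rates) log-likelihood, stable near k1 = k2
dhypoexp2_ll <- function(t, k1, k2) {
  kb <- (k1 + k2) / 2
  if (abs(k1 - k2) < 1e-6 * kb) {
    sum(2 * log(kb) + log(t) - kb * t)
  } else {
    klo <- min(k1, k2); khi <- max(k1, k2)
    sum(log(k1) + log(k2) - log(khi - klo) - klo * t +
          log1p(-exp(-(khi - klo) * t)))
  }
}

#' Maximum-likelihood fit of a dwell-time model
#'
#' Fits raw (unbinned) dwell times. Models:
#' * `erlang2`: two equal sequential rates, density `k^2 t exp(-kt)`;
#'   closed-form MLE `k = 2/mean(t)` with Fisher SE `k/sqrt(2n)`.
#' * `single_exp`: `k = 1/mean(t)`, SE `k/sqrt(n)`.
#' * `gamma`: two-parameter numerical MLE (shape, rate).
#' * `two_rate`: unconstrained convolution of two exponentials with
#'   distinct rates (reduces to `erlang2` when the rates coincide).
#'
#' A binned-histogram least-squares mode is available via
#' [fit_dwell_histogram()] for comparison only; raw-dwell MLE is the
#' primary route because prebinned fitting depends on the bin choice.
#'
#' @param dwells A [dwell_sample()] or numeric vector (s).
#' @param model One of `"erlang2"`, `"single_exp"`, `"gamma"`, `"two_rate"`.
#' @param min_n Minimum number of dwells.
#' @return Object of class `dwell_fit`: `model`, `k` (and `shape` or `k2`
#'   where relevant), `se`, `loglik`, `aic`, `n`.
#' @export
fit_dwell_mle <- function(dwells, model = c("erlang2", "single_exp", "gamma",
                                            "two_rate"), min_n = 30) {
  model <- match.arg(model)
  t <- if (inherits(dwells, "dwell_sample")) dwells$times else as.numeric(dwells)
  if (any(t <= 0)) stop("non-positive dwells rejected")
  n <- length(t)
  if (n < min_n) stop("need at least ", min_n, " dwells")
  mt <- mean(t)
  out <- switch(model,
    erlang2 = {
      k <- 2 / mt
      ll <- sum(2 * log(k) + log(t) - k * t)
      list(k = k, se = k / sqrt(2 * n), loglik = ll, n_par = 1L)
    },
    single_exp = {
      k <- 1 / mt
      ll <- sum(log(k) - k * t)
      list(k = k, se = k / sqrt(n), loglik = ll, n_par = 1L)
    },
    gamma = {
      nll <- function(p) -sum(stats::dgamma(t, shape = exp(p[1]),
                                            rate = exp(p[2]), log = TRUE))
      p0 <- c(log(mt^2 / stats::var(t)), log(mt / stats::var(t)))
      opt <- stats::optim(p0, nll, method = "BFGS", hessian = TRUE)
      sh <- exp(opt$par[1]); k <- exp(opt$par[2])
      # delta method on log scale
      vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
      list(k = k, shape = sh, se = k * sqrt(vc[2, 2]),
           se_shape = sh * sqrt(vc[1, 1]), loglik = -opt$value, n_par = 2L)
    },
    two_rate = {
      # parametrize k1 = k e^-d, k2 = k e^d
      nll <- function(p) -dhypoexp2_ll(t, exp(p[1] - abs(p[2])),
                                       exp(p[1] + abs(p[2])))
      opt <- stats::optim(c(log(2 / mt), 0.05), nll, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 5000))
      k1 <- exp(opt$par[1] - abs(opt$par[2]))
      k2 <- exp(opt$par[1] + abs(opt$par[2]))
      list(k = k1, k2 = k2, se = NA_real_, loglik = -opt$value, n_par = 2L)
    })
  structure(c(out, list(model = model, n = n,
                        aic = 2 * out$n_par - 2 * out$loglik)),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Dwell fit [%s]: k = %.4g", x$model, x$k))
  if (!is.null(x$k2)) cat(sprintf(", k2 = %.4g", x$k2))
  if (!is.null(x$shape)) cat(sprintf(", shape = %.3g", x$shape))
  if (is.finite(x$se)) cat(sprintf(" (SE %.3g)", x$se))
  cat(sprintf(" /s; n = %d, logLik = %.4g, AIC = %.5g\n", x$n, x$loglik, x$aic))
  invisible(x)
}

#' Histogram least-squares dwell fit (comparison mode)
#'
#' Least-squares fit of the Erlang-2 density to a binned dwell histogram.
#' Provided only to compare against the raw-dwell MLE; the result
#' depends on the bin width, which is why MLE is the default.
#'
#' @param dwells Dwell sample or numeric vector (s).
#' @param bins Number of bins.
#' @return List with `k`.
#' @export
fit_dwell_histogram <- function(dwells, bins = 30) {
  t <- if (inherits(dwells, "dwell_sample")) dwells$times else as.numeric(dwells)
  h <- graphics::hist(t, breaks = bins, plot = FALSE)
  xm <- h$mids; y <- h$density
  fit <- minpack.lm::nlsLM(y ~ k^2 * xm * exp(-k * xm),
                           start = list(k = 2 / mean(t)))
  list(k = unname(stats::coef(fit)["k"]))
}

#' Compare dwell-time models by AIC
#'
#' Fits the candidate models to the same raw dwells and ranks them by
#' AIC. The gamma shape estimate is reported as a diagnostic: a shape
#' near 2 supports two equal sequential rate-limiting transitions.
#'
#' @param dwells Dwell sample or numeric vector (s), n >= 100.
#' @param models Models to compare.
#' @return Data frame sorted by AIC with attribute `fits` (the full fit
#'   objects, named).
#' @export
compare_dwell_models <- function(dwells,
                                 models = c("single_exp", "erlang2", "gamma")) {
  t <- if (inherits(dwells, "dwell_sample")) dwells$times else as.numeric(dwells)
  if (length(t) < 100) stop("need at least 100 dwells for model comparison")
  fits <- lapply(models, function(m) fit_dwell_mle(t, m))
  names(fits) <- models
  tab <- data.frame(model = models,
                    k = vapply(fits, function(f) f$k, 0),
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    aic = vapply(fits, function(f) f$aic, 0))
  if ("gamma" %in% models) tab$shape <- ifelse(tab$model == "gamma",
                                               fits[["gamma"]]$shape, NA)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Randomness parameter and minimum number of kinetic steps
#'
#' The randomness parameter `r = (<t^2> - <t>^2) / <t>^2` of a dwell-time
#' distribution; its inverse `n_min = 1/r` lower-bounds the number of
#' rate-limiting transitions per cycle (r = 1/m for an Erlang-m law).
#' A percentile bootstrap CI is attached.
#'
#' @param dwells Dwell sample or numeric vector, n >= 100.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional RNG seed for the bootstrap.
#' @return Object of class `randomness_result`: `r`, `n_min`, `ci_r`,
#'   `ci_n_min`, `n`.
#' @export
randomness <- function(dwells, n_boot = 1000, conf = 0.95, seed = NULL) {
  t <- if (inherits(dwells, "dwell_sample")) dwells$times else as.numeric(dwells)
  if (length(t) < 100) stop("need at least 100 dwells")
  if (mean(t) <= 0) stop("zero mean dwell")
  if (!is.null(seed)) set.seed(seed)
  r_of <- function(z) (mean(z^2) - mean(z)^2) / mean(z)^2
  r <- r_of(t)
  rb <- replicate(n_boot, r_of(sample(t, replace = TRUE)))
  a <- (1 - conf) / 2
  ci_r <- stats::quantile(rb, c(a, 1 - a), names = FALSE)
  structure(list(r = r, n_min = 1 / r, ci_r = ci_r,
                 ci_n_min = rev(1 / ci_r), n = length(t)),
            class = "randomness_result")
}

#' @export
print.randomness_result <- function(x, ...) {
  cat(sprintf("Randomness r = %.4g, n_min = 1/r = %.3g (95%% CI %.3g-%.3g), n = %d\n",
              x$r, x$n_min, x$ci_n_min[1], x$ci_n_min[2], x$n))
  invisible(x)
}

#' Arrhenius analysis of temperature-dependent rates
#'
#' Least squares of `ln k` on `1/T` (T in kelvin, T = degC + 273.15);
#' the activation energy is `Ea = -slope * R` with
#' `R = 1.987e-3 kcal mol^-1 K^-1`, and the prefactor `A = exp(intercept)`.
#' The default is unweighted; `weighted = TRUE` weights by `1/SE(ln k)^2`.
#'
#' @param temperature_C Temperatures (deg C), all distinct, >= 2.
#' @param k Rate constants (1/s).
#' @param se Optional SEs of `k` (needed for the weighted mode).
#' @param weighted Use SE weighting.
#' @return Object of class `arrhenius_result`: `Ea_kcal_mol`, `se_Ea`,
#'   `prefactor`, the (T, k) table and the `lm` fit.
#' @export
arrhenius_fit <- function(temperature_C, k, se = NULL, weighted = FALSE) {
  if (length(temperature_C) < 2) stop("need at least 2 temperatures")
  if (anyDuplicated(temperature_C)) stop("duplicate temperatures")
  stopifnot(length(k) == length(temperature_C), all(k > 0))
  R_kcal <- 1.987e-3
  TK <- temperature_C + 273.15
  invT <- 1 / TK
  w <- NULL
  if (weighted) {
    if (is.null(se)) stop("weighted fit requires se")
    w <- (k / se)^2  # Var(ln k) = (se/k)^2
  }
  fit <- stats::lm(log(k) ~ invT, weights = w)
  sl <- stats::coef(fit)[["invT"]]
  Ea <- -sl * R_kcal
  se_Ea <- if (length(k) > 2) {
    # suppress the "essentially perfect fit" note on exactly-Arrhenius input
    suppressWarnings(sqrt(stats::vcov(fit)[2, 2]) * R_kcal)
  } else NA_real_
  structure(list(Ea_kcal_mol = Ea, se_Ea = se_Ea,
                 prefactor = exp(stats::coef(fit)[[1]]),
                 table = data.frame(temperature_C = temperature_C,
                                    T_K = TK, k = k,
                                    se = if (is.null(se)) NA_real_ else se),
                 weighted = weighted, R_kcal_mol_K = R_kcal, fit = fit),
            class = "arrhenius_result")
}

#' @export
print.arrhenius_result <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%s): Ea = %.3g kcal/mol",
              if (x$weighted) "SE-weighted" else "unweighted", x$Ea_kcal_mol))
  if (is.finite(x$se_Ea)) cat(sprintf(" (SE %.2g)", x$se_Ea))
  cat(sprintf(", A = %.3g /s\n", x$prefactor))
  print(x$table, row.names = FALSE)
  invisible(x)
}
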