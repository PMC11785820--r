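#' Per-delay displacement statistics
#'
#' For each delay tau, forms all overlapping displacement pairs
#' `x(t + tau) - x(t)` within the segment and records their sample mean
#' `mu`, variance `s^2`, the ratio `phi = 2*mu/s^2` and the number of
#' pairs. Sample moments are the Gaussian maximum-likelihood estimates;
#' an optional histogram-fit mode is available in [gaussian_hist_fit()]
#' for cross-checking. Delays that are not integer multiples of the
#' frame interval are snapped to the nearest multiple with a warning;
#' delays with fewer than `min_pairs` pairs are dropped.
#'
#' @param segment A segment from [extract_segments()], a
#'   `cargo_trajectory` (x projected internally), or a numeric 1-D
#'   position vector (then `dt` is required).
#' @param tau_grid Delays in seconds (default 10-ms steps, 10-200 ms).
#' @param dt Frame interval (s); taken from the segment if absent.
#' @param min_pairs Minimum displacement pairs per reported delay.
#' @return Data frame of class `displacement_stats`: `tau_s`, `mu_nm`,
#'   `s2_nm2`, `phi_inv_nm`, `n_pairs`.
#' @export
displacement_stats <- function(segment, tau_grid = seq(0.01, 0.2, by = 0.01),
                               dt = NULL, min_pairs = 50) {
  if (is.list(segment) && !is.data.frame(segment) && !is.null(segment$x)) {
    x <- segment$x; dt <- segment$dt
  } else if (inherits(segment, "cargo_trajectory")) {
    dt <- trajectory_meta(segment)$dt_s
    x <- project_to_axis(segment)
  } else {
    x <- as.numeric(segment)
    if (is.null(dt)) stop("dt required for a bare position vector")
  }
  n <- length(x)
  lags <- round(tau_grid / dt)
  if (any(abs(lags * dt - tau_grid) > 1e-9)) {
    warning("some delays are not multiples of the frame interval; snapped")
  }
  lags <- unique(pmax(lags, 1L))
  rows <- lapply(lags, function(l) {
    if (n - l < min_pairs) return(NULL)
    d <- x[(1 + l):n] - x[1:(n - l)]
    mu <- mean(d); s2 <- stats::var(d)
    data.frame(tau_s = l * dt, mu_nm = mu, s2_nm2 = s2,
               phi_inv_nm = 2 * mu / s2, n_pairs = length(d))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("segment too short for the requested delays")
  out <- do.call(rbind, rows)
  class(out) <- c("displacement_stats", "data.frame")
  out
}

#' Gaussian fit of a displacement histogram
#'
#' Comparison mode for [displacement_stats()]: least-squares fit of a
#' Gaussian density to a binned displacement histogram. Included because
#' moment and histogram estimates should agree on Gaussian data; the
#' moment route is the default throughout.
#'
#' @param d Displacements (nm).
#' @param bins Number of histogram bins.
#' @return List with `mu` and `s2`.
#' @export
gaussian_hist_fit <- function(d, bins = 30) {
  h <- graphics::hist(d, breaks = bins, plot = FALSE)
  xm <- h$mids; y <- h$density
  fit <- minpack.lm::nlsLM(y ~ stats::dnorm(xm, m, s),
                           start = list(m = mean(d), s = stats::sd(d)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(mu = unname(cf["m"]), s2 = unname(cf["s"]^2))
}

#' Displacement-fluctuation relaxation curve phi(tau)
#'
#' `phi(tau) = 2*mu/(s^2 - 2*sigma^2)` when the localization noise SD
#' `sigma` is supplied (static noise adds `2 sigma^2` to every
#' displacement variance), else `2*mu/s^2`. Entries whose corrected
#' variance is nonpositive are dropped with a warning.
#'
#' For a cargo driven by n independent motors stepping at rate
#' `lambda` with per-step mean `d` and variance `v`, the curve follows
#' `phi(tau) = 2 lambda tau d / (lambda tau (d^2 + v)/n + 2 sigma^2)`,
#' rising toward the quantized asymptote `n * 2d/(d^2 + v)`.
#'
#' @param stats A [displacement_stats()] result.
#' @param noise_sd Localization noise SD (nm), or `NULL` to skip the
#'   correction.
#' @return Data frame of class `phi_curve` (`tau_s`, `phi_inv_nm`, ...).
#' @export
phi_curve <- function(stats, noise_sd = NULL) {
  stopifnot(nrow(stats) > 0)
  s2 <- stats$s2_nm2
  if (!is.null(noise_sd)) s2 <- s2 - 2 * noise_sd^2
  keep <- s2 > 0
  if (any(!keep)) warning(sum(!keep), " entries dropped: corrected variance <= 0")
  out <- stats[keep, , drop = FALSE]
  out$phi_inv_nm <- 2 * out$mu_nm / s2[keep]
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("phi_curve", "data.frame")
  out
}

#' Asymptote of a phi relaxation curve
#'
#' The asymptote is the mean of phi(tau) over the tail window
#' `tau >= tau_min` (default 120 ms, where the relaxation has leveled
#' off). The curve counts as converged when the magnitude of the fitted
#' relative trend over the window -- |slope| x window span / |mean phi|
#' -- is below `flatness_tol`; non-converged curves carry no asymptote.
#'
#' @param curve A [phi_curve()] result.
#' @param tau_min Start of the tail window (s).
#' @param flatness_tol Relative-trend threshold for convergence.
#' @return List with `phi_inf` (nm^-1, `NA` when not converged),
#'   `converged`, `rel_slope`, `n_tail`.
#' @export
phi_asymptote <- function(curve, tau_min = 0.12, flatness_tol = 0.1) {
  tail_ <- curve[curve$tau_s >= tau_min, ]
  if (nrow(tail_) < 3) {
    return(list(phi_inf = NA_real_, converged = FALSE, rel_slope = NA_real_,
                n_tail = nrow(tail_)))
  }
  fit <- stats::lm(phi_inv_nm ~ tau_s, data = tail_)
  sl <- stats::coef(fit)[["tau_s"]]
  span <- diff(range(tail_$tau_s))
  m <- mean(tail_$phi_inv_nm)
  rel <- abs(sl) * span / abs(m)
  conv <- is.finite(rel) && rel < flatness_tol
  list(phi_inf = if (conv) m else NA_real_, converged = conv,
       rel_slope = rel, n_tail = nrow(tail_))
}

#' Block-bootstrap standard error of the phi asymptote
#'
#' Overlapping displacement pairs are serially correlated, so the SE of
#' the asymptote is estimated by resampling contiguous time blocks of
#' the segment positions and recomputing the tail mean of phi.
#'
#' @param segment Segment (as in [displacement_stats()]).
#' @param tau_grid,noise_sd,tau_min Passed through to the phi pipeline.
#' @param block_s Block length (s).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @return Standard error (nm^-1).
#' @export
phi_boot_se <- function(segment, tau_grid = seq(0.01, 0.2, by = 0.01),
                        noise_sd = NULL, tau_min = 0.12, block_s = 0.5,
                        n_boot = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- if (is.list(segment) && !is.null(segment$x)) segment$x else as.numeric(segment)
  dt <- if (is.list(segment) && !is.null(segment$dt)) segment$dt else
    stop("segment must carry dt")
  bl <- max(round(block_s / dt), round(max(tau_grid) / dt) + 1)
  nb <- floor(length(x) / bl)
  if (nb < 2) return(NA_real_)
  vals <- replicate(n_boot, {
    pick <- sample.int(nb, nb, replace = TRUE)
    # phi is computed on increments, so blocks are concatenated as increments
    dxb <- unlist(lapply(pick, function(j) diff(x[((j - 1) * bl + 1):(j * bl)])))
    xb <- c(0, cumsum(dxb))
    st <- displacement_stats(xb, tau_grid, dt = dt, min_pairs = 10)
    pc <- phi_curve(st, noise_sd)
    mean(pc$phi_inv_nm[pc$tau_s >= tau_min])
  })
  stats::sd(vals, na.rm = TRUE)
}

#' Cluster quantized values and extract the unit quantum
#'
#' k-means over a range of k (50 restarts); k is chosen by the largest
#' relative drop in within-cluster sum of squares (elbow). Cluster
#' centres are then regressed onto integer multiples `{phi1, 2 phi1, ...}`
#' (least squares through the origin, iterated once) to extract the unit
#' quantum, and each value is assigned the integer multiple of its
#' cluster.
#'
#' @param values Numeric values to cluster (e.g. pooled phi asymptotes).
#' @param k_range Candidate numbers of clusters.
#' @param seed Optional RNG seed (k-means restarts).
#' @param nstart k-means restarts.
#' @return List: `centers` (sorted), `k`, `assignments` (integer multiple
#'   per value), `quantum` (fitted phi1), `wss` per k.
#' @export
cluster_quantized <- function(values, k_range = 1:6, seed = NULL, nstart = 50) {
  values <- as.numeric(values)
  k_max <- max(k_range)
  if (length(values) < 2 * k_max) {
    k_range <- k_range[k_range <= floor(length(values) / 2)]
    if (!length(k_range)) k_range <- 1L
  }
  if (!is.null(seed)) set.seed(seed)
  if (diff(range(values)) < .Machine$double.eps) {
    return(list(centers = values[1], k = 1L,
                assignments = rep(1L, length(values)),
                quantum = values[1], wss = 0))
  }
  wss <- rep(NA_real_, max(k_range))
  fits <- list()
  for (k in k_range) {
    km <- stats::kmeans(values, centers = k, nstart = nstart)
    wss[k] <- km$tot.withinss
    fits[[k]] <- km
  }
  ks <- sort(k_range)
  # a solution with a singleton cluster is an outlier split, not structure
  ok <- vapply(ks, function(k) min(fits[[k]]$size) >= 2L, TRUE)
  if (any(ok)) ks <- ks[ok]
  if (length(ks) == 1L) {
    k_best <- ks
  } else {
    drops <- vapply(seq_along(ks)[-1], function(i) {
      prev <- wss[ks[i - 1]]
      (prev - wss[ks[i]]) / prev
    }, 0)
    k_best <- ks[-1][which.max(drops)]
    # a flat WSS profile means no real structure beyond one cluster
    if (max(drops) < 0.3) k_best <- ks[1]
  }
  km <- fits[[k_best]]
  centers <- sort(as.numeric(km$centers))
  # map cluster id -> sorted-centre rank
  rank_of <- match(as.numeric(km$centers), centers)
  # fit quantum: centres ~ m * phi1 with integer m, LS through origin
  phi1 <- centers[1]
  for (it in 1:3) {
    m <- pmax(1L, round(centers / phi1))
    phi1 <- sum(m * centers) / sum(m^2)
  }
  m <- pmax(1L, round(centers / phi1))
  assignments <- m[rank_of[km$cluster]]
  list(centers = centers, k = k_best, assignments = as.integer(assignments),
       quantum = phi1, wss = wss[ks])
}

#' Summarize per-segment motor numbers
#'
#' Pools the quantized phi asymptotes of a cohort of constant-velocity
#' segments into motor-number assignments and reports the histogram and
#' mean +/- SE (SE = SD/sqrt(#segments)), plus the per-cargo timeline.
#'
#' @param phi_values Pooled converged phi asymptotes (nm^-1).
#' @param segment_ids Optional parallel ids for the timeline.
#' @param k_range,seed Passed to [cluster_quantized()].
#' @return Object of class `motor_count_result`: `n` (per segment),
#'   `mean_n`, `se_n`, `histogram`, `centers`, `quantum`.
#' @export
motor_count_summary <- function(phi_values, segment_ids = NULL,
                                k_range = 1:6, seed = NULL) {
  cl <- cluster_quantized(phi_values, k_range = k_range, seed = seed)
  n <- cl$assignments
  se <- if (length(n) > 1) stats::sd(n) / sqrt(length(n)) else 0
  structure(list(n = n, mean_n = mean(n), se_n = se,
                 histogram = table(factor(n, levels = seq_len(max(n)))),
                 centers = cl$centers, quantum = cl$quantum,
                 phi_values = phi_values,
                 segment_ids = if (is.null(segment_ids)) seq_along(n) else segment_ids),
            class = "motor_count_result")
}

#' @export
print.motor_count_result <- function(x, ...) {
  cat(sprintf("Motor-number summary over %d segments\n", length(x$n)))
  cat(sprintf("  unit quantum phi1 = %.4g nm^-1; centers: %s nm^-1\n",
              x$quantum, paste(signif(x$centers, 3), collapse = ", ")))
  cat(sprintf("  mean n = %.3f +/- %.3f (SE)\n", x$mean_n, x$se_n))
  print(x$histogram)
  invisible(x)
}

#' Full phi pipeline for one segment
#'
#' Convenience composition: displacement statistics, noise-corrected phi
#' curve and asymptote extraction.
#'
#' @param segment Segment (as in [displacement_stats()]).
#' @param tau_grid Delay grid (s).
#' @param noise_sd Localization noise SD (nm) or `NULL`.
#' @param tau_min,flatness_tol Passed to [phi_asymptote()].
#' @param dt Frame interval for bare numeric input.
#' @return List with `stats`, `curve`, `asymptote`.
#' @export
phi_pipeline <- function(segment, tau_grid = seq(0.01, 0.2, by = 0.01),
                         noise_sd = NULL, tau_min = 0.12, flatness_tol = 0.1,
                         dt = NULL) {
  st <- displacement_stats(segment, tau_grid, dt = dt)
  pc <- phi_curve(st, noise_sd)
  asy <- phi_asymptote(pc, tau_min = tau_min, flatness_tol = flatness_tol)
  list(stats = st, curve = pc, asymptote = asy)
}
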