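#' Point-spread-function / camera model
#'
#' Shot-noise-limited imaging model. The effective Gaussian spot SD is
#' `wavelength/(2*NA)/width_factor`; with the default `width_factor = 1`
#' the theoretical localization precision of a centroid-class estimator is
#' `(wavelength/2NA)/sqrt(n_photons)`, the standard diffraction-limit
#' scaling for background-free imaging. Set `width_factor = 2.355` to
#' interpret `wavelength/2NA` as the spot FWHM instead.
#'
#' @param wavelength Emission wavelength (nm).
#' @param na Numerical aperture, in (0, 1.49].
#' @param pixel_nm Camera pixel size (nm).
#' @param photons Expected detected photons per frame.
#' @param background Expected background photons per pixel.
#' @param width_factor Divisor converting `wavelength/2NA` to the Gaussian
#'   spot SD.
#' @return Object of class `psf_model`.
#' @export
psf_model <- function(wavelength = 605, na = 1.49, pixel_nm = 160,
                      photons = 1000, background = 0, width_factor = 1) {
  stopifnot(na > 0, na <= 1.49, photons > 0, pixel_nm > 0, background >= 0)
  spot_sd <- wavelength / (2 * na) / width_factor
  structure(list(wavelength = wavelength, na = na, pixel_nm = pixel_nm,
                 photons = photons, background = background,
                 spot_sd = spot_sd),
            class = "psf_model")
}

#' Theoretical localization precision
#'
#' `delta_x = (wavelength / 2NA) / sqrt(n_photons)` for background-free,
#' shot-noise-limited imaging.
#'
#' @param psf A [psf_model()].
#' @param photons Photon count (defaults to the model's).
#' @return Precision in nm.
#' @export
localization_precision <- function(psf, photons = psf$photons) {
  psf$wavelength / (2 * psf$na) / sqrt(photons)
}

# Expected photons per pixel for a Gaussian spot integrated over pixels.
spot_expectation <- function(cx, cy, n_photons, spot_sd, pixel_nm, nx, ny) {
  ex <- diff(stats::pnorm(seq(0, nx) * pixel_nm, mean = cx, sd = spot_sd))
  ey <- diff(stats::pnorm(seq(0, ny) * pixel_nm, mean = cy, sd = spot_sd))
  n_photons * outer(ey, ex)
}

#' Render an image stack of a moving emitter
#'
#' Each frame is an independent Poisson realization of a pixel-integrated
#' 2-D Gaussian spot plus uniform background.
#'
#' @param positions n x 2 matrix of true emitter positions (nm), in image
#'   coordinates with the origin at the field-of-view corner. A single
#'   position may be given as a length-2 vector (recycled per frame with
#'   `n_frames`).
#' @param psf A [psf_model()].
#' @param fov_px Field of view, pixels `c(nx, ny)`.
#' @param n_frames Number of frames when `positions` is a single point.
#' @param seed Optional RNG seed.
#' @return Array `[ny, nx, n_frames]` of photon counts, with the pixel
#'   size and true positions in attributes.
#' @export
render_psf_stack <- function(positions, psf, fov_px = c(16, 16),
                             n_frames = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  if (!is.null(n_frames) && nrow(positions) == 1L) {
    positions <- positions[rep(1, n_frames), , drop = FALSE]
  }
  nx <- fov_px[1]; ny <- fov_px[2]
  lim <- c(nx, ny) * psf$pixel_nm
  if (any(positions < 0) || any(positions[, 1] > lim[1]) ||
      any(positions[, 2] > lim[2])) {
    stop("positions outside the field of view")
  }
  if (psf$spot_sd < psf$pixel_nm) {
    warning("spot SD below one pixel: undersampled PSF")
  }
  nf <- nrow(positions)
  stack <- array(0L, c(ny, nx, nf))
  for (i in seq_len(nf)) {
    mu <- spot_expectation(positions[i, 1], positions[i, 2], psf$photons,
                           psf$spot_sd, psf$pixel_nm, nx, ny) + psf$background
    stack[, , i] <- stats::rpois(nx * ny, mu)
  }
  attr(stack, "pixel_nm") <- psf$pixel_nm
  attr(stack, "true_positions") <- positions
  stack
}

# 3x3 local maxima above threshold; returns pixel-centre coordinates (col, row).
find_spot_candidates <- function(img, threshold) {
  ny <- nrow(img); nx <- ncol(img)
  out <- NULL
  for (r in 2:(ny - 1)) for (cc in 2:(nx - 1)) {
    v <- img[r, cc]
    if (v > threshold && v == max(img[(r - 1):(r + 1), (cc - 1):(cc + 1)])) {
      out <- rbind(out, c(cc, r, v))
    }
  }
  if (is.null(out)) return(out)
  # deduplicate plateaus of equal-valued neighbours
  out[!duplicated(round(out[, 1:2, drop = FALSE] / 2)), , drop = FALSE]
}

# Poisson maximum-likelihood Gaussian fit on an ROI; returns centre (nm),
# width, photons. MLE attains the shot-noise precision bound sigma/sqrt(N),
# which plain least squares misses by ~40% on Poisson data.
fit_gaussian_roi <- function(roi, x0_px, y0_px, pixel_nm, spot_sd_init) {
  ny <- nrow(roi); nx <- ncol(roi)
  tot <- sum(roi)
  obj <- function(p) {
    mu <- spot_expectation(p[1], p[2], exp(p[4]), exp(p[3]), pixel_nm, nx, ny) +
      exp(p[5]) + 1e-12
    sum(mu - roi * log(mu))
  }
  p0 <- c(x0_px * pixel_nm, y0_px * pixel_nm, log(spot_sd_init),
          log(max(tot, 1)), log(max(min(roi), 0.1)))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-9))
  c(x = fit$par[1], y = fit$par[2], width = exp(fit$par[3]),
    photons = exp(fit$par[4]), converged = as.numeric(fit$convergence == 0))
}

#' Localize emitters by 2-D Gaussian fitting
#'
#' Per frame, candidate spots are 3x3 local maxima above `threshold`; each
#' is refined by least-squares fitting of a pixel-integrated 2-D Gaussian
#' (centre, width, amplitude, flat background) on a square region of
#' interest. Frames with no candidate, and fits that fail to converge, are
#' dropped and counted.
#'
#' @param stack Image stack from [render_psf_stack()] (or any
#'   `[ny, nx, n]` array with a `pixel_nm` attribute).
#' @param psf A [psf_model()] supplying the pixel size and initial width.
#' @param threshold Counts threshold for candidate detection; default
#'   `mean + 4 sd` of each frame.
#' @param roi_radius_px Half-width of the fit region (pixels).
#' @return Data frame of class `detections`: `frame`, `x_nm`, `y_nm`,
#'   `width_nm`, `photons`; dropped-fit count in attribute `n_dropped`.
#' @export
localize_frames <- function(stack, psf, threshold = NULL, roi_radius_px = NULL) {
  stopifnot(length(dim(stack)) == 3)
  pixel_nm <- attr(stack, "pixel_nm")
  if (is.null(pixel_nm)) pixel_nm <- psf$pixel_nm
  if (is.null(roi_radius_px)) {
    roi_radius_px <- max(3L, ceiling(2.5 * psf$spot_sd / pixel_nm))
  }
  nf <- dim(stack)[3]
  rows <- list(); dropped <- 0L
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    if (all(img == 0)) { dropped <- dropped + 1L; next }
    thr <- if (is.null(threshold)) mean(img) + 4 * stats::sd(img) else threshold
    cand <- find_spot_candidates(img, thr)
    if (is.null(cand)) { dropped <- dropped + 1L; next }
    for (j in seq_len(nrow(cand))) {
      cx <- cand[j, 1]; cy <- cand[j, 2]
      xr <- max(1, cx - roi_radius_px):min(ncol(img), cx + roi_radius_px)
      yr <- max(1, cy - roi_radius_px):min(nrow(img), cy + roi_radius_px)
      roi <- img[yr, xr, drop = FALSE]
      est <- fit_gaussian_roi(roi, cx - min(xr) + 0.5, cy - min(yr) + 0.5,
                              pixel_nm, psf$spot_sd)
      if (est["converged"] < 1 || est["width"] <= 0) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f - 1L,
        x_nm = est[["x"]] + (min(xr) - 1) * pixel_nm,
        y_nm = est[["y"]] + (min(yr) - 1) * pixel_nm,
        width_nm = est[["width"]], photons = est[["photons"]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               width_nm = numeric(0), photons = numeric(0))
  attr(out, "n_dropped") <- dropped
  class(out) <- c("detections", "data.frame")
  out
}

#' Link detections into trajectories
#'
#' Greedy nearest-neighbour linking between consecutive frames, gated at
#' `max_jump`; each chain becomes one trajectory. Unlinked detections
#' start new chains; chains are closed when no detection falls inside the
#' gate. Linking is invariant to the ordering of detections within a
#' frame (pairs are assigned in order of increasing distance).
#'
#' @param detections A `detections` data frame.
#' @param max_jump Gating radius (nm).
#' @param dt Frame interval (s) used for the time axis.
#' @return List of `cargo_trajectory` objects, longest first.
#' @export
link_tracks <- function(detections, max_jump, dt = 0.01) {
  if (nrow(detections) == 0) return(list())
  det <- detections[order(detections$frame), ]
  frames <- sort(unique(det$frame))
  chains <- list()   # each: list(rows = row indices)
  active <- integer(0)  # chain ids alive in previous frame
  last_idx <- integer(0)
  for (f in frames) {
    cur <- which(det$frame == f)
    if (length(active)) {
      dmat <- outer(seq_along(active), seq_along(cur),
                    Vectorize(function(i, j) {
                      sqrt((det$x_nm[last_idx[i]] - det$x_nm[cur[j]])^2 +
                           (det$y_nm[last_idx[i]] - det$y_nm[cur[j]])^2)
                    }))
      pairs <- which(dmat <= max_jump, arr.ind = TRUE)
      taken_i <- logical(length(active)); taken_j <- logical(length(cur))
      new_active <- integer(0); new_last <- integer(0)
      if (nrow(pairs)) {
        ord <- order(dmat[pairs])
        for (p in ord) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          if (taken_i[i] || taken_j[j]) next
          taken_i[i] <- TRUE; taken_j[j] <- TRUE
          id <- active[i]
          chains[[id]] <- c(chains[[id]], cur[j])
          new_active <- c(new_active, id); new_last <- c(new_last, cur[j])
        }
      }
      for (j in which(!taken_j)) {
        chains[[length(chains) + 1L]] <- cur[j]
        new_active <- c(new_active, length(chains))
        new_last <- c(new_last, cur[j])
      }
      active <- new_active; last_idx <- new_last
    } else {
      for (j in cur) {
        chains[[length(chains) + 1L]] <- j
        active <- c(active, length(chains)); last_idx <- c(last_idx, j)
      }
    }
  }
  trajs <- lapply(chains, function(rows) {
    d <- det[rows, ]
    new_trajectory(d$frame, d$frame * dt, d$x_nm, d$y_nm, round(d$photons),
                   list(dt_s = dt, temperature_C = NA_real_, seed = NULL))
  })
  trajs[order(-vapply(trajs, nrow, 0L))]
}
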