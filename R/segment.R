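#' Project a trajectory onto its principal axis
#'
#' Quasi-1-D transport (e.g. along an axon in a microchannel) is reduced
#' to one dimension by projecting the (x, y) track onto the first
#' principal axis of the windowed positions; the sign is chosen so the
#' mean displacement is nonnegative.
#'
#' @param traj A `cargo_trajectory` (or data frame with `x_nm`, `y_nm`).
#' @param window Optional integer index vector selecting frames.
#' @return Numeric vector of 1-D positions (nm).
#' @export
project_to_axis <- function(traj, window = NULL) {
  xy <- cbind(traj$x_nm, traj$y_nm)
  if (!is.null(window)) xy <- xy[window, , drop = FALSE]
  if (nrow(xy) < 2) stop("need at least 2 frames")
  ctr <- colMeans(xy)
  cc <- stats::cov(xy)
  if (max(abs(cc)) < .Machine$double.eps) stop("zero-variance window")
  ax <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  p <- as.numeric((xy[, 1] - ctr[1]) * ax[1] + (xy[, 2] - ctr[2]) * ax[2])
  if (sum(diff(p)) < 0) p <- -p
  p - p[1]
}

# ---- Gaussian HMM with a mean-zero (diffusive) first state -------------

hmm_loglik_forward <- function(dx, means, vars, trans, init) {
  n <- length(dx); K <- length(means)
  dens <- vapply(seq_len(K),
                 function(k) stats::dnorm(dx, means[k], sqrt(vars[k])), dx)
  dens <- matrix(dens, n, K)
  alpha <- matrix(0, n, K)
  a <- init * dens[1, ]
  c1 <- sum(a); alpha[1, ] <- a / c1
  ll <- log(c1)
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * dens[t, ]
    ct <- sum(a)
    alpha[t, ] <- a / ct
    ll <- ll + log(ct)
  }
  list(ll = ll, alpha = alpha, dens = dens)
}

hmm_em <- function(dx, K, means0, vars0, max_iter = 100, tol = 1e-6) {
  n <- length(dx)
  means <- means0; vars <- pmax(vars0, 1e-8)
  trans <- matrix(0.05 / max(K - 1, 1), K, K); diag(trans) <- 0.95
  if (K == 1) trans <- matrix(1, 1, 1)
  init <- rep(1 / K, K)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    fw <- hmm_loglik_forward(dx, means, vars, trans, init)
    dens <- fw$dens; alpha <- fw$alpha
    beta <- matrix(0, n, K); beta[n, ] <- 1
    for (t in (n - 1):1) {
      b <- trans %*% (dens[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / sum(b)
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    if (K > 1) {
      # vectorized transition counts: xi_num[j,k] propto
      # trans[j,k] * sum_t alpha[t,j] * dens[t+1,k] * beta[t+1,k] / c_t
      Q <- dens * beta
      A <- alpha[1:(n - 1), , drop = FALSE]
      Qn <- Q[2:n, , drop = FALSE]
      ct <- rowSums((A %*% trans) * Qn)
      xi_num <- trans * crossprod(A / ct, Qn)
      trans <- xi_num / rowSums(xi_num)
    }
    init <- gamma[1, ]
    w <- colSums(gamma)
    # state 1 is the diffusive state: mean pinned at zero
    means <- as.numeric(crossprod(gamma, dx)) / w
    means[1] <- 0
    for (k in seq_len(K)) {
      vars[k] <- sum(gamma[, k] * (dx - means[k])^2) / w[k]
    }
    vars <- pmax(vars, 1e-10)
    if (abs(fw$ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE; break }
    ll_old <- fw$ll
  }
  fw <- hmm_loglik_forward(dx, means, vars, trans, init)
  list(ll = fw$ll, means = means, vars = vars, trans = trans, init = init,
       converged = converged)
}

hmm_viterbi <- function(dx, means, vars, trans, init) {
  n <- length(dx); K <- length(means)
  logdens <- vapply(seq_len(K),
                    function(k) stats::dnorm(dx, means[k], sqrt(vars[k]), log = TRUE),
                    dx)
  logdens <- matrix(logdens, n, K)
  lt <- log(trans)
  delta <- matrix(-Inf, n, K); psi <- matrix(1L, n, K)
  delta[1, ] <- log(init) + logdens[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      v <- delta[t - 1, ] + lt[, k]
      # ties break to the lowest state index
      j <- which.max(v)
      psi[t, k] <- j
      delta[t, k] <- v[j] + logdens[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Annotate a trajectory with diffusive / directed motion states
#'
#' Fits hidden-Markov models with K = 1..`max_states` states to the 1-D
#' frame displacements of the projected track. Emissions are Gaussian
#' with state mean `v * dt` (pinned to zero for the diffusive state) and
#' free variance, which absorbs both `2 D dt` and localization noise.
#' EM is run from several velocity-quantile initializations; the number
#' of states is selected by minimum BIC and the most probable path by
#' Viterbi (ties break to the lowest state index).
#'
#' @param traj A `cargo_trajectory` with at least 100 frames.
#' @param max_states Largest number of states considered (1..3).
#' @param restarts EM restarts per K.
#' @param seed Optional RNG seed for restart jitter.
#' @return Object of class `motion_annotation`: per-frame labels among
#'   `"D"`, `"DV+"`, `"DV-"`, state table (velocity, effective diffusion),
#'   selected K, per-K BIC, log-likelihood, projected positions.
#' @export
annotate_motion <- function(traj, max_states = 3, restarts = 10, seed = NULL) {
  if (nrow(traj) < 100) stop("need at least 100 frames")
  if (!is.null(seed)) set.seed(seed)
  meta <- trajectory_meta(traj)
  dt <- if (!is.null(meta$dt_s)) meta$dt_s else stats::median(diff(traj$t_s))
  x1 <- project_to_axis(traj)
  dx <- diff(x1)
  n <- length(dx)
  fits <- list(); bic <- rep(NA_real_, max_states)
  any_nonconv <- FALSE
  for (K in seq_len(max_states)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      # velocity-quantile seeding: means from displacement quantiles
      qs <- if (K == 1) numeric(0) else
        stats::quantile(dx, probs = stats::runif(K - 1, 0.05, 0.95))
      means0 <- c(0, as.numeric(qs))
      vars0 <- rep(stats::var(dx) / K, K)
      fit <- tryCatch(hmm_em(dx, K, means0, vars0), error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
      if (K == 1) break  # closed form, no restart needed
    }
    if (is.null(best)) next
    if (!best$converged) any_nonconv <- TRUE
    p <- (K - 1) + K * (K - 1) + (K - 1) + K  # init + trans + means + vars
    bic[K] <- -2 * best$ll + p * log(n)
    fits[[K]] <- best
  }
  K <- which.min(bic)
  fit <- fits[[K]]
  path <- if (K == 1) rep(1L, n) else
    hmm_viterbi(dx, fit$means, fit$vars, fit$trans, fit$init)
  lab <- ifelse(fit$means == 0 & seq_along(fit$means) == 1, "D",
                ifelse(fit$means > 0, "DV+", "DV-"))
  labels <- c(lab[path], lab[path[n]])  # frame i <- displacement i; last copies
  states <- data.frame(label = lab, v_nm_s = fit$means / dt,
                       emission_var_nm2 = fit$vars,
                       D_eff_nm2_s = fit$vars / (2 * dt))
  structure(list(labels = labels, states = states, K = K, bic = bic,
                 loglik = fit$ll, path = path, x = x1, dt = dt,
                 warning_nonconvergent = any_nonconv && K > 1),
            class = "motion_annotation")
}

#' @export
print.motion_annotation <- function(x, ...) {
  cat(sprintf("Motion annotation: K = %d states over %d frames (BIC-selected)\n",
              x$K, length(x$labels)))
  print(x$states, row.names = FALSE)
  invisible(x)
}

#' Extract approximately constant-velocity segments
#'
#' Contiguous runs of a single directed (DV) state are trimmed of
#' boundary frames and gated on the coefficient of variation of
#' block-wise velocities; positions are signed so the segment velocity is
#' positive (retrograde-positive convention).
#'
#' @param annotation A [annotate_motion()] result.
#' @param min_duration Minimum segment duration (s).
#' @param max_velocity_cv Gate on sd/mean of block velocities.
#' @param trim Frames trimmed from each end of a run.
#' @param block_s Block length for the velocity CV (s).
#' @return List of class `velocity_segments`; each element has `id`,
#'   `start`, `end` (frame indices), `t`, `x` (nm, velocity-positive),
#'   `v_nm_s`, `duration_s`.
#' @export
extract_segments <- function(annotation, min_duration = 1,
                             max_velocity_cv = 0.3, trim = 2, block_s = 0.5) {
  lab <- annotation$labels
  dt <- annotation$dt
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!(r$values[i] %in% c("DV+", "DV-"))) next
    a <- starts[i] + trim; b <- ends[i] - trim
    if (b - a < 2) next
    dur <- (b - a) * dt
    if (dur < min_duration) next
    x <- annotation$x[a:b]
    if (r$values[i] == "DV-") x <- -x
    x <- x - x[1]
    v <- (x[length(x)] - x[1]) / dur
    # velocity CV over blocks
    bl <- max(2L, round(block_s / dt))
    nb <- floor(length(x) / bl)
    cv <- NA_real_
    if (nb >= 2) {
      bv <- vapply(seq_len(nb), function(j) {
        idx <- ((j - 1) * bl + 1):(j * bl)
        (x[idx[length(idx)]] - x[idx[1]]) / ((length(idx) - 1) * dt)
      }, 0)
      cv <- stats::sd(bv) / abs(mean(bv))
    }
    if (!is.na(cv) && cv > max_velocity_cv) next
    segs[[length(segs) + 1L]] <- list(
      id = length(segs) + 1L, start = a, end = b,
      t = (seq_along(x) - 1L) * dt, x = x, dt = dt,
      v_nm_s = v, duration_s = dur, velocity_cv = cv)
  }
  structure(segs, class = "velocity_segments")
}

#' @export
print.velocity_segments <- function(x, ...) {
  cat(sprintf("%d constant-velocity segment(s)\n", length(x)))
  for (s in x) {
    cat(sprintf("  #%d frames %d-%d: v = %.0f nm/s, %.2f s (CV %.2f)\n",
                s$id, s$start, s$end, s$v_nm_s, s$duration_s,
                ifelse(is.na(s$velocity_cv), NA, s$velocity_cv)))
  }
  invisible(x)
}
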