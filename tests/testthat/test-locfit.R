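test_that("noise-free limit recovers the true position", {
  psf <- psf_model(photons = 1e8)
  pos <- c(1300, 1240)
  st <- render_psf_stack(pos, psf, n_frames = 1, seed = 1)
  det <- localize_frames(st, psf)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_nm - pos[1]), 0.1)
  expect_lt(abs(det$y_nm - pos[2]), 0.1)
})

test_that("localization precision follows the shot-noise formula", {
  psf <- psf_model(photons = 1000)
  st <- render_psf_stack(c(1280, 1280), psf, n_frames = 250, seed = 3)
  det <- localize_frames(st, psf)
  expect_gt(nrow(det), 240)
  theory <- localization_precision(psf)  # (lambda/2NA)/sqrt(n)
  expect_lt(abs(sd(det$x_nm) / theory - 1), 0.15)

  # precision ratio between 1,000 and 5,000 photons ~ sqrt(5)
  psf5 <- psf_model(photons = 5000)
  st5 <- render_psf_stack(c(1280, 1280), psf5, n_frames = 250, seed = 4)
  det5 <- localize_frames(st5, psf5)
  ratio <- sd(det$x_nm) / sd(det5$x_nm)
  expect_lt(abs(ratio / sqrt(5) - 1), 0.15)
})

test_that("localization SD scales as photons^(-1/2) over two decades", {
  sds <- vapply(c(500, 5000, 50000), function(np) {
    psf <- psf_model(photons = np)
    st <- render_psf_stack(c(1280, 1280), psf, n_frames = 120,
                           seed = 100 + np %% 97)
    det <- localize_frames(st, psf)
    sd(det$x_nm)
  }, 0)
  slope <- coef(lm(log10(sds) ~ log10(c(500, 5000, 50000))))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("well-separated spots yield one detection each", {
  # FWHM-convention spot (86-nm SD) so that 5 spot widths of separation
  # leaves negligible overlap between the two ROIs
  psf <- psf_model(photons = 5000, width_factor = 2.355)
  sep <- 5 * (psf$wavelength / (2 * psf$na))
  pos <- rbind(c(1920 - sep / 2, 1280), c(1920 + sep / 2, 1280))
  # render both spots in one frame by summing two single-spot renders
  # (narrow spot vs 160-nm pixels triggers the undersampling warning by design)
  a <- suppressWarnings(render_psf_stack(pos[1, , drop = FALSE], psf,
                                         fov_px = c(24, 16), seed = 10))
  b <- suppressWarnings(render_psf_stack(pos[2, , drop = FALSE], psf,
                                         fov_px = c(24, 16), seed = 11))
  both <- a + b
  attr(both, "pixel_nm") <- attr(a, "pixel_nm")
  det <- localize_frames(both, psf, threshold = 30)
  expect_equal(nrow(det), 2L)
  found <- sort(det$x_nm)
  sigma_fit <- psf$spot_sd / sqrt(psf$photons)
  expect_lt(abs(found[1] - pos[1, 1]), 3 * sigma_fit + 2)
  expect_lt(abs(found[2] - pos[2, 1]), 3 * sigma_fit + 2)
})

test_that("all-zero frames are dropped and counted", {
  psf <- psf_model(photons = 100)
  st <- array(0L, c(8, 8, 3))
  attr(st, "pixel_nm") <- psf$pixel_nm
  det <- localize_frames(st, psf)
  expect_equal(nrow(det), 0L)
  expect_equal(attr(det, "n_dropped"), 3L)
})

test_that("greedy gated linking keeps tracks whole and apart", {
  # one detection per frame, jumps below gate -> single full-length track
  n <- 50
  det <- data.frame(frame = 0:(n - 1), x_nm = cumsum(rep(28.1, n)),
                    y_nm = rep(0, n), width_nm = 200, photons = 1000)
  class(det) <- c("detections", "data.frame")
  tracks <- link_tracks(det, max_jump = 100, dt = 0.01)
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]), n)

  # two tracks crossing in x but separated by > gate in y stay distinct
  t1 <- data.frame(frame = 0:19, x_nm = seq(0, 950, by = 50), y_nm = 0)
  t2 <- data.frame(frame = 0:19, x_nm = seq(950, 0, by = -50), y_nm = 200)
  det2 <- rbind(t1, t2)
  det2$width_nm <- 200; det2$photons <- 1000
  class(det2) <- c("detections", "data.frame")
  tracks2 <- link_tracks(det2, max_jump = 100, dt = 0.01)
  expect_length(tracks2, 2L)
  expect_true(all(vapply(tracks2, nrow, 0L) == 20L))
  # each output track stays on one y level
  expect_true(all(vapply(tracks2, function(tr) length(unique(tr$y_nm)), 0L) == 1L))
})

test_that("linking is invariant to detection order within a frame", {
  t1 <- data.frame(frame = rep(0:9, each = 2),
                   x_nm = c(rbind(seq(0, 270, by = 30), seq(1000, 1270, by = 30))),
                   y_nm = 0, width_nm = 200, photons = 1000)
  shuffled <- t1[order(t1$frame, -t1$x_nm), ]
  class(t1) <- class(shuffled) <- c("detections", "data.frame")
  a <- link_tracks(t1, max_jump = 100)
  b <- link_tracks(shuffled, max_jump = 100)
  xa <- lapply(a, function(z) z$x_nm)
  xb <- lapply(b, function(z) z$x_nm)
  expect_setequal(sapply(xa, paste, collapse = ","),
                  sapply(xb, paste, collapse = ","))
})

test_that("fast axonal drift stays linked at the tracking gate", {
  # 2.81 um/s at 10-ms frames = 28.1 nm/frame against a 100-nm gate
  psf <- psf_model(photons = 2000)
  n <- 25
  pos <- cbind(800 + 28.1 * (0:(n - 1)), 1280)
  st <- render_psf_stack(pos, psf, seed = 21)
  det <- localize_frames(st, psf)
  tracks <- link_tracks(det, max_jump = 100, dt = 0.01)
  expect_equal(nrow(tracks[[1]]), n)
  v <- coef(lm(tracks[[1]]$x_nm ~ tracks[[1]]$t_s))[2]
  expect_lt(abs(v - 2810), 200)
})
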