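test_that("noiseless staircases are fit exactly", {
  x <- rep(c(0, 8, 16, 24, 32, 40), each = 25)
  f <- find_steps(x)
  expect_equal(f$n_steps, 5L)
  expect_equal(f$step_sizes, rep(8, 5), tolerance = 1e-12)
  # flat trace yields zero steps
  f0 <- find_steps(rep(3.2, 50))
  expect_equal(f0$n_steps, 0L)
})

test_that("steps are recovered from noisy traces with high recall", {
  m <- step_model()
  tr <- simulate_step_trace(m, dwell_rate = 13.9, n_steps = 100, noise_sd = 2,
                            frame_interval = 0.0025, seed = 51)
  f <- find_steps(tr)
  truth <- trajectory_meta(tr)$truth
  # a step at time s first manifests in frame ceiling(s/dt)
  true_frames <- ceiling(truth$step_times / 0.0025)
  diffs <- vapply(true_frames,
                  function(t0) min(abs(f$step_frames - 1L - t0)), 0)
  hit <- diffs <= 1
  expect_gte(mean(hit), 0.95)
  # matched step-size errors
  matched <- vapply(true_frames[hit], function(t0) {
    f$step_sizes[which.min(abs(f$step_frames - 1L - t0))]
  }, 0)
  rmse <- sqrt(mean((matched - truth$step_sizes[hit])^2))
  expect_lt(rmse, 2)
  # step-size histogram shows its mode near 8 nm on the 4-nm grid
  mode_bin <- as.numeric(names(which.max(table(round(f$step_sizes / 4) * 4))))
  expect_equal(mode_bin, 8)
})

test_that("the step finder is idempotent on its own staircase", {
  m <- step_model()
  tr <- simulate_step_trace(m, 13.9, 40, noise_sd = 2, frame_interval = 0.0025,
                            seed = 52)
  f1 <- find_steps(tr)
  f2 <- find_steps(staircase_of(f1))
  expect_equal(f2$n_steps, f1$n_steps)
  expect_equal(f2$levels, f1$levels, tolerance = 1e-9)
})

test_that("dwell extraction censors the camera dead time", {
  fit <- structure(list(step_frames = c(10L, 20L, 35L, 36L), n_steps = 4L),
                   class = "step_fit")
  dw <- dwell_times(fit, frame_interval = 0.001)
  expect_equal(dw$times, c(0.010, 0.015), tolerance = 1e-12)
  expect_equal(attr(dw, "n_censored"), 1L)  # the 1-frame dwell
  expect_equal(dw$censor_threshold, 0.002)
})

test_that("recovered dwell distribution matches ground truth (KS)", {
  m <- step_model()
  tr <- simulate_step_trace(m, 13.9, 150, noise_sd = 2,
                            frame_interval = 0.0025, seed = 53)
  f <- find_steps(tr)
  dw <- dwell_times(f, 0.0025)
  truth <- diff(trajectory_meta(tr)$truth$step_times)
  ks <- suppressWarnings(ks.test(dw$times, truth))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("Erlang-2 MLE has its closed form and Fisher uncertainty", {
  # equal dwells: k = 2/t0 exactly
  f <- fit_dwell_mle(rep(0.05, 40), "erlang2")
  expect_equal(f$k, 40, tolerance = 1e-12)
  # closed form agrees with the numerical optimizer of the same likelihood
  d <- simulate_dwells("erlang2", list(k = 13.9), 283, seed = 54)
  fc <- fit_dwell_mle(d, "erlang2")
  ll <- function(k) sum(2 * log(k) + log(d$times) - k * d$times)
  kopt <- optimize(ll, c(1, 100), maximum = TRUE)$maximum
  expect_equal(fc$k, kopt, tolerance = 1e-5)
  expect_equal(fc$se, fc$k / sqrt(2 * 283), tolerance = 1e-12)
  # large-sample recovery at the 37 degC rate, within its own CI
  d2 <- simulate_dwells("erlang2", list(k = 97.1), 1e5, seed = 55)
  f2 <- fit_dwell_mle(d2, "erlang2")
  expect_lt(abs(f2$k - 97.1), 3 * f2$se)
  # replicate spread matches the Fisher oracle k/sqrt(2n) = 0.584
  ks <- vapply(1:400, function(r) {
    set.seed(1000 + r)
    2 / mean(rgamma(283, shape = 2, rate = 13.9))
  }, 0)
  expect_lt(abs(sd(ks) - 0.584) / 0.584, 0.12)
  # estimator converges at n^(-1/2)
  sds <- vapply(c(100, 400, 1600), function(n) {
    sd(vapply(1:200, function(r) {
      set.seed(n * 7 + r)
      2 / mean(rgamma(n, shape = 2, rate = 13.9))
    }, 0))
  }, 0)
  slope <- coef(lm(log(sds) ~ log(c(100, 400, 1600))))[2]
  expect_lt(abs(slope + 0.5), 0.08)
  expect_error(fit_dwell_mle(c(-1, rep(0.1, 40)), "erlang2"), "non-positive")
})

test_that("model comparison identifies the dwell law", {
  d <- simulate_dwells("erlang2", list(k = 97.1), 920, seed = 56)
  cmp <- compare_dwell_models(d)
  expect_equal(cmp$model[1], "erlang2")
  aic <- setNames(cmp$aic, cmp$model)
  expect_gt(aic["single_exp"] - aic["erlang2"], 10)
  expect_true(cmp$shape[cmp$model == "gamma"] > 1.8 &&
              cmp$shape[cmp$model == "gamma"] < 2.2)
  # exponential data prefer the single-exponential model
  de <- simulate_dwells("single_exp", list(k = 20), 500, seed = 57)
  cmp2 <- compare_dwell_models(de)
  expect_equal(cmp2$model[1], "single_exp")
  # unconstrained two-rate fit on equal-rate data returns near-equal rates
  ft <- fit_dwell_mle(d, "two_rate")
  expect_gt(ft$k / ft$k2, 0.8)
  expect_lt(ft$k / ft$k2, 1.25)
})

test_that("randomness parameter bounds the number of kinetic steps", {
  d <- simulate_dwells("erlang2", list(k = 97.1), 1e5, seed = 58)
  r <- randomness(d, n_boot = 300, seed = 1)
  expect_lt(abs(r$r - 0.5), 0.01)
  expect_lt(abs(r$n_min - 2), 0.05)
  expect_equal(r$n_min, 1 / r$r, tolerance = 1e-12)
  expect_true(r$ci_n_min[1] < 2 && r$ci_n_min[2] > 2)
  # Erlang-4 (four equal sequential rates): n_min -> 4
  set.seed(59)
  d4 <- rowSums(matrix(rexp(4e5, 97.1), ncol = 4))
  r4 <- randomness(d4, n_boot = 200, seed = 2)
  expect_lt(abs(r4$n_min - 4), 0.15)
})

test_that("dead-time censoring biases the rate by under 3 percent", {
  # excluding dwells below 2 frames lengthens the sample mean, so the
  # closed-form estimate 2/mean shifts slightly DOWN; the magnitude stays
  # small while the frame interval is <= 5% of the mean dwell
  for (k in c(13.9, 97.1)) {
    fi <- 0.05 * (2 / k)
    d <- simulate_dwells("erlang2", list(k = k), 3e4, seed = 60 + round(k))
    kept <- d$times[d$times >= 2 * fi]
    khat <- fit_dwell_mle(kept, "erlang2")$k
    expect_lt(abs(khat - k) / k, 0.03)
    expect_lt(khat, k * 1.005)
  }
})

test_that("Arrhenius analysis inverts exactly and matches the rate triple", {
  R <- 1.987e-3
  # exact generation at Ea = 20 kcal/mol
  Tc <- c(15, 25, 35); A <- 1e16
  kex <- A * exp(-20 / (R * (Tc + 273.15)))
  fit <- arrhenius_fit(Tc, kex)
  expect_equal(fit$Ea_kcal_mol, 20, tolerance = 1e-6)
  expect_equal(fit$prefactor, A, tolerance = 1e-4)
  # the published temperature-rate triple: unweighted recomputation
  fit2 <- arrhenius_fit(c(22, 30, 37), c(13.9, 56.1, 97.1))
  expect_equal(fit2$Ea_kcal_mol, 23.82, tolerance = 0.005)
  # SE-weighted mode gives a nearby value
  fit3 <- arrhenius_fit(c(22, 30, 37), c(13.9, 56.1, 97.1),
                        se = c(0.6, 1.8, 2.3), weighted = TRUE)
  expect_equal(fit3$Ea_kcal_mol, 22.18, tolerance = 0.01)
  # equal rates: Ea = 0
  expect_equal(arrhenius_fit(c(22, 37), c(50, 50))$Ea_kcal_mol, 0,
               tolerance = 1e-12)
  expect_error(arrhenius_fit(c(22, 22), c(1, 2)), "duplicate")
  expect_error(arrhenius_fit(22, 1), "at least 2")
})
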