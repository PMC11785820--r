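test_that("cycle schemes have the contracted transition structure", {
  m1 <- build_cycle("one_ATP", S = 3000)
  expect_equal(nrow(m1$transitions), 4L)
  expect_equal(sum(grepl("ATP_binding", m1$transitions$name)), 1L)
  expect_equal(sum(grepl("Pi_release", m1$transitions$name)), 1L)
  m2 <- build_cycle("two_ATP", S = 3000)
  expect_equal(nrow(m2$transitions), 8L)
  # the primary-site block strictly precedes the secondary-site block
  expect_true(max(grep("AAA1", m2$transitions$name)) <
              min(grep("AAA3", m2$transitions$name)))
  # ATP binding rate at 3 mM: 0.29 uM^-1 s^-1 x 3000 uM = 870 s^-1
  expect_equal(m2$transitions$rate[m2$transitions$name == "ATP_binding_AAA1"],
               870, tolerance = 1e-12)
  expect_error(build_cycle("two_ATP", k_Pi = -1), "positive")
  expect_error(build_cycle("three_ATP"), "arg")
})

test_that("closed-form dwell statistics are exact for sequential chains", {
  # Erlang-4: four equal rates
  m <- build_cycle("two_ATP", k_MT = 0.29, S = 97.1 / 0.29, k_Pi = 97.1,
                   instantaneous = TRUE)
  st <- closed_form_dwell_stats(m)
  expect_equal(st$mean, 4 / 97.1, tolerance = 1e-12)
  expect_equal(st$r, 1 / 4, tolerance = 1e-12)
  expect_equal(st$n_min, 4, tolerance = 1e-12)
  # full two-ATP chain at 3 mM with fast steps at 5000/s
  st2 <- closed_form_dwell_stats(build_cycle("two_ATP", S = 3000))
  expect_equal(st2$mean, 2 * (1 / 870 + 1 / 5000 + 1 / 97.1 + 1 / 5000),
               tolerance = 1e-12)
  expect_equal(st2$n_min, 2.6126, tolerance = 1e-4)
  # one-ATP at saturating ATP approaches a single rate-limiting transition
  st3 <- closed_form_dwell_stats(build_cycle("one_ATP", S = 1e9,
                                             instantaneous = TRUE))
  expect_lt(abs(st3$n_min - 1), 1e-5)
})

test_that("sampled dwells agree with the closed form within Monte-Carlo error", {
  grid <- list(build_cycle("one_ATP", S = 500),
               build_cycle("two_ATP", S = 500),
               build_cycle("two_ATP", S = 3000, instantaneous = TRUE))
  for (i in seq_along(grid)) {
    m <- grid[[i]]
    cf <- closed_form_dwell_stats(m)
    d <- sample_cycle_dwells(m, 1e5, seed = 70 + i)
    se_mean <- sqrt(cf$variance / 1e5)
    expect_lt(abs(mean(d$times) - cf$mean), 3 * se_mean)
    r_hat <- (mean(d$times^2) - mean(d$times)^2) / mean(d$times)^2
    expect_lt(abs(r_hat - cf$r), 3 * cf$r * sqrt(20 / 1e5))
  }
  # two slow equal rates with the others effectively instantaneous: r ~ 1/2
  m2 <- build_cycle("two_ATP", S = 1e8, instantaneous = TRUE)
  d2 <- sample_cycle_dwells(m2, 5e4, seed = 74)
  r2 <- (mean(d2$times^2) - mean(d2$times)^2) / mean(d2$times)^2
  expect_lt(abs(r2 - 0.5), 0.02)
})

test_that("dwell statistics are invariant to transition order", {
  m <- build_cycle("two_ATP", S = 800)
  st <- closed_form_dwell_stats(m)
  for (perm in 1:3) {
    set.seed(perm)
    mp <- m
    mp$transitions <- m$transitions[sample(nrow(m$transitions)), ]
    stp <- closed_form_dwell_stats(mp)
    expect_equal(stp$mean, st$mean, tolerance = 1e-12)
    expect_equal(stp$n_min, st$n_min, tolerance = 1e-12)
  }
})

test_that("velocity versus ATP is exactly Michaelis-Menten for the reduced chain", {
  m <- build_cycle("two_ATP", instantaneous = TRUE)
  resp <- velocity_vs_atp(m, 10^seq(0, 4, length.out = 30))
  # algebraic identity: Vmax = d*k_Pi/2, K = k_Pi/k_MT
  Vmax <- 8 * 97.1 / 2; K <- 97.1 / 0.29
  pred <- Vmax * resp$S_uM / (K + resp$S_uM)
  expect_equal(resp$v_nm_s, pred, tolerance = 1e-9)
  expect_true(all(diff(resp$v_nm_s) > 0))        # monotone in S
  expect_true(all(resp$v_nm_s < Vmax))           # bounded by saturation
  # midpoint: v(K) = Vmax/2
  respK <- velocity_vs_atp(m, c(K, 10 * K, rep(K, 6)))
  expect_equal(respK$v_nm_s[1], Vmax / 2, tolerance = 1e-9)
})

test_that("Hill fits recover the cooperativity of the generator", {
  m <- build_cycle("two_ATP", instantaneous = TRUE)
  h <- fit_hill(velocity_vs_atp(m))
  expect_lt(abs(h$n_hill - 1), 1e-3)
  expect_equal(h$Vmax, 8 * 97.1 / 2, tolerance = 1e-3)
  expect_equal(h$K, 97.1 / 0.29, tolerance = 1e-2)
  # synthetic cooperative curve with n = 2
  S <- 10^seq(0, 4, length.out = 20)
  coop <- data.frame(S_uM = S, v_nm_s = 400 * S^2 / (300^2 + S^2))
  h2 <- fit_hill(coop)
  expect_lt(abs(h2$n_hill - 2), 0.01)
  # degenerate constant response is rejected
  flat <- data.frame(S_uM = S, v_nm_s = rep(100, 20))
  expect_error(fit_hill(flat), "degenerate")
})

test_that("n_min versus ATP discriminates the one- and two-ATP schemes", {
  two <- build_cycle("two_ATP", instantaneous = TRUE)
  one <- build_cycle("one_ATP", instantaneous = TRUE)
  # low ATP: binding dominates; two-ATP still has two rate-limiting steps
  expect_lt(abs(nmin_vs_atp(two, 1e-4)$n_min - 2), 1e-3)
  # high ATP: the two Pi desorptions dominate
  expect_lt(abs(nmin_vs_atp(two, 1e9)$n_min - 2), 1e-3)
  # matched rates k_MT*S = k_Pi: four equal transitions
  expect_equal(nmin_vs_atp(two, 97.1 / 0.29)$n_min, 4, tolerance = 1e-9)
  # one-ATP at saturating ATP: a single step, n_min -> 1
  expect_lt(abs(nmin_vs_atp(one, 1e9)$n_min - 1), 1e-3)
  # the curve peaks at the matched-rate concentration
  curve <- nmin_vs_atp(two, 10^seq(0, 5, length.out = 41))
  peak_S <- curve$S_uM[which.max(curve$n_min)]
  expect_lt(abs(log10(peak_S) - log10(97.1 / 0.29)), 0.15)
})
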