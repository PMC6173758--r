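test_that("parameter object enforces conventions and stationary fraction", {
  sp <- switching_params(k_sf = 1e-4, p_fast = 0.6)
  expect_equal(sp$p_fast, 0.6)
  expect_equal(sp$k_fs, 1e-4 * 0.4 / 0.6)
  expect_error(switching_params(k_sf = 1e-4, k_fs = 1e-4,
                                tau_fast = 100, tau_slow = 50),
               "tau_fast <= tau_slow")
  expect_error(simulate_switching(switching_params(k_sf = 0, k_fs = 0), 10),
               "init_state")
})

test_that("no-switching degenerate equals the exponential renewal model", {
  sp <- switching_params(k_sf = 0, k_fs = 1e-4)
  tr <- simulate_switching(sp, 5000, seed = 4, init_state = "slow")
  expect_true(all(tr$state_at_spike == "slow"))
  m <- renewal_model(refractory_params(2, 2), exp_excitation(1 / 200))
  D <- suppressWarnings(
    ks.test(as.numeric(tr$isis), function(t) isi_cdf(m, t))$statistic)
  expect_lt(D, ks_crit(5000))
})

test_that("state holding times are exponential with the stated rates", {
  sp <- switching_params(k_sf = 2e-3, p_fast = 0.5, tau_fast = 40,
                         tau_slow = 80)
  tr <- simulate_switching(sp, 20000, seed = 14)
  hold <- diff(tr$switch_times)
  # alternating states: odd gaps are one state's holding times, even the
  # other's; both rates are 2e-3 here since p_fast = 0.5
  expect_gt(length(hold), 100)
  p1 <- suppressWarnings(ks.test(hold[seq(1, length(hold), 2)],
                                 "pexp", 2e-3)$p.value)
  p2 <- suppressWarnings(ks.test(hold[seq(2, length(hold), 2)],
                                 "pexp", 2e-3)$p.value)
  expect_gt(p1, 0.001)
  expect_gt(p2, 0.001)
  # long-run fraction of time in the fast state converges to p_fast
  total <- sum(as.numeric(tr$isis))
  sw <- c(0, tr$switch_times[tr$switch_times <= total], total)
  # state at time 0 known from first switch parity is unavailable here;
  # use the spike-state record as an occupancy proxy instead
  expect_equal(mean(tr$state_at_spike == "fast"), 0.62, tolerance = 0.1)
})

test_that("equal timescales give SRC(1) in the null band", {
  srcs <- vapply(1:10, function(s) {
    sp <- switching_params(k_sf = 1e-4, p_fast = 0.6, tau_fast = 100,
                           tau_slow = 100)
    serial_correlation(simulate_switching(sp, 2000, seed = 40 + s)$isis,
                       1)$src
  }, numeric(1))
  expect_lt(abs(median(srcs)), 2 / sqrt(2000))
})

test_that("the printed mixture mapping and per-interval equivalence hold", {
  sp <- switching_params(k_sf = 1e-4, p_fast = 0.6, tau_fast = 40,
                         tau_slow = 200)
  mix <- equivalent_mixture(sp)
  expect_equal(mix$p, 0.6)
  expect_equal(mix$lambda_E1, 0.025)
  expect_equal(mix$lambda_E2, 0.005)

  # per-interval state resampling makes the marginal exactly the mapped
  # case (iii) renewal model
  tr <- simulate_switching(sp, 20000, seed = 7, resample_per_interval = TRUE)
  D <- suppressWarnings(ks.test(
    as.numeric(tr$isis),
    function(t) isi_cdf(equivalent_renewal_model(sp), t))$statistic)
  expect_lt(D, ks_crit(20000))
  # and it carries no serial correlation
  expect_lt(abs(serial_correlation(tr$isis, 1)$src), 2 / sqrt(20000))

  # tau_fast = tau_slow collapses the mixture to a single exponential
  spc <- switching_params(k_sf = 1e-4, p_fast = 0.6, tau_fast = 100,
                          tau_slow = 100)
  mc <- equivalent_mixture(spc)
  expect_equal(mc$lambda_E1, mc$lambda_E2)
})

test_that("the p_fast-weighted mixture mean bounds the empirical mean", {
  # the continuous-time process over-represents the fast state among
  # spikes, so its mean ISI is at most the p_fast-weighted mixture mean
  # and at least the all-fast mean
  for (k in c(1e-4, 1e-3, 1e-2)) {
    sp <- switching_params(k_sf = k, p_fast = 0.5)
    tr <- simulate_switching(sp, 4000, seed = 60 + round(1e4 * k))
    mix_mean <- 4 + 0.5 * 40 + 0.5 * 200
    fast_mean <- 4 + 40
    expect_lte(mean(tr$isis), mix_mean)
    expect_gte(mean(tr$isis), fast_mean)
  }
})

test_that("SRC(1) trends across the switching-parameter sweeps", {
  # decreasing in k_sf (faster switching destroys correlation)
  grid <- data.frame(k_sf = c(1e-4, 1e-3, 1e-2), p_fast = 0.6)
  sw <- src_sweep(grid, n_trials = 12, n_isis = 2000, lags = 1, seed = 3)
  med <- tapply(sw$src, sw$k_sf, median)
  expect_gt(med[["1e-04"]], 0)
  expect_true(med[["1e-04"]] > med[["0.001"]])
  expect_true(med[["0.001"]] > med[["0.01"]] - 0.01)

  # vanishing at p_fast in {0, 1}, maximal near 0.5
  grid2 <- data.frame(k_sf = 1e-4, p_fast = c(0.001, 0.5, 0.999))
  sw2 <- src_sweep(grid2, n_trials = 12, n_isis = 2000, lags = 1, seed = 4)
  med2 <- tapply(sw2$src, sw2$p_fast, median)
  expect_gt(med2[["0.5"]], med2[["0.001"]])
  expect_gt(med2[["0.5"]], med2[["0.999"]])
  expect_lt(abs(med2[["0.001"]]), 0.05)

  # larger when the timescales separate more
  grid3 <- data.frame(k_sf = 1e-4, p_fast = 0.6,
                      tau_fast = c(20, 100), tau_slow = 200)
  sw3 <- src_sweep(grid3, n_trials = 12, n_isis = 2000, lags = 1, seed = 5)
  med3 <- tapply(sw3$src, sw3$tau_fast, median)
  expect_gt(med3[["20"]], med3[["100"]])
})

test_that("SRC(n) decays with lag, staying nonnegative, slower for slow switching", {
  lag_profile <- function(k, seed) {
    sw <- src_sweep(data.frame(k_sf = k, p_fast = 0.4),
                    n_trials = 10, n_isis = 2000,
                    lags = c(1, 5, 10, 50), seed = seed)
    tapply(sw$src, sw$lag, mean)[c("1", "5", "10", "50")]
  }
  slow <- lag_profile(1e-4, 11)
  fast <- lag_profile(1e-3, 12)
  expect_true(all(slow > -0.02))
  expect_lt(slow[["50"]], slow[["1"]])
  expect_lt(fast[["10"]], fast[["1"]])
  # slower switching decays more gradually: SRC(10)/SRC(1) larger
  expect_gt(slow[["10"]] / slow[["1"]], fast[["10"]] / fast[["1"]])
})

test_that("simulation is reproducible under seed", {
  sp <- switching_params(k_sf = 1e-3, p_fast = 0.4)
  a <- simulate_switching(sp, 500, seed = 99)
  b <- simulate_switching(sp, 500, seed = 99)
  expect_identical(as.numeric(a$isis), as.numeric(b$isis))
  expect_identical(a$state_at_spike, b$state_at_spike)
})
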