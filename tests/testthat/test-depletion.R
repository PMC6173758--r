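test_that("pool trajectories stay in [0, n_max] and releases imply spikes", {
  src <- depletion_source_params(n_max = 4, p_depl = 0.08, tau_repl = 2.5)
  sim <- simulate_depletion(src, depletion_refractory(0.6, 0.6), 500,
                            seed = 1, record_releases = TRUE)
  expect_length(sim$isis, 500)
  expect_true(all(sim$final_pools >= 0 & sim$final_pools <= 4))
  # every spike time is a release time of some source
  rel <- sort(unlist(sim$releases))
  expect_true(all(as.numeric(sim$spikes) %in% rel))
  # reproducibility
  sim2 <- simulate_depletion(src, depletion_refractory(0.6, 0.6), 500,
                             seed = 1, record_releases = TRUE)
  expect_identical(as.numeric(sim$spikes), as.numeric(sim2$spikes))
})

test_that("step-size guard rejects coarse steps", {
  src <- depletion_source_params(n_max = 4, p_depl = 0.5, tau_repl = 2.5)
  expect_error(simulate_depletion(src, depletion_refractory(), 10, dt = 0.1),
               "too coarse")
})

test_that("instant replenishment reduces to the exponential renewal model", {
  # tau_repl -> 0: the pool is always full, release rate n_max * p_depl
  src <- depletion_source_params(n_max = 4, p_depl = 0.01, tau_repl = 1e-4)
  refr <- depletion_refractory(2, 2)
  sim <- simulate_depletion(src, refr, 5000, seed = 3)
  m <- renewal_model(refractory_params(2, 2), exp_excitation(0.04))
  D <- suppressWarnings(
    ks.test(as.numeric(sim$isis), function(t) isi_cdf(m, t))$statistic)
  expect_lt(D, ks_crit(5000))
})

test_that("non-depleting source without refractoriness is Poisson", {
  # Fano averaged over 3 runs: a single run estimates F at the longest
  # window with sd ~0.07
  src <- depletion_source_params(n_max = 4, p_depl = 0.005, tau_repl = 1e-4)
  curves <- vapply(1:3, function(s) {
    sim <- simulate_depletion(src, depletion_refractory(0, 0), 5000,
                              seed = 3 + s)
    fano_factor(sim$spikes, c(10, 100, 500))$fano
  }, numeric(3))
  expect_true(all(abs(rowMeans(curves) - 1) < 0.1))
})

test_that("superposed sources match a single source of the summed rate", {
  refr <- depletion_refractory(2, 2)
  srcs <- rep(list(depletion_source_params(4, 0.0025, 1e-4)), 4)
  sim4 <- simulate_depletion(srcs, refr, 4000, seed = 5)
  sim1 <- simulate_depletion(depletion_source_params(4, 0.01, 1e-4),
                             refr, 4000, seed = 6)
  se <- sd(sim4$isis) / sqrt(4000)
  expect_lt(abs(mean(sim4$isis) - mean(sim1$isis)), 5 * se)
})

test_that("strong depletion yields negative SRC(1) and a depressed first quartile", {
  src <- depletion_source_params(n_max = 4, p_depl = 0.08, tau_repl = 2.5)
  r <- vapply(1:4, function(s) {
    sim <- simulate_depletion(src, depletion_refractory(0.6, 0.6), 5000,
                              seed = 10 + s)
    c(serial_correlation(sim$isis, 1)$src, ell_index(sim$isis)$ell)
  }, numeric(2))
  expect_lt(median(r[1, ]), 0)        # negative serial correlation
  expect_lt(median(r[2, ]), 0.2)      # ell << 1: no short-ISI mass
})

test_that("the printed recursive replenishment washes depletion memory out", {
  # under the printed update the pool deficit decays on a ~sqrt(tau*dt)
  # timescale, so the depletion signature weakens markedly
  src <- depletion_source_params(n_max = 4, p_depl = 0.08, tau_repl = 2.5)
  refr <- depletion_refractory(0.6, 0.6)
  s_rel <- vapply(1:3, function(s) serial_correlation(
    simulate_depletion(src, refr, 4000, seed = 20 + s)$isis, 1)$src,
    numeric(1))
  s_pr <- vapply(1:3, function(s) serial_correlation(
    simulate_depletion(src, refr, 4000, seed = 20 + s,
                       scheme = "printed")$isis, 1)$src,
    numeric(1))
  expect_lt(median(s_rel), median(s_pr))
  expect_lt(abs(median(s_pr)), 0.02)
})

test_that("single-source scan: depletion corner negative, weak corner null", {
  hi <- single_source_scan(p_depl_range = c(0.2, 1),
                           tau_repl_range = c(10, 50),
                           n_points = 6, n_isis = 2000, seed = 2)
  expect_lt(median(hi$src1), 0)
  lo <- single_source_scan(p_depl_range = c(0.01, 0.02),
                           tau_repl_range = c(0.1, 0.3),
                           n_points = 6, n_isis = 2000, seed = 3)
  expect_lt(abs(median(lo$src1)), 2 / sqrt(2000))
  # no L-shaped distributions arise anywhere in the scans
  expect_true(all(c(hi$ell, lo$ell) < 1))
})

test_that("many identical sources pull SRC(1) toward zero", {
  # dilution of per-source depletion memory; under this parameterization
  # the shrinkage becomes unambiguous from ~8 sources on
  res <- multi_source_experiment(n_sources_list = c(1, 8),
                                 source = depletion_source_params(4, 0.08, 2.5),
                                 n_trials = 16, n_isis = 4000,
                                 refractory = depletion_refractory(0.6, 0.6),
                                 seed = 9)
  med <- tapply(res$src1, res$n_sources, median)
  expect_lt(med[["1"]], 0)
  expect_lt(abs(med[["8"]]), abs(med[["1"]]))
})

test_that("heterogeneous sources can generate positive SRC(1)", {
  # reference two-source configuration with widely differing release rates
  srcs <- list(depletion_source_params(4, 0.0028, 20.90),
               depletion_source_params(4, 0.715, 90.30))
  srcs_pos <- vapply(1:4, function(s) serial_correlation(
    simulate_depletion(srcs, depletion_refractory(0.6, 0.6), 2000,
                       seed = 30 + s)$isis, 1)$src, numeric(1))
  expect_gt(median(srcs_pos), 0)

  # symmetric sources show no such correlation
  sym <- list(depletion_source_params(4, 0.04, 5),
              depletion_source_params(4, 0.04, 5))
  srcs_sym <- vapply(1:4, function(s) serial_correlation(
    simulate_depletion(sym, depletion_refractory(0.6, 0.6), 2000,
                       seed = 40 + s)$isis, 1)$src, numeric(1))
  expect_lt(abs(median(srcs_sym)), 2 / sqrt(2000))
})

test_that("two-source scan reports a small strongly-positive fraction", {
  sc <- two_source_scan(n_points = 12, n_isis = 1500, seed = 5)
  frac <- attr(sc, "frac_strong_pos")
  expect_gte(frac, 0)
  expect_lt(frac, 0.5)
  expect_equal(frac, mean(sc$src1 > 0.05))
})
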