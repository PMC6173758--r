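test_that("excitation densities follow their formulas and collapse limits", {
  expect_equal(excitation_pdf(exp_excitation(0.5), 0), 0.5)
  t <- c(0, 0.5, 3, 20, 100)
  # gamma mixture at n = 1 reduces to the pure exponential
  expect_equal(excitation_pdf(gamma_mix_excitation(0.3, 0.1, 1), t),
               excitation_pdf(exp_excitation(0.1), t))
  # equal-rate two-exponential mixture collapses likewise
  expect_equal(excitation_pdf(two_exp_mix_excitation(0.5, 0.2, 0.2), t),
               excitation_pdf(exp_excitation(0.2), t))
  expect_error(excitation_pdf(exp_excitation(0.5), -1), "t must be")
  expect_error(two_exp_mix_excitation(0.5, 0.01, 0.2), "lambda_E1 >=")
})

test_that("refractory pdf is the shifted exponential", {
  r <- refractory_params(2, 2)
  expect_equal(refractory_pdf(r, c(0, 1, 1.999)), c(0, 0, 0))
  expect_equal(refractory_pdf(r, 2), 0.5)
  nrm <- integrate(function(t) refractory_pdf(r, t), 2, Inf)$value
  expect_equal(nrm, 1, tolerance = 1e-8)
})

test_that("ISI pdf matches the closed-form convolution and quadrature", {
  m <- renewal_model(refractory_params(2, 2), exp_excitation(0.1))
  expect_equal(isi_pdf(m, 1), 0)            # inside the refractory support
  ts <- c(2.5, 5, 10, 30, 100, 300)
  lamR <- 0.5; lamE <- 0.1
  closed <- lamE * lamR / (lamR - lamE) *
    (exp(-lamE * (ts - 2)) - exp(-lamR * (ts - 2)))
  expect_equal(isi_pdf(m, ts), closed, tolerance = 1e-12)
  # independent adaptive-quadrature oracle of the convolution integral
  num <- vapply(ts, function(t) {
    integrate(function(u) dexp(u, lamR) * dexp(t - 2 - u, lamE),
              0, t - 2, rel.tol = 1e-11)$value
  }, numeric(1))
  expect_equal(isi_pdf(m, ts), num, tolerance = 1e-8)
})

test_that("ISI pdf integrates to 1 across cases and parameters", {
  models <- list(
    renewal_model(refractory_params(0, 2), exp_excitation(0.5)),
    renewal_model(refractory_params(2, 2), exp_excitation(0.05)),
    renewal_model(refractory_params(1, 0.5), exp_excitation(2)),     # lam_R = lam_E
    renewal_model(refractory_params(2, 2), gamma_mix_excitation(0.6, 0.05, 3.5)),
    renewal_model(refractory_params(1, 4), gamma_mix_excitation(0.1, 0.2, 8)),
    renewal_model(refractory_params(2, 2), two_exp_mix_excitation(0.6, 0.025, 0.005)),
    renewal_model(refractory_params(0.5, 1), two_exp_mix_excitation(0.9, 1, 0.01))
  )
  for (m in models) {
    total <- integrate(function(t) isi_pdf(m, t), 0, Inf,
                       rel.tol = 1e-9, subdivisions = 500)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("ISI cdf is a valid distribution function agreeing with the pdf", {
  for (m in list(ref_case_i(), ref_case_iii(),
                 renewal_model(refractory_params(2, 2),
                               gamma_mix_excitation(0.6, 0.05, 3.5)))) {
    ts <- seq(0, 400, by = 2)
    Fv <- isi_cdf(m, ts)
    expect_true(all(diff(Fv) >= -1e-12))
    expect_equal(isi_cdf(m, 2), 0)          # F(t_abs) = 0
    expect_gt(isi_cdf(m, 2000), 0.999)
    chk <- integrate(function(t) isi_pdf(m, t), 0, 150,
                     rel.tol = 1e-9, subdivisions = 400)$value
    expect_equal(isi_cdf(m, 150), chk, tolerance = 1e-5)
  }
})

test_that("degenerate limits reduce to simpler laws", {
  # tau_rel = 0: pure shifted exponential
  m <- renewal_model(refractory_params(3, 0), exp_excitation(0.2))
  ts <- c(3.5, 8, 30)
  expect_equal(isi_pdf(m, ts), dexp(ts - 3, 0.2))
  expect_equal(isi_cdf(m, ts), pexp(ts - 3, 0.2))
  # gamma mixture with n = 1 equals case (i) through the full convolution
  mi <- renewal_model(refractory_params(2, 2), exp_excitation(0.1))
  mii <- renewal_model(refractory_params(2, 2), gamma_mix_excitation(0.3, 0.1, 1))
  expect_equal(isi_pdf(mii, ts), isi_pdf(mi, ts), tolerance = 1e-8)
  expect_equal(isi_cdf(mii, ts), isi_cdf(mi, ts), tolerance = 1e-4)
  # equal-rate case (iii) equals case (i) pointwise
  miii <- renewal_model(refractory_params(2, 2), two_exp_mix_excitation(0.4, 0.1, 0.1))
  expect_equal(isi_pdf(miii, ts), isi_pdf(mi, ts), tolerance = 1e-12)
})

test_that("sampling matches the analytic distribution (means and KS)", {
  m <- ref_case_i()
  x <- sample_isis(m, 1e5, seed = 5)
  expect_gte(min(x), 2)                      # support above t_abs
  # E = t_abs + tau_rel + 1/lambda_E = 24; sd/sqrt(n) CLT band
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 24), 4 * se)
  D <- suppressWarnings(ks.test(as.numeric(x), function(t) isi_cdf(m, t))$statistic)
  expect_lt(D, ks_crit(1e5))

  for (m2 in list(ref_case_iii(),
                  renewal_model(refractory_params(2, 2),
                                gamma_mix_excitation(0.6, 0.05, 3.5)))) {
    x2 <- sample_isis(m2, 2e4, seed = 6)
    D2 <- suppressWarnings(ks.test(as.numeric(x2), function(t) isi_cdf(m2, t))$statistic)
    expect_lt(D2, ks_crit(2e4))
  }
  # seed reproducibility
  expect_identical(as.numeric(sample_isis(m, 100, seed = 9)),
                   as.numeric(sample_isis(m, 100, seed = 9)))
})

test_that("model config round-trips through the flat key-value form", {
  for (m in list(ref_case_i(), ref_case_iii(),
                 renewal_model(refractory_params(1, 3),
                               gamma_mix_excitation(0.2, 0.08, 2)))) {
    expect_equal(model_from_config(model_to_config(m)), m)
  }
  expect_equal(n_free_params(ref_case_i()), 3L)
  expect_equal(n_free_params("ii"), 5L)
  expect_equal(n_free_params(ref_case_iii()$excitation), 5L)
})
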