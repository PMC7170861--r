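# Steady-state isotherm fitting and assay normalizations.

test_that("isotherm generator reproduces the closed form at zero noise", {
  # C = KD gives half-max
  half <- simulate_isotherm(isotherm_sim_params(
    kd = 2, rmax = 100, concentrations = c(0.5, 2, 8)))
  expect_equal(half$responses[2], 50)
  # saturation limit
  sat <- simulate_isotherm(isotherm_sim_params(
    kd = 2, rmax = 100, concentrations = c(1, 10, 2 * 2000)))
  expect_lt(abs(sat$responses[3] - 100) / 100, 0.001)
  # hand-computed series
  conc <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  iso <- simulate_isotherm(isotherm_sim_params(
    kd = 3, rmax = 80, concentrations = conc))
  expect_equal(iso$responses, 80 / (1 + 3 / conc), tolerance = 1e-15)
  expect_error(isotherm_sim_params(kd = 3, rmax = 80,
                                   concentrations = c(-1, 2, 3)),
               "positive")
  # noisy generation is seed-deterministic
  p <- isotherm_sim_params(kd = 3, rmax = 80, noise_sd = 2, seed = 7)
  expect_identical(simulate_isotherm(p), simulate_isotherm(p))
})

test_that("background correction is element-wise subtraction", {
  expect_equal(background_correct(c(100, 200), c(10, 20)), c(90, 180))
  expect_equal(background_correct(c(5, 5), c(5, 5)), c(0, 0))
  withr::with_seed(4, { sig <- runif(6, 0, 100); bg <- runif(6, 0, 10) })
  expect_equal(background_correct(sig, bg), sig - bg)
  expect_error(background_correct(1:3, 1:2), "equal length")
})

test_that("fitter recovers noise-free parameters across a KD grid", {
  for (kd in c(0.1, 1, 3.16, 10, 50)) {
    iso <- simulate_isotherm(isotherm_sim_params(kd = kd, rmax = 100))
    fit <- fit_isotherm(iso)
    expect_true(fit$converged)
    expect_lt(abs(fit$kd - kd) / kd, 1e-6)
    expect_lt(abs(fit$rmax - 100) / 100, 1e-6)
  }
})

test_that("fitted KD scales with a common concentration rescaling", {
  conc <- 0.25 * 2^(0:7)
  iso <- simulate_isotherm(isotherm_sim_params(
    kd = 2, rmax = 90, concentrations = conc))
  base <- fit_isotherm(iso)$kd
  scaled <- isotherm(conc * 10, iso$responses)
  expect_equal(fit_isotherm(scaled)$kd / base, 10, tolerance = 1e-6)
})

test_that("degenerate and malformed isotherms are refused", {
  expect_error(isotherm(c(1, 2), c(10, 20)), ">= 3")
  expect_error(isotherm(c(1, 1, 2), c(1, 2, 3)), "distinct")
  flat <- isotherm(c(1, 2, 4), c(50, 50, 50))
  expect_error(fit_isotherm(flat), "flat")
})

test_that("percent of maximal binding", {
  expect_equal(percent_max_binding(80, 80), 100)
  # at C = KD on the exact model, response is half of rmax
  iso <- simulate_isotherm(isotherm_sim_params(
    kd = 4, rmax = 120, concentrations = c(1, 4, 16)))
  expect_equal(percent_max_binding(iso$responses[2], 120), 50)
  withr::with_seed(5, req <- runif(5, 0, 100))
  expect_equal(percent_max_binding(req, 200), 100 * req / 200)
  # linearity in req
  expect_equal(percent_max_binding(2 * req, 200),
               2 * percent_max_binding(req, 200))
  expect_error(percent_max_binding(10, 0), "r_saturation")
})

test_that("fraction bound and its complement", {
  expect_equal(fraction_bound(50, 50), 0.5)
  expect_equal(fraction_bound(0, 30), 1)
  lanes <- data.frame(sup = c(10, 20, 5, 0), pel = c(30, 20, 15, 8))
  fb <- fraction_bound(lanes$sup, lanes$pel)
  expect_equal(fb, c(0.75, 0.5, 0.75, 1))
  expect_equal(fb + fraction_bound(lanes$pel, lanes$sup), rep(1, 4))
  expect_error(fraction_bound(0, 0), "both zero")
})

test_that("kinase fold normalizes to the zero-protein baseline", {
  tab <- data.frame(conc_uM = c(0, 0.5, 1, 2),
                    activity = c(1000, 1400, 2000, 2600))
  out <- kinase_fold(tab)
  expect_equal(out$fold, c(1, 1.4, 2, 2.6))
  expect_equal(out$fold[out$conc_uM == 0], 1)
  # monotone synthetic dose-response stays monotone after normalization
  withr::with_seed(6, act <- cumsum(runif(6, 10, 50)) + 500)
  tab2 <- data.frame(conc_uM = c(0, 0.25, 0.5, 1, 2, 4), activity = act)
  expect_true(all(diff(kinase_fold(tab2)$fold) > 0))
  expect_equal(kinase_fold(tab2)$fold, act / act[1])
  expect_error(kinase_fold(data.frame(conc_uM = c(1, 2),
                                      activity = c(1, 2))), "zero-protein")
  expect_error(kinase_fold(data.frame(conc_uM = c(0, 1),
                                      activity = c(0, 2))), "> 0")
})
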