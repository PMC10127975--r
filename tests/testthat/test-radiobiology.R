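test_that("growth laws evaluate correctly, including the exponential-linear limits", {
  expect_equal(growth_rate(growth_parameters("exponential", a = 0.1), 2), 0.2)
  expect_equal(growth_rate(growth_parameters("logistic", a = 0.5, K = 10), 10), 0)

  el <- growth_parameters("exponential_linear", lambda0 = 0.0118,
                          lambda1 = 0.5007, psi = 20)
  # far beyond the transition volume the rate saturates at lambda1
  v_big <- 1e6 * el$lambda1 / el$lambda0
  expect_rel_equal(growth_rate(el, v_big), el$lambda1, 1e-9)
  # at the transition volume the bracket is exactly 2^(-1/psi)
  v_star <- el$lambda1 / el$lambda0
  expect_equal(growth_rate(el, v_star), el$lambda0 * v_star * 2^(-1 / 20),
               tolerance = 1e-12)
  # small-volume regime reduces to exponential growth at rate lambda0
  ex <- growth_parameters("exponential", a = el$lambda0)
  for (v in c(1e-6, 1e-4, 1e-3) * v_star) {
    expect_rel_equal(growth_rate(el, v), growth_rate(ex, v), 1e-6)
  }
  # stays finite at extreme volumes (log-space bracket)
  expect_true(is.finite(growth_rate(el, 1e300)))
})

test_that("growth parameter validation rejects bad inputs", {
  expect_error(growth_rate(growth_parameters("exponential", a = 0.1), -1),
               ">= 0")
  expect_error(growth_parameters("logistic", a = 0.1), "requires parameter 'K'")
  expect_error(growth_parameters("exponential", a = -0.1), "strictly positive")
  expect_error(growth_parameters("exponential_linear", lambda0 = 0.01,
                                 lambda1 = 0.5, psi = 0.5), "psi")
})

test_that("LQ surviving fraction matches its closed form", {
  r <- p5_rad()
  expect_equal(lq_survival_fraction(r, 0), 1)
  expect_equal(lq_survival_fraction(r, 2), exp(-0.0222 * 2 - 0.00222 * 4),
               tolerance = 1e-15)
  expect_equal(lq_survival_fraction(radiation_parameters(0, 0), 70), 1)
  expect_error(lq_survival_fraction(r, -1), ">= 0")
  # beta defaults to alpha/10 exactly
  expect_identical(r$beta, r$alpha / 10)
  expect_error(radiation_parameters(0.02, epsilon = 0.5), "epsilon")
})

test_that("smoothed Heaviside has the right value, symmetry and tails", {
  eps <- 1e-5
  expect_equal(smooth_heaviside(0, eps), 0.5)
  expect_equal(smooth_heaviside(1e-5, eps), (1 + tanh(1)) / 2, tolerance = 1e-15)
  expect_lt(smooth_heaviside(-1e-4, eps), 3e-9)
  set.seed(11)
  t <- rnorm(100, sd = 1e-4)
  expect_equal(smooth_heaviside(t, eps) + smooth_heaviside(-t, eps),
               rep(1, 100), tolerance = 1e-12)
  expect_true(all(diff(smooth_heaviside(sort(t), eps)) >= 0))
  expect_error(smooth_heaviside(0, 0), "epsilon")
})

test_that("each smoothed treatment window integrates to one LQ kill", {
  eps <- 1e-5
  for (tw in c(1 / 48, 1 / 96, 1 / 144, 1 / 288)) {
    wf <- function(t) (smooth_heaviside(t, eps) - smooth_heaviside(t - tw, eps)) / tw
    # integrate the sharp edges separately so quadrature resolves them
    total <- stats::integrate(wf, -10 * eps, 10 * eps, rel.tol = 1e-10)$value +
      stats::integrate(wf, 10 * eps, tw - 10 * eps, rel.tol = 1e-10)$value +
      stats::integrate(wf, tw - 10 * eps, tw + 10 * eps, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("death rate vanishes off-window, with zero sensitivity, and truncation is exact", {
  r <- p5_rad()
  proto <- treatment_protocol(2, c(3, 4), tw_days = 1 / 96)
  v <- 25
  # midway between the two windows
  expect_lt(abs(death_rate(r, proto, 3.5, v)), 1e-8 * v / proto$tw_days)
  # inside a window the rate is ~ v * kill / tw
  kill <- 1 - lq_survival_fraction(r, 2)
  expect_rel_equal(death_rate(r, proto, 3 + 1 / 192, v), v * kill / proto$tw_days,
                   1e-6)
  expect_equal(death_rate(radiation_parameters(0, 0), proto, 3.005, v), 0)
  # widening the truncation cutoff changes nothing at double precision
  expect_equal(death_rate(r, proto, 3.005, v),
               death_rate(r, proto, 3.005, v, cutoff = 10), tolerance = 1e-14)
  expect_error(treatment_protocol(2, c(3, 3 + 1 / 200), tw_days = 1 / 96),
               "overlap")
})

test_that("treated rhs reduces to growth off-window and is continuous across edges", {
  g <- p5_exp(); r <- p5_rad()
  proto <- single_fraction(tau = 3)
  expect_equal(treated_rhs(g, r, proto, 1.5, 10), growth_rate(g, 10))
  expect_identical(treated_rhs(g, radiation_parameters(0, 0), proto, 3.001, 10),
                   growth_rate(g, 10))
  # continuity probe across the window's leading edge
  eps <- r$epsilon
  tt <- seq(3 - 20 * eps, 3 + 20 * eps, by = eps / 10)
  rhs <- treated_rhs(g, r, proto, tt, 10)
  kill <- 1 - lq_survival_fraction(r, 2)
  lipschitz <- 10 * kill / proto$tw_days / (2 * eps) # v*kill/tw * max dH/dt
  expect_lt(max(abs(diff(rhs))), lipschitz * (eps / 10) * 1.05)
})

test_that("standard fractionation builds weekday-only schedules", {
  p66 <- standard_fractionation(66, 2)
  expect_length(p66$times_days, 33)
  expect_equal(max(p66$times_days), 44)
  p70 <- standard_fractionation(70, 2)
  expect_length(p70$times_days, 35)
  expect_equal(max(p70$times_days), 46)
  expect_equal(standard_fractionation(2, 2, start_day = 5)$times_days, 5)
  # 5-on / 2-off: gaps are 1 day within weeks, 3 days across weekends
  expect_true(all(diff(p66$times_days) %in% c(1, 3)))
  expect_error(standard_fractionation(66, 4), "multiple")
})

test_that("tumour series validation names the offending row", {
  expect_error(tumour_series(c(0, 7, 6), c(1, 2, 3)), "row 3")
  expect_error(tumour_series(c(0, 7), c(1, -2)), "row 2")
  expect_error(tumour_series(c(1, 7), c(1, 2)), "time 0")
})
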