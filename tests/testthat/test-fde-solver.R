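test_that("zero right-hand side gives a constant trajectory at any order", {
  for (mu in c(0.3, 0.7, 1)) {
    tr <- solve_caputo_abm(function(t, v) 0, v0 = 5, t_end = 2, mu = mu, h = 1 / 16)
    expect_equal(tr$volumes, rep(5, length(tr$times)))
  }
})

test_that("mu = 1 reproduces the exponential closed form", {
  tr <- solve_caputo_abm(treated_model(p5_exp(), radiation_parameters(0),
                                       treatment_protocol(0, numeric(0))),
                         v0 = 20, t_end = 10, mu = 1, h = 1 / 288)
  expect_rel_equal(tr$volumes[length(tr$volumes)], 20 * exp(0.118), 1e-4)
})

test_that("fractional growth matches the Mittag-Leffler solution", {
  a <- 0.05
  g <- growth_parameters("exponential", a = a)
  m <- treated_model(g, radiation_parameters(0), treatment_protocol(0, numeric(0)))
  tr <- solve_caputo_abm(m, v0 = 1, t_end = 5, mu = 0.8, h = 1 / 288)
  ref <- mittag_leffler(0.8, a * 5^0.8)
  expect_rel_equal(tr$volumes[length(tr$volumes)], ref, 1e-3)
})

test_that("Mittag-Leffler series matches known identities and guards its domain", {
  expect_equal(mittag_leffler(1, 1), exp(1), tolerance = 1e-12)
  expect_equal(mittag_leffler(1, c(-2, 0.5)), exp(c(-2, 0.5)), tolerance = 1e-12)
  # E_{1/2}(z) = exp(z^2) erfc(-z); erfc(x) = 2 pnorm(-x sqrt(2))
  expect_equal(mittag_leffler(0.5, 1), exp(1) * 2 * pnorm(sqrt(2)),
               tolerance = 1e-10)
  expect_equal(mittag_leffler(0.6, 0), 1)
  expect_error(mittag_leffler(1.2, 1), "mu")
  expect_error(mittag_leffler(0.8, 25), "safety bound")
})

test_that("predictor-corrector matches an independent Volterra-sum oracle", {
  # brute-force re-derivation of the discretized scheme, written directly
  # from the weight formulas with no shared code
  oracle <- function(f, v0, mu, h, N, iters = 1) {
    v <- numeric(N + 1); v[1] <- v0
    fv <- numeric(N + 1); fv[1] <- f(0, v0)
    for (n in 0:(N - 1)) {
      b <- sapply(0:n, function(j) h^mu / mu * ((n + 1 - j)^mu - (n - j)^mu))
      pred <- v0 + sum(b * fv[1:(n + 1)]) / gamma(mu)
      A <- sapply(0:n, function(j) {
        if (j == 0) {
          h^mu / (mu * (mu + 1)) * (n^(mu + 1) - (n - mu) * (n + 1)^mu)
        } else {
          h^mu / (mu * (mu + 1)) *
            ((n - j + 2)^(mu + 1) - 2 * (n - j + 1)^(mu + 1) + (n - j)^(mu + 1))
        }
      })
      a_last <- h^mu / (mu * (mu + 1))
      vc <- pred
      for (it in seq_len(iters)) {
        vc <- v0 + (sum(A * fv[1:(n + 1)]) + a_last * f((n + 1) * h, vc)) / gamma(mu)
      }
      v[n + 2] <- vc
      fv[n + 2] <- f((n + 1) * h, vc)
    }
    v
  }
  f <- function(t, v) 0.3 * v - 0.02 * v^2 + 0.1 * sin(t)
  for (mu in c(0.5, 0.85, 1)) {
    tr <- solve_caputo_abm(f, v0 = 2, t_end = 10 / 16, mu = mu, h = 1 / 16)
    expect_equal(tr$volumes, oracle(f, 2, mu, 1 / 16, 10), tolerance = 1e-12)
  }
  # compiled treated-model path agrees with the R path
  m <- treated_model(growth_parameters("exponential", a = 0.05),
                     radiation_parameters(0.02), single_fraction(tau = 0.25))
  trc <- solve_caputo_abm(m, 10, 0.625, mu = 0.85, h = 1 / 16)
  g <- m$growth; r <- m$radiation
  trr <- solve_caputo_abm(function(t, v) treated_rhs(g, r, m$protocol, t, v),
                          10, 0.625, mu = 0.85, h = 1 / 16)
  expect_equal(trc$volumes, trr$volumes, tolerance = 1e-12)
})

test_that("smaller fractional order slows early growth and stays positive", {
  m <- treated_model(growth_parameters("exponential", a = 0.05),
                     radiation_parameters(0), treatment_protocol(0, numeric(0)))
  ends <- sapply(c(0.6, 0.8, 1), function(mu) {
    tr <- solve_caputo_abm(m, v0 = 10, t_end = 10, mu = mu, h = 1 / 96)
    expect_true(all(tr$volumes > 0))
    tr$volumes[length(tr$volumes)]
  })
  expect_true(all(diff(ends) > 0)) # v(10) increases with mu pre-treatment
})

test_that("halving the step shrinks the error against the Mittag-Leffler oracle", {
  a <- 0.05; mu <- 0.8
  m <- treated_model(growth_parameters("exponential", a = a),
                     radiation_parameters(0), treatment_protocol(0, numeric(0)))
  ref <- mittag_leffler(mu, a * 5^mu)
  errs <- sapply(c(1 / 36, 1 / 72, 1 / 144), function(h) {
    tr <- solve_caputo_abm(m, 1, 5, mu = mu, h = h)
    abs(tr$volumes[length(tr$volumes)] - ref)
  })
  expect_true(all(diff(errs) < 0))
  # empirical order roughly min(2, 1 + mu)
  slope <- mean(log2(errs[-3] / errs[-1]))
  expect_gt(slope, 1)
})

test_that("solver guards orders, states and reports blow-ups with a step index", {
  expect_error(solve_caputo_abm(function(t, v) v, 1, 1, mu = 1.5), "\\(0, 1\\]")
  expect_error(solve_caputo_abm(function(t, v) v, -1, 1), "v0")
  expect_error(solve_caputo_abm(function(t, v) v^4, 1e3, 5, h = 1 / 8), "step")
  expect_warning(solve_caputo_abm(function(t, v) -5, 1, 2, h = 1 / 8),
                 "negative")
})

test_that("impulsive solver matches piecewise closed forms and refuses mu < 1", {
  g <- growth_parameters("exponential", a = 0.05)
  r <- p5_rad()
  # no fractions: pure growth
  tr <- solve_impulsive(g, r, treatment_protocol(2, numeric(0)), 10, 4)
  expect_rel_equal(tr$volumes[length(tr$volumes)], 10 * exp(0.2), 1e-8)
  # single fraction: v0 e^{aT} SF
  proto <- single_fraction(tau = 3)
  sf <- lq_survival_fraction(r, 2)
  tr <- solve_impulsive(g, r, proto, 10, 6)
  expect_rel_equal(tr$volumes[length(tr$volumes)], 10 * exp(0.3) * sf, 1e-6)
  # pre- and post-impulse values recorded at tau
  at_tau <- tr$volumes[tr$times == 3]
  expect_length(at_tau, 2)
  expect_rel_equal(at_tau[2] / at_tau[1], sf, 1e-9)
  # full course with zero sensitivity equals untreated growth
  p66 <- course_66gy(gap = 0)
  tr0 <- solve_impulsive(g, radiation_parameters(0), p66, 10, 45)
  expect_rel_equal(tr0$volumes[length(tr0$volumes)], 10 * exp(0.05 * 45), 1e-7)
  expect_error(solve_impulsive(g, r, proto, 10, 6, mu = 0.9), "mu = 1")
})

test_that("mu = 1 predictor-corrector agrees with the adaptive continuous-death solver", {
  g <- p5_exp(); r <- p5_rad()
  proto <- treatment_protocol(2, c(2, 3, 4), tw_days = 1 / 96)
  tr1 <- solve_caputo_abm(treated_model(g, r, proto), 20, 6, mu = 1, h = 1 / 288)
  tr2 <- radgrowth:::solve_continuous_rk45(g, r, proto, 20, 6,
                                           sample_times = c(1, 2.5, 5, 6))
  expect_rel_equal(trajectory_at(tr1, c(1, 2.5, 5, 6)),
                   tr2$volumes[match(c(1, 2.5, 5, 6), tr2$times)], 1e-5)
})

test_that("continuous death approaches its impulsive-model floor as tw shrinks", {
  g <- growth_parameters("exponential", a = 0.05)
  r <- p5_rad()
  proto <- single_fraction(tau = 3)
  tab <- compare_death_models(g, r, proto, v0 = 10, t_end = 6,
                              tw_list = c(1 / 48, 1 / 96, 1 / 288))
  # For a linear (exponential) law the off-window deviation is analytically
  # tw-independent: the shrinking-window limit multiplies by e^{SF-1}, the
  # impulsive model by SF, so the gap sits at the (1-SF)^2/2 floor.
  # "Non-increasing" therefore holds only up to solver tolerance.
  expect_true(all(diff(tab$max_deviation) <= 1e-5 * 10))
  kill <- 1 - lq_survival_fraction(r, 2)
  floor_dev <- (exp(-kill) - (1 - kill)) * 10 * exp(0.05 * 6)
  expect_rel_equal(tab$max_deviation, floor_dev, 0.01)
  # zero dose effect: deviation at solver-tolerance level only
  tab0 <- compare_death_models(g, radiation_parameters(0, 0), proto, 10, 6,
                               tw_list = c(1 / 48, 1 / 96))
  expect_lt(max(tab0$max_deviation), 1e-5)
  expect_error(compare_death_models(g, r, proto, 10, 6, tw_list = c(1 / 96, 1 / 48)),
               "decreasing")
})

test_that("for a nonlinear law the shrinking window converges with order >= 1", {
  # the delta-function limit is only reached at rate O(tw) when growth and
  # kill interact nonlinearly; check a logistic case with strong kill
  g <- growth_parameters("logistic", a = 0.5, K = 12)
  r <- radiation_parameters(0.3, 0.03)
  end_vol <- function(tw, h_frac = 8) {
    pr <- treatment_protocol(2, 3, tw_days = tw)
    tr <- solve_caputo_abm(treated_model(g, r, pr), 10, 6, mu = 1, h = tw / h_frac)
    tr$volumes[length(tr$volumes)]
  }
  ref <- end_vol(1 / 768)
  devs <- abs(sapply(c(1 / 12, 1 / 24, 1 / 48, 1 / 96), end_vol) - ref)
  expect_true(all(diff(devs) < 0))
  orders <- log2(devs[-length(devs)] / devs[-1])
  expect_gt(mean(orders), 1)
})
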