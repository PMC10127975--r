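# Shared fixtures: the worked-example parameter set (median-SSR patient of
# the reference cohort) and small protocols used across tests.

p5_exp <- function() growth_parameters("exponential", a = 0.0118)
p5_rad <- function() radiation_parameters(alpha = 0.0222)

single_fraction <- function(tau = 3, tw = 1 / 96, dose = 2) {
  treatment_protocol(dose, tau, tw)
}

course_66gy <- function(gap = 7, tw = 1 / 96) {
  standard_fractionation(66, 2, start_day = gap, tw_days = tw)
}

# closed-form treated exponential + impulsive kill at measurement times
exp_impulsive_closed_form <- function(a, alpha, v0, times, taus, dose = 2,
                                      beta = alpha / 10) {
  sf <- exp(-alpha * dose - beta * dose^2)
  vapply(times, function(t) v0 * exp(a * t) * sf^sum(taus < t), numeric(1))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), rel_tol)
}
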