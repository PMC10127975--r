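#' Synthetic cohort configuration
#'
#' Describes a virtual radiotherapy cohort with the structure of the clinical
#' dataset the package's methods were designed around: curative head-and-neck
#' courses of 66-70 Gy in 2 Gy weekday fractions, volumes measured at
#' planning (day 0), immediately before the first fraction (after a
#' planning-to-treatment gap), weekly during treatment, and finally on the
#' last treatment day. Ground-truth parameters are drawn uniformly from the
#' published cohort min-max ranges for the generating law (see
#' [reference_parameter_ranges()]), independently across parameters and
#' patients. Measurement noise is multiplicative lognormal with scale
#' `sigma`, a declared stand-in for an unreported clinical error model.
#'
#' @param n_patients Cohort size. Default 19.
#' @param law Generating growth law. Default `"exponential"`.
#' @param mu Fractional order of the generating model; `NULL` (default) for
#'   the ordinary model.
#' @param param_ranges Named list of `c(min, max)` sampling ranges for the
#'   law's parameters plus `alpha`; defaults to the published cohort ranges.
#' @param v0_range Initial (planning) volume range, cm^3. Default c(5, 50).
#' @param gap_days Planning-to-treatment gap. Default 7.
#' @param fraction_time_of_day Time of day (fraction of a day) at which each
#'   fraction is delivered. Default 0.5 (midday): measurements taken on
#'   treatment days precede the day's fraction, and the trajectory is never
#'   sampled exactly at a treatment-window edge, where a fixed-step solution
#'   carries an O(kill * h / tw) discretization smear.
#' @param total_dose_choices Total dose options (Gy). Default c(66, 68, 70).
#' @param dose_per_fraction Gy per fraction. Default 2.
#' @param sigma Lognormal noise scale. Default 0.05.
#' @param seed Cohort-level RNG seed.
#' @param h Solver step for the generating simulation. Default 1/288.
#' @param tw Treatment window length (days). Default 1/96.
#' @param epsilon Heaviside smoothing width. Default 1e-5.
#' @param psi Exponential-linear transition sharpness. Default 20.
#' @param alpha_beta_ratio Fixed alpha/beta ratio (Gy). Default 10.
#' @param k_factor Logistic carrying capacity as a multiple of v0. Default 2.
#' @return An object of class `rg_cohort_config`.
#' @export
cohort_config <- function(n_patients = 19, law = "exponential", mu = NULL,
                          param_ranges = NULL, v0_range = c(5, 50),
                          gap_days = 7, fraction_time_of_day = 0.5,
                          total_dose_choices = c(66, 68, 70),
                          dose_per_fraction = 2, sigma = 0.05, seed = 1,
                          h = 1 / 288, tw = 1 / 96, epsilon = 1e-5, psi = 20,
                          alpha_beta_ratio = 10, k_factor = 2) {
  law <- match.arg(law, c("exponential", "logistic", "exponential_linear"))
  if (is.null(param_ranges)) {
    param_ranges <- default_param_ranges(law, fractional = !is.null(mu))
  }
  structure(list(n_patients = as.integer(n_patients), law = law, mu = mu,
                 param_ranges = param_ranges, v0_range = v0_range,
                 gap_days = gap_days,
                 fraction_time_of_day = fraction_time_of_day,
                 total_dose_choices = total_dose_choices,
                 dose_per_fraction = dose_per_fraction, sigma = sigma,
                 seed = as.integer(seed), h = h, tw = tw, epsilon = epsilon,
                 psi = psi, alpha_beta_ratio = alpha_beta_ratio,
                 k_factor = k_factor),
            class = "rg_cohort_config")
}

default_param_ranges <- function(law, fractional = FALSE) {
  rr <- reference_parameter_ranges()
  model <- paste0(if (fractional) "fractional_" else "", law)
  rows <- rr[rr$model == model & rr$parameter != "mu", ]
  out <- lapply(seq_len(nrow(rows)), function(i) c(rows$min[i], rows$max[i]))
  names(out) <- rows$parameter
  out
}

measurement_days <- function(proto, gap_days) {
  last <- floor(max(proto$times_days)) # the last treatment day (fractions
  weekly <- if (gap_days + 7 <= last - 1) { # may be delivered mid-day)
    seq(gap_days + 7, last - 1, by = 7)
  } else numeric(0)
  sort(unique(c(0, gap_days, weekly, last)))
}

#' Generate one synthetic patient
#'
#' Simulates the generating model with the package solver, samples the
#' trajectory at the cohort's measurement days, applies multiplicative
#' lognormal noise, and returns the noisy series together with the protocol
#' and the ground truth. Fully reproducible for a given seed. If a simulated
#' pre-noise volume is non-positive (possible for strongly fractional
#' dynamics), the draw is rejected and resampled with a shifted seed, with a
#' warning.
#'
#' @param config An [cohort_config()] object.
#' @param seed Patient-level seed.
#' @return A list with elements `series` ([tumour_series()]), `protocol`
#'   ([treatment_protocol()]), and `truth` (sampled parameters, v0, total
#'   dose, mu, seed).
#' @export
generate_patient <- function(config, seed) {
  stopifnot(inherits(config, "rg_cohort_config"))
  for (attempt in 0:19) {
    set.seed(seed + 1000000L * attempt)
    draw <- lapply(config$param_ranges, function(rg) runif(1, rg[1], rg[2]))
    v0 <- runif(1, config$v0_range[1], config$v0_range[2])
    total <- config$total_dose_choices[sample.int(length(config$total_dose_choices), 1)]
    noise_mult <- NULL # drawn after simulation so rejection resamples all
    proto <- standard_fractionation(total, config$dose_per_fraction,
                                    start_day = config$gap_days +
                                      config$fraction_time_of_day,
                                    tw_days = config$tw)
    growth <- switch(config$law,
      exponential = growth_parameters("exponential", a = draw$a),
      logistic = growth_parameters("logistic", a = draw$a,
                                   K = config$k_factor * v0),
      exponential_linear = growth_parameters("exponential_linear",
                                             lambda0 = draw$lambda0,
                                             lambda1 = draw$lambda1,
                                             psi = config$psi))
    radiation <- radiation_parameters(draw$alpha,
                                      draw$alpha / config$alpha_beta_ratio,
                                      config$epsilon)
    mu <- if (is.null(config$mu)) 1 else config$mu
    days <- measurement_days(proto, config$gap_days)
    traj <- solve_caputo_abm(treated_model(growth, radiation, proto), v0,
                             max(days), mu = mu, h = config$h)
    v_true <- trajectory_at(traj, days)
    if (any(v_true <= 0)) {
      warning("generate_patient: non-positive simulated volume; resampling ",
              "(seed ", seed, ", attempt ", attempt + 1, ")", call. = FALSE)
      next
    }
    noise_mult <- exp(rnorm(length(days), 0, config$sigma))
    series <- tumour_series(days, v_true * noise_mult)
    return(list(series = series, protocol = proto,
                truth = c(draw, list(v0 = v0, total_dose = total, mu = mu,
                                     seed = seed, true_volumes = v_true))))
  }
  stop("generate_patient: could not generate a positive trajectory in 20 attempts",
       call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' Applies [generate_patient()] over deterministic per-patient seed
#' substreams and assembles a manifest of the configuration, seeds and
#' ground truth. Optionally writes per-patient CSV series, JSON protocols
#' and a JSON manifest to a directory.
#'
#' @param config An [cohort_config()] object.
#' @param out_dir Optional output directory (created if missing).
#' @return A list: `patients` (list of [generate_patient()] results) and
#'   `manifest` (config echo, per-patient seeds and truths).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "rg_cohort_config"))
  seeds <- config$seed + 7919L * seq_len(config$n_patients)
  patients <- lapply(seeds, function(s) generate_patient(config, s))
  manifest <- list(config = unclass(config),
                   package_version = as.character(packageVersion("radgrowth")),
                   patient_seeds = seeds,
                   truth = lapply(patients, function(p)
                     p$truth[setdiff(names(p$truth), "true_volumes")]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(patients)) {
      tag <- sprintf("%02d", i)
      write_tumour_series(patients[[i]]$series,
                          file.path(out_dir, paste0("patient_", tag, ".csv")))
      write_protocol(patients[[i]]$protocol,
                     file.path(out_dir, paste0("protocol_", tag, ".json")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(patients = patients, manifest = manifest)
}
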