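test_that("patient generation is deterministic and respects the stated world", {
  cfg <- cohort_config(seed = 9)
  p1 <- generate_patient(cfg, 901)
  p2 <- generate_patient(cfg, 901)
  expect_identical(p1$series$volumes, p2$series$volumes)
  expect_identical(p1$truth, p2$truth)
  # measurement schedule: planning, first-fraction day, weekly, last day
  expect_equal(p1$series$times[1:2], c(0, cfg$gap_days))
  # final measurement falls on the last treatment day, before its fraction
  expect_equal(max(p1$series$times), floor(max(p1$protocol$times_days)))
  expect_equal(max(p1$protocol$times_days) - floor(max(p1$protocol$times_days)),
               cfg$fraction_time_of_day)
  expect_true(length(p1$series$times) >= 7 && length(p1$series$times) <= 9)
  # weekday protocol invariants
  expect_true(all(diff(p1$protocol$times_days) %in% c(1, 3)))
  expect_true(p1$truth$total_dose %in% c(66, 68, 70))
  # sampled parameters inside the published ranges (= fitting bounds)
  expect_true(p1$truth$a >= 0.0010 && p1$truth$a <= 0.0404)
  expect_true(p1$truth$alpha >= 0.0048 && p1$truth$alpha <= 0.0450)
})

test_that("noiseless generation lies exactly on the model curve", {
  cfg <- cohort_config(sigma = 0, seed = 10)
  p <- generate_patient(cfg, 1001)
  expect_equal(p$series$volumes, p$truth$true_volumes, tolerance = 1e-12)
})

test_that("noise calibration: residual coefficient of variation matches sigma", {
  cfg <- cohort_config(n_patients = 60, sigma = 0.05, seed = 11)
  coh <- generate_cohort(cfg)
  logres <- unlist(lapply(coh$patients, function(p)
    log(p$series$volumes / p$truth$true_volumes)))
  expect_rel_equal(sd(logres), 0.05, 0.10)
})

test_that("cohort generation writes complete file sets and a manifest", {
  dir <- tempfile("cohort")
  cfg <- cohort_config(n_patients = 3, seed = 12)
  coh <- generate_cohort(cfg, out_dir = dir)
  expect_length(coh$patients, 3)
  expect_true(file.exists(file.path(dir, "patient_02.csv")))
  expect_true(file.exists(file.path(dir, "protocol_03.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_length(man$patient_seeds, 3)
  expect_equal(man$config$sigma, 0.05)
  # round trip through the files reproduces the in-memory objects
  s2 <- read_tumour_series(file.path(dir, "patient_01.csv"))
  expect_equal(s2$volumes, coh$patients[[1]]$series$volumes, tolerance = 1e-12)
  pr2 <- read_protocol(file.path(dir, "protocol_01.json"))
  expect_equal(pr2$times_days, coh$patients[[1]]$protocol$times_days)
  unlink(dir, recursive = TRUE)
})

test_that("the generating model class wins the information-criterion comparison", {
  # ordinary-exponential cohort: the exponential model should out-rank the
  # fractional variant once its parameter-count penalty applies
  cfg <- cohort_config(n_patients = 4, sigma = 0.01, seed = 13, h = 1 / 96)
  coh <- generate_cohort(cfg)
  tabs <- lapply(seq_along(coh$patients), function(i) {
    p <- coh$patients[[i]]
    fo <- fit_model(p$series, "exponential", FALSE, p$protocol,
                    fit_config(n_starts = 3, seed = 130 + i, h = 1 / 96))
    ff <- fit_model(p$series, "exponential", TRUE, p$protocol,
                    fit_config(n_starts = 2, seed = 160 + i, h = 1 / 96))
    comparison_table(list(exponential = fo, fractional_exponential = ff),
                     patient = i)
  })
  summ <- cohort_summary(tabs)
  expect_lt(summ$mean_delta_aicc[summ$model == "exponential"],
            summ$mean_delta_aicc[summ$model == "fractional_exponential"])

  # strongly fractional generator at low noise: the fractional model wins
  cfgf <- cohort_config(n_patients = 3, sigma = 0.01, mu = 0.9, seed = 14,
                        h = 1 / 96)
  cohf <- generate_cohort(cfgf)
  tabsf <- lapply(seq_along(cohf$patients), function(i) {
    p <- cohf$patients[[i]]
    fo <- fit_model(p$series, "exponential", FALSE, p$protocol,
                    fit_config(n_starts = 3, seed = 140 + i, h = 1 / 96))
    ff <- fit_model(p$series, "exponential", TRUE, p$protocol,
                    fit_config(n_starts = 2, seed = 170 + i, h = 1 / 96))
    comparison_table(list(exponential = fo, fractional_exponential = ff),
                     patient = i)
  })
  summf <- cohort_summary(tabsf)
  expect_lt(summf$mean_delta_aicc[summf$model == "fractional_exponential"],
            summf$mean_delta_aicc[summf$model == "exponential"])
})
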