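# Published summary numbers from the 19-patient head-and-neck radiotherapy
# cohort study the package's methodology reproduces. The raw patient series
# were never deposited; these printed summaries are the only anchors
# available and are used as inputs (sampling ranges, regression checks).

#' Published per-patient AICc deltas for the reference cohort
#'
#' The AICc Delta_i values (2 d.p.) for all six candidate models across the
#' 19 patients of the published head-and-neck cohort, as printed in the
#' original comparison table. Row order is patient 1-19; columns are the six
#' models.
#'
#' @return A 19 x 6 numeric matrix with model names as columns.
#' @export
reference_aicc_deltas <- function() {
  path <- system.file("extdata", "reference_aicc_deltas.csv",
                      package = "radgrowth", mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- paste0("patient_", tab$patient)
  m
}

#' Published fitted-parameter ranges for the reference cohort
#'
#' Min and max of each fitted parameter over the 19 patients, per model, as
#' printed in the original fit-summary table. These ranges seed the uniform
#' sampling priors of the synthetic cohort generator.
#'
#' @return A data.frame with columns `model`, `parameter`, `min`, `max`.
#' @export
reference_parameter_ranges <- function() {
  data.frame(
    model = c(rep("exponential", 2), rep("fractional_exponential", 3),
              rep("logistic", 2), rep("fractional_logistic", 3),
              rep("exponential_linear", 3),
              rep("fractional_exponential_linear", 4)),
    parameter = c("a", "alpha",
                  "a", "alpha", "mu",
                  "a", "alpha",
                  "a", "alpha", "mu",
                  "lambda0", "lambda1", "alpha",
                  "lambda0", "lambda1", "alpha", "mu"),
    min = c(0.0010, 0.0048,
            0.0010, 0.0048, 0.7880,
            0.0010, 0.0049,
            0.0010, 0.0049, 0.8605,
            0.0018, 0.0010, 0.0048,
            0.0018, 0.0010, 0.0048, 0.8678),
    max = c(0.0404, 0.0450,
            0.0632, 0.0964, 1.0000,
            0.0919, 0.0533,
            0.0920, 0.0534, 1.0000,
            0.4985, 1.0000, 0.0521,
            0.0653, 1.0000, 0.0568, 1.0000))
}

#' Published patient-5 best-fit parameters
#'
#' The fitted parameter values for the reference cohort's patient 5 (the
#' patient with median SSR, used throughout the original analysis as the
#' worked example), per model.
#'
#' @return A named list of named numeric vectors, one per model.
#' @export
reference_patient5_fits <- function() {
  list(
    exponential = c(a = 0.0118, alpha = 0.0222),
    fractional_exponential = c(a = 0.0118, alpha = 0.0222, mu = 1),
    logistic = c(a = 0.0168, alpha = 0.0203),
    fractional_logistic = c(a = 0.0168, alpha = 0.0203, mu = 1),
    exponential_linear = c(lambda0 = 0.0118, lambda1 = 0.5007, alpha = 0.0222),
    fractional_exponential_linear = c(lambda0 = 0.0118, lambda1 = 0.5874,
                                      alpha = 0.0222, mu = 1)
  )
}
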