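#' Corrected Akaike information criterion from an SSR fit
#'
#' AICc = n ln(SSR/n) + 2k + 2k(k+1)/(n - k - 1), the least-squares form with
#' the small-sample correction term. Requires n >= k + 2 so the correction
#' denominator is positive.
#'
#' @param ssr Sum of squared residuals, > 0.
#' @param n Number of data points.
#' @param k Number of fitted parameters.
#' @return AICc score (lower is better).
#' @export
aicc <- function(ssr, n, k) {
  check_ic_inputs(ssr, n, k)
  if (n <= k + 1) {
    stop("aicc: undefined for n <= k + 1 (correction denominator)", call. = FALSE)
  }
  n * log(ssr / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Bayesian information criterion from an SSR fit
#'
#' BIC = n ln(SSR/n) + k ln(n).
#'
#' @inheritParams aicc
#' @return BIC score (lower is better).
#' @export
bic <- function(ssr, n, k) {
  check_ic_inputs(ssr, n, k)
  n * log(ssr / n) + k * log(n)
}

check_ic_inputs <- function(ssr, n, k) {
  if (!is.finite(ssr) || ssr < 0) stop("information criterion: SSR must be >= 0",
                                       call. = FALSE)
  if (ssr == 0) {
    stop("information criterion: SSR is exactly 0; the log-likelihood is ",
         "unbounded (model interpolates the data)", call. = FALSE)
  }
  if (n < 1 || k < 0) stop("information criterion: invalid n or k", call. = FALSE)
  invisible(TRUE)
}

#' Criterion differences from the best model
#'
#' Delta_i = score_i - min(score); at least one entry is exactly 0.
#'
#' @param scores Numeric vector (optionally named) of AICc or BIC scores.
#' @return Deltas, same names.
#' @export
deltas <- function(scores) {
  if (!length(scores)) stop("deltas: empty score vector", call. = FALSE)
  scores - min(scores)
}

#' Akaike weights from criterion differences
#'
#' w_i = exp(-Delta_i/2) / sum_r exp(-Delta_r/2): the normalized evidence
#' weight of each candidate model; the weights sum to 1.
#'
#' @param d Non-negative deltas (from [deltas()]).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(d) {
  if (any(d < 0)) stop("akaike_weights: deltas must be >= 0", call. = FALSE)
  l <- exp(-d / 2)
  l / sum(l)
}

#' Rank models by criterion difference, averaging ties
#'
#' Ascending competition ranks on the deltas; models whose deltas agree
#' within `tie_tol` share the average of the positions they occupy (two
#' models tied for third and fourth place both rank 3.5). The default
#' tolerance of 5e-3 treats values equal at 2-decimal printing as tied.
#'
#' @param d Criterion deltas.
#' @param tie_tol Absolute tolerance below which deltas are tied.
#' @return Ranks (average-of-positions for ties), same order as input.
#' @export
#' @examples
#' rank_models(c(0, 5.60, 1.33, 6.93, 5.60, 14.93))  # 1 3.5 2 5 3.5 6
rank_models <- function(d, tie_tol = 5e-3) {
  if (!length(d)) return(numeric(0))
  o <- order(d)
  sorted <- d[o]
  grp <- cumsum(c(1, diff(sorted) > tie_tol))
  pos <- seq_along(sorted)
  avg <- stats::ave(pos, grp)
  ranks <- numeric(length(d))
  ranks[o] <- avg
  names(ranks) <- names(d)
  ranks
}

#' Per-patient model comparison table
#'
#' Builds the AICc/BIC comparison for one patient from a consistent set of
#' fits (or directly from SSR/n/k triplets): scores, deltas, Akaike weights
#' (from the AICc deltas) and tie-averaged ranks for both criteria.
#'
#' @param fits Named list of `rg_fit` objects for one patient.
#' @param patient Optional patient identifier carried into the table.
#' @param tie_tol Passed to [rank_models()].
#' @return An `rg_comparison` data.frame with one row per model.
#' @export
comparison_table <- function(fits, patient = NA, tie_tol = 5e-3) {
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    stop("comparison_table: 'fits' must be a named list", call. = FALSE)
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("comparison_table: fits disagree on n", call. = FALSE)
  }
  a <- vapply(fits, function(f) aicc(f$ssr, f$n, f$k), numeric(1))
  b <- vapply(fits, function(f) bic(f$ssr, f$n, f$k), numeric(1))
  da <- deltas(a); db <- deltas(b)
  out <- data.frame(patient = patient, model = names(fits),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    ssr = vapply(fits, function(f) f$ssr, numeric(1)),
                    n = ns, aicc = a, bic = b,
                    delta_aicc = da, delta_bic = db,
                    weight = akaike_weights(da),
                    rank_aicc = rank_models(da, tie_tol),
                    rank_bic = rank_models(db, tie_tol),
                    row.names = NULL)
  class(out) <- c("rg_comparison", "data.frame")
  out
}

#' Comparison table from precomputed criterion deltas
#'
#' Convenience constructor for working with published delta tables: computes
#' weights and tie-averaged ranks from a vector of AICc deltas.
#'
#' @param d Named vector of AICc deltas for one patient.
#' @param patient Optional identifier.
#' @param tie_tol Passed to [rank_models()].
#' @return An `rg_comparison` data.frame.
#' @export
comparison_from_deltas <- function(d, patient = NA, tie_tol = 5e-3) {
  if (is.null(names(d))) names(d) <- paste0("model_", seq_along(d))
  out <- data.frame(patient = patient, model = names(d), delta_aicc = as.numeric(d),
                    weight = akaike_weights(as.numeric(d)),
                    rank_aicc = rank_models(as.numeric(d), tie_tol),
                    row.names = NULL)
  class(out) <- c("rg_comparison", "data.frame")
  out
}

#' Cohort-level model-selection summary
#'
#' Column means of the deltas and weights plus the rank tally (sum of the
#' tie-averaged per-patient ranks) for each model across patients; lower
#' tallies indicate better overall standing.
#'
#' @param tables List of `rg_comparison` tables with identical model sets.
#' @return A data.frame with one row per model: mean delta, rank tally, mean
#'   weight (if present), ordered as in the input tables.
#' @export
cohort_summary <- function(tables) {
  if (!length(tables)) stop("cohort_summary: no tables", call. = FALSE)
  models <- tables[[1]]$model
  for (tb in tables) {
    if (!identical(tb$model, models)) {
      stop("cohort_summary: inconsistent model sets across patients", call. = FALSE)
    }
  }
  get <- function(col) if (col %in% names(tables[[1]]))
    sapply(tables, function(tb) tb[[col]]) else NULL
  da <- get("delta_aicc"); rk <- get("rank_aicc"); w <- get("weight")
  db <- get("delta_bic"); rkb <- get("rank_bic")
  as_mat <- function(x) matrix(x, nrow = length(models))
  out <- data.frame(model = models,
                    mean_delta_aicc = rowMeans(as_mat(da)),
                    aicc_tally = rowSums(as_mat(rk)))
  if (!is.null(w)) out$mean_weight <- rowMeans(as_mat(w))
  if (!is.null(db)) {
    out$mean_delta_bic <- rowMeans(as_mat(db))
    out$bic_tally <- rowSums(as_mat(rkb))
  }
  out
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  cdf <- pnorm(z)
  max(max((1:n) / n - cdf), max(cdf - (0:(n - 1)) / n))
}

#' Residual normality checks (Lilliefors and Shapiro-Wilk)
#'
#' Information-criterion comparisons assume normally distributed residuals;
#' this verifies that assumption. The Lilliefors statistic (Kolmogorov-
#' Smirnov distance with mean and variance estimated from the sample) is
#' calibrated by a seeded Monte-Carlo null of standard-normal samples rather
#' than by published critical-value tables; the Shapiro-Wilk test comes from
#' [stats::shapiro.test()].
#'
#' @param residuals Numeric vector, length >= 4.
#' @param n_mc Monte-Carlo null size for the Lilliefors p-value. Default 1e4.
#' @param seed RNG seed for the null draw.
#' @param alpha Significance level for the pass/fail flag. Default 0.05.
#' @return A list: `lilliefors_stat`, `lilliefors_p`, `shapiro_stat`,
#'   `shapiro_p`, and `normal` (TRUE if neither test rejects at `alpha`).
#' @export
residual_normality <- function(residuals, n_mc = 1e4, seed = 1, alpha = 0.05) {
  n <- length(residuals)
  if (n < 4) {
    stop("residual_normality: at least 4 residuals are required", call. = FALSE)
  }
  obs <- lilliefors_stat(residuals)
  set.seed(seed)
  null_mat <- matrix(rnorm(n * n_mc), nrow = n)
  z <- apply(null_mat, 2, function(col) sort((col - mean(col)) / sd(col)))
  cdf <- pnorm(z)
  up <- (1:n) / n - cdf
  lo <- cdf - (0:(n - 1)) / n
  null_d <- pmax(apply(up, 2, max), apply(lo, 2, max))
  p_lil <- (1 + sum(null_d >= obs)) / (n_mc + 1)
  sw <- shapiro.test(residuals)
  list(lilliefors_stat = obs, lilliefors_p = p_lil,
       shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value,
       normal = p_lil >= alpha && sw$p.value >= alpha)
}
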