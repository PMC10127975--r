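#' Read a tumour-volume time series from CSV
#'
#' Expects a two-column CSV with a one-line header `day,volume_cm3`.
#' Validation failures name the offending row.
#'
#' @param path CSV path.
#' @return An [tumour_series()] object.
#' @export
read_tumour_series <- function(path) {
  tab <- read.csv(path)
  if (ncol(tab) < 2) {
    stop("read_tumour_series: expected columns 'day' and 'volume_cm3' in ",
         path, call. = FALSE)
  }
  if (!all(c("day", "volume_cm3") %in% names(tab))) {
    stop("read_tumour_series: malformed header in ", path,
         " (expected 'day,volume_cm3')", call. = FALSE)
  }
  tumour_series(tab$day, tab$volume_cm3)
}

#' Write a tumour-volume time series to CSV
#'
#' @param x An [tumour_series()] object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tumour_series <- function(x, path) {
  stopifnot(inherits(x, "rg_series"))
  write.csv(data.frame(day = x$times, volume_cm3 = x$volumes), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

protocol_to_list <- function(p) {
  list(dose_gy = p$dose_gy, times_days = p$times_days, tw_days = p$tw_days)
}

#' Write a treatment protocol to JSON or YAML
#'
#' The format follows the file extension: `.json` (default) or `.yaml`/`.yml`.
#' Fields: `dose_gy`, `times_days`, `tw_days`.
#'
#' @param p An [treatment_protocol()] object.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "rg_protocol"))
  lst <- protocol_to_list(p)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path, precision = 15)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a treatment protocol from JSON or YAML
#'
#' @param path Source path (`.json`, `.yaml` or `.yml`).
#' @return An [treatment_protocol()] object.
#' @export
read_protocol <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (f in c("dose_gy", "times_days", "tw_days")) {
    if (is.null(lst[[f]])) {
      stop("read_protocol: missing field '", f, "' in ", path, call. = FALSE)
    }
  }
  treatment_protocol(lst$dose_gy, unlist(lst$times_days), lst$tw_days)
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted parameters, SSR, n, k, convergence information, the
#' protocol, and a full echo of the fitting configuration (provenance).
#'
#' @param fit An `rg_fit`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "rg_fit"))
  lst <- list(law = fit$law, fractional = fit$fractional,
              parameters = fit$parameters, fitted_names = fit$fitted_names,
              ssr = fit$ssr, n = fit$n, k = fit$k, v0 = fit$v0,
              best_start = fit$best_start, converged = fit$converged,
              n_failed_starts = fit$n_failed_starts, seed = fit$seed,
              protocol = protocol_to_list(fit$protocol),
              config = unclass(fit$config),
              package_version = as.character(packageVersion("radgrowth")))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path Source path.
#' @return An `rg_fit` object.
#' @export
read_fit <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  proto <- treatment_protocol(lst$protocol$dose_gy,
                              unlist(lst$protocol$times_days),
                              lst$protocol$tw_days)
  cfg <- do.call(fit_config, lst$config[names(lst$config) %in%
                                          names(formals(fit_config))])
  structure(list(law = lst$law, fractional = lst$fractional,
                 parameters = as.list(lst$parameters),
                 fitted_names = unlist(lst$fitted_names), ssr = lst$ssr,
                 n = lst$n, k = lst$k, v0 = lst$v0,
                 best_start = lst$best_start, converged = lst$converged,
                 n_failed_starts = lst$n_failed_starts, seed = lst$seed,
                 protocol = proto, config = cfg),
            class = "rg_fit")
}

#' Write comparison tables to CSV
#'
#' @param tables An `rg_comparison` data.frame or a list of them (rows are
#'   concatenated).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tables, path) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  out <- do.call(rbind, lapply(tables, as.data.frame))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repeated-fit benchmark of the three radiation-effect implementations
#'
#' Runs `M` independent single-start fits of the exponential treated model to
#' one patient's data for a chosen implementation of the radiation effect:
#' the smooth (tanh-window) continuous death rate, the discontinuous
#' (hard-Heaviside) death rate, or the impulsive stop-and-restart model.
#' Start values are drawn uniformly (a in [0, 0.2], alpha in [0, 0.1]) per
#' instance. Reports wall and CPU time per fit, the best SSR, the per-
#' instance results, and the "consensus": the fraction of successful
#' instances whose SSR lies within `ssr_tol` (relative) of the best.
#'
#' Timings are machine-dependent and are reported, never asserted. The
#' hard-Heaviside variant exists only for this comparison; it is incredibly
#' slow under adaptive stepping and not recommended, and instances whose
#' integration fails are reported as failed repetitions rather than raising.
#'
#' @param variant One of `"death_rate_smooth"`, `"death_rate_hard"`,
#'   `"impulsive"`.
#' @param data An [tumour_series()] object.
#' @param proto A [treatment_protocol()] object.
#' @param M Number of fitting instances. Default 1.
#' @param seed RNG seed.
#' @param solver `"fixed_step"` (predictor-corrector at mu = 1) or
#'   `"adaptive"` (RK45 with bounded max step). Default `"fixed_step"`; the
#'   hard variant under `"adaptive"` may fail by step-size underflow.
#' @param h Fixed step / maximum adaptive step (days). Default 1/288.
#' @param ssr_tol Relative SSR tolerance defining consensus. Default 0.05.
#' @param alpha_beta_ratio,epsilon,maxit As in [fit_config()].
#' @return A list of class `rg_benchmark`: per-instance data.frame and
#'   summary fields (times per fit, best SSR and parameters, consensus).
#' @export
benchmark_fit <- function(variant = c("death_rate_smooth", "death_rate_hard",
                                      "impulsive"),
                          data, proto, M = 1, seed = 1,
                          solver = c("fixed_step", "adaptive"), h = 1 / 288,
                          ssr_tol = 0.05, alpha_beta_ratio = 10,
                          epsilon = 1e-5, maxit = 200) {
  variant <- match.arg(variant)
  solver <- match.arg(solver)
  stopifnot(inherits(data, "rg_series"), M >= 1)
  v0 <- data$volumes[1]
  t_end <- max(data$times)
  hard <- variant == "death_rate_hard"

  simulate <- function(a, alpha) {
    g <- growth_parameters("exponential", a = a)
    r <- radiation_parameters(alpha, alpha / alpha_beta_ratio, epsilon)
    if (variant == "impulsive") {
      tr <- solve_impulsive(g, r, proto, v0, t_end, max_step = h,
                            sample_times = data$times[data$times > 0])
      trajectory_at_pre(tr, data$times)
    } else if (solver == "fixed_step") {
      m <- treated_model(g, r, proto)
      tr <- solve_caputo_abm_hard(m, v0, t_end, h = h, hard = hard)
      trajectory_at(tr, data$times)
    } else {
      tr <- solve_continuous_rk45(g, r, proto, v0, t_end, max_step = h,
                                  sample_times = data$times[data$times > 0],
                                  hard = hard)
      trajectory_at_post(tr, data$times)
    }
  }
  objective <- function(par) {
    pred <- simulate(par[1], par[2])
    sum((pred - data$volumes)^2)
  }

  set.seed(seed)
  starts <- cbind(a = runif(M, 0, 0.2), alpha = runif(M, 0, 0.1))
  rows <- vector("list", M)
  for (i in seq_len(M)) {
    t0 <- proc.time()
    res <- try(suppressWarnings(stats::nlminb(
      pmax(starts[i, ], 1e-4), function(par) {
        v <- try(objective(par), silent = TRUE)
        if (inherits(v, "try-error") || !is.finite(v)) 1e30 else v
      },
      lower = c(1e-4, 0), upper = c(1, 10),
      control = list(iter.max = maxit, eval.max = 4 * maxit))), silent = TRUE)
    dt <- proc.time() - t0
    ok <- !inherits(res, "try-error") && is.finite(res$objective) &&
      res$objective < 1e30
    rows[[i]] <- data.frame(
      instance = i, success = ok,
      ssr = if (ok) res$objective else NA_real_,
      a = if (ok) res$par[1] else NA_real_,
      alpha = if (ok) res$par[2] else NA_real_,
      wall_s = unname(dt["elapsed"]),
      cpu_s = unname(dt["user.self"] + dt["sys.self"]))
  }
  tab <- do.call(rbind, rows)
  ok <- tab$success
  best <- if (any(ok)) which.min(ifelse(ok, tab$ssr, Inf)) else NA_integer_
  consensus <- if (any(ok)) {
    sum(tab$ssr[ok] <= tab$ssr[best] * (1 + ssr_tol))
  } else 0L
  structure(list(variant = variant, solver = solver, instances = tab,
                 M = M, seed = seed,
                 time_per_fit = mean(tab$wall_s),
                 cpu_time_per_fit = mean(tab$cpu_s),
                 best_ssr = if (!is.na(best)) tab$ssr[best] else NA_real_,
                 best_a = if (!is.na(best)) tab$a[best] else NA_real_,
                 best_alpha = if (!is.na(best)) tab$alpha[best] else NA_real_,
                 consensus = consensus, n_failed = sum(!ok)),
            class = "rg_benchmark")
}

#' @export
print.rg_benchmark <- function(x, ...) {
  cat("<rg_benchmark> ", x$variant, " (", x$solver, "), M = ", x$M, "\n",
      "  time/fit = ", signif(x$time_per_fit, 3), " s (cpu ",
      signif(x$cpu_time_per_fit, 3), " s), best SSR = ",
      signif(x$best_ssr, 5), ", consensus ", x$consensus, "/", x$M,
      ", failed ", x$n_failed, "\n", sep = "")
  invisible(x)
}

# fixed-step mu=1 run with optional hard windows (benchmark only)
solve_caputo_abm_hard <- function(model, v0, t_end, h, hard = FALSE) {
  g <- model$growth; r <- model$radiation; pr <- model$protocol
  n_steps <- as.integer(ceiling(t_end / h - 1e-9))
  res <- abm_solve_model_cpp(
    law = law_code(g$law), a = g$a %||% 0, K = g$K %||% 1,
    l0 = g$lambda0 %||% 0, l1 = g$lambda1 %||% 1, psi = g$psi %||% 20,
    alpha = r$alpha, beta = r$beta, eps = r$epsilon, dose = pr$dose_gy,
    tau = pr$times_days, tw = pr$tw_days, cutoff = 50 * r$epsilon,
    hard = hard, v0 = v0, mu = 1, h = h, n_steps = n_steps, corr_iters = 1L)
  new_trajectory(h * (0:n_steps), res$v, 1, h, "caputo_abm",
                 negative = res$negative, n_evals = res$n_evals)
}
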