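#' Dynamic relative sensitivity of the predicted volume to one parameter
#'
#' Computes the time-resolved relative (normalized) local sensitivity
#' coefficient by a one-sided finite difference:
#' S(t) = (v(t; p + dp) - v(t; p)) / v_nominal(t) * p_nominal / dp,
#' with dp = direction * rel_step * p_nominal (a 1% perturbation by default).
#' Two solver runs are performed, both with the same solver settings as the
#' nominal model so numerical error does not masquerade as parameter effect.
#'
#' When `honour_alpha_beta = TRUE` (the default, matching the fitting
#' assumption) a perturbation of `alpha` rescales `beta` so that the
#' alpha/beta ratio is preserved.
#'
#' @param growth An [growth_parameters()] object (nominal values).
#' @param radiation A [radiation_parameters()] object (nominal values).
#' @param proto A [treatment_protocol()] object.
#' @param v0 Initial volume (cm^3).
#' @param param One of the model's parameters: `"a"`, `"K"`, `"lambda0"`,
#'   `"lambda1"`, `"alpha"`, `"beta"`, or `"mu"`.
#' @param t_end Final time (days).
#' @param direction +1 or -1: the sign of the perturbation. If the perturbed
#'   value leaves the admissible domain (e.g. mu + dp > 1), an error instructs
#'   the opposite direction.
#' @param rel_step Relative perturbation size. Default 0.01 (1%).
#' @param mu Fractional order of the nominal model. Default 1.
#' @param h,corrector_iterations Solver settings (shared by both runs).
#' @param honour_alpha_beta Keep beta = alpha / ratio when perturbing alpha.
#' @return An `rg_sensitivity` data.frame with columns `time` and `S`, and
#'   attributes recording the parameter, direction and step.
#' @export
#' @examples
#' g <- growth_parameters("exponential", a = 0.05)
#' r <- radiation_parameters(alpha = 0)
#' pr <- treatment_protocol(0, numeric(0))
#' s <- relative_sensitivity(g, r, pr, v0 = 10, param = "a", t_end = 10, h = 1 / 32)
#' # S(t) ~ a * t for untreated exponential growth
relative_sensitivity <- function(growth, radiation, proto, v0, param, t_end,
                                 direction = 1, rel_step = 0.01, mu = 1,
                                 h = 1 / 288, corrector_iterations = 1,
                                 honour_alpha_beta = TRUE) {
  stopifnot(direction %in% c(-1, 1), rel_step > 0)
  nominal <- list(growth = growth, radiation = radiation, mu = mu)
  p0 <- switch(param,
    a = growth$a, K = growth$K, lambda0 = growth$lambda0,
    lambda1 = growth$lambda1, alpha = radiation$alpha, beta = radiation$beta,
    mu = mu, stop("relative_sensitivity: unknown parameter '", param, "'",
                  call. = FALSE))
  if (is.null(p0)) {
    stop("relative_sensitivity: parameter '", param,
         "' is not part of the '", growth$law, "' model", call. = FALSE)
  }
  if (p0 == 0) { # relative change of a zero parameter is identically zero
    tr0 <- solve_caputo_abm(treated_model(growth, radiation, proto), v0, t_end,
                            mu = mu, h = h,
                            corrector_iterations = corrector_iterations)
    out <- data.frame(time = tr0$times, S = 0)
    attr(out, "param") <- param
    attr(out, "direction") <- direction
    attr(out, "rel_step") <- rel_step
    class(out) <- c("rg_sensitivity", "data.frame")
    return(out)
  }
  dp <- direction * rel_step * p0
  p1 <- p0 + dp

  pert <- nominal
  if (param == "mu") {
    if (p1 > 1 || p1 <= 0) {
      stop("relative_sensitivity: mu + dp = ", signif(p1, 6),
           " leaves (0, 1]; perturb in the opposite direction (direction = ",
           -direction, ")", call. = FALSE)
    }
    pert$mu <- p1
  } else if (param %in% c("alpha", "beta")) {
    if (p1 < 0) {
      stop("relative_sensitivity: perturbed ", param, " is negative; ",
           "use direction = ", -direction, call. = FALSE)
    }
    ratio <- radiation$alpha / radiation$beta
    if (param == "alpha") {
      beta_new <- if (honour_alpha_beta && is.finite(ratio)) p1 / ratio else radiation$beta
      pert$radiation <- radiation_parameters(p1, beta_new, radiation$epsilon)
    } else {
      pert$radiation <- radiation_parameters(radiation$alpha, p1, radiation$epsilon)
    }
  } else {
    if (p1 <= 0) {
      stop("relative_sensitivity: perturbed ", param, " is non-positive; ",
           "use direction = ", -direction, call. = FALSE)
    }
    g <- unclass(growth)
    g[[param]] <- p1
    pert$growth <- do.call(growth_parameters,
                           c(list(law = g$law), g[setdiff(names(g), "law")]))
  }

  run <- function(st) {
    solve_caputo_abm(treated_model(st$growth, st$radiation, proto), v0, t_end,
                     mu = st$mu, h = h,
                     corrector_iterations = corrector_iterations)
  }
  tr0 <- run(nominal)
  tr1 <- run(pert)
  if (any(tr0$volumes <= 0)) {
    stop("relative_sensitivity: nominal trajectory is not strictly positive",
         call. = FALSE)
  }
  S <- (tr1$volumes - tr0$volumes) / tr0$volumes * (p0 / dp)
  out <- data.frame(time = tr0$times, S = S)
  attr(out, "param") <- param
  attr(out, "direction") <- direction
  attr(out, "rel_step") <- rel_step
  class(out) <- c("rg_sensitivity", "data.frame")
  out
}
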