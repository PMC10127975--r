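#' Growth rate of a tumour growth law
#'
#' Evaluates dv/dt for the selected untreated growth law at volume `v`.
#' The exponential-linear denominator is computed in log space so the rate
#' stays finite far beyond the exponential-to-linear transition volume.
#'
#' @param p An [growth_parameters()] object.
#' @param v Volume (cm^3), >= 0. Vectorized.
#' @return Growth rate(s), cm^3/day.
#' @export
#' @examples
#' growth_rate(growth_parameters("exponential", a = 0.1), 2)  # 0.2
growth_rate <- function(p, v) {
  stopifnot(inherits(p, "rg_growth"))
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("growth_rate: volume must be finite and >= 0", call. = FALSE)
  }
  switch(p$law,
    exponential = p$a * v,
    logistic = p$a * v * (1 - v / p$K),
    exponential_linear = {
      out <- numeric(length(v))
      pos <- v > 0
      if (any(pos)) {
        # log((lambda0 v / lambda1)^psi), then log1p for the bracket
        lr <- p$psi * (log(p$lambda0) + log(v[pos]) - log(p$lambda1))
        lden <- ifelse(lr > 0, (lr + log1p(exp(-lr))) / p$psi,
                       log1p(exp(lr)) / p$psi)
        out[pos] <- p$lambda0 * v[pos] * exp(-lden)
      }
      out
    }
  )
}

#' Linear-quadratic surviving fraction
#'
#' SF = exp(-alpha d - beta d^2): the fraction of cells surviving a single
#' radiation fraction of dose `d` Gy.
#'
#' @param r A [radiation_parameters()] object.
#' @param d Dose (Gy), >= 0. Vectorized.
#' @return Surviving fraction(s) in (0, 1].
#' @export
lq_survival_fraction <- function(r, d) {
  stopifnot(inherits(r, "rg_radiation"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("lq_survival_fraction: dose must be finite and >= 0", call. = FALSE)
  }
  exp(-r$alpha * d - r$beta * d^2)
}

#' Smoothed Heaviside step
#'
#' The tanh approximation H(t) ~ (1 + tanh(t/epsilon)) / 2 used to switch
#' treatment windows on and off while keeping the right-hand side continuous
#' (a requirement for well-posedness of the Caputo fractional models).
#'
#' @param t Time (days). Vectorized.
#' @param epsilon Smoothing width (days), > 0.
#' @return Values in (0, 1), 0.5 at t = 0.
#' @export
smooth_heaviside <- function(t, epsilon) {
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("smooth_heaviside: 'epsilon' must be > 0", call. = FALSE)
  }
  0.5 * (1 + tanh(t / epsilon))
}

#' Continuous radiation-induced death rate
#'
#' The death rate v (1 - SF) sum_i (H(t - tau_i) - H(t - tau_i - tw)) / tw,
#' which spreads each fraction's LQ cell kill uniformly (up to tanh smoothing)
#' over a window of length `tw` starting at the treatment time. Each window
#' factor integrates to 1 over time, so the total kill per fraction matches
#' the LQ prediction; as tw -> 0 the term approaches the impulsive model.
#'
#' Only windows with `t` within `cutoff` of `[tau_i, tau_i + tw]` are summed;
#' the tanh tails make the truncation error negligible (below 1e-40 at the
#' default cutoff of 50 epsilon).
#'
#' @param r A [radiation_parameters()] object.
#' @param proto A [treatment_protocol()] object.
#' @param t Time (days). Vectorized.
#' @param v Volume (cm^3), >= 0 (scalar or same length as `t`).
#' @param cutoff Window-sum truncation distance (days); default 50 * epsilon.
#' @param hard If `TRUE`, use exact (discontinuous) indicator windows instead
#'   of the tanh smoothing. Intended only for solver benchmarking.
#' @return Death rate(s), cm^3/day.
#' @export
death_rate <- function(r, proto, t, v, cutoff = 50 * r$epsilon, hard = FALSE) {
  stopifnot(inherits(r, "rg_radiation"), inherits(proto, "rg_protocol"))
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("death_rate: volume must be finite and >= 0", call. = FALSE)
  }
  kill <- 1 - lq_survival_fraction(r, proto$dose_gy)
  if (kill == 0 || !length(proto$times_days)) return(0 * t * v[1] + 0 * v)
  tw <- proto$tw_days
  wsum <- vapply(t, function(ti) {
    dt <- ti - proto$times_days
    keep <- dt >= -cutoff & dt <= tw + cutoff
    if (!any(keep)) return(0)
    dt <- dt[keep]
    if (hard) {
      sum(dt >= 0 & dt < tw) / tw
    } else {
      sum(smooth_heaviside(dt, r$epsilon) - smooth_heaviside(dt - tw, r$epsilon)) / tw
    }
  }, numeric(1))
  v * kill * wsum
}

#' Treated right-hand side: growth minus radiation death rate
#'
#' The full right-hand side of the treated tumour models,
#' dv/dt = growth(v) - death(t, v). Continuous in `t` by construction.
#'
#' @param p An [growth_parameters()] object.
#' @param r A [radiation_parameters()] object.
#' @param proto A [treatment_protocol()] object.
#' @param t Time (days). Vectorized.
#' @param v Volume (cm^3), >= 0.
#' @inheritParams death_rate
#' @return Net rate(s), cm^3/day.
#' @export
treated_rhs <- function(p, r, proto, t, v, cutoff = 50 * r$epsilon, hard = FALSE) {
  growth_rate(p, v) - death_rate(r, proto, t, v, cutoff = cutoff, hard = hard)
}
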