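#' Growth-law parameters
#'
#' Bundles the parameters of one of the three supported tumour growth laws.
#' Volumes are in cm^3 and time is nondimensionalized by a characteristic
#' scale of 1 day, so all rates are per day.
#'
#' * `exponential`: dv/dt = a v
#' * `logistic`: dv/dt = a v (1 - v/K)
#' * `exponential_linear`: dv/dt = lambda0 v (1 + (lambda0 v / lambda1)^psi)^(-1/psi),
#'   which grows exponentially at rate `lambda0` for small volumes and linearly
#'   at rate `lambda1` (cm^3/day) beyond the transition volume `lambda1/lambda0`;
#'   `psi` controls the sharpness of the transition.
#'
#' @param law One of `"exponential"`, `"logistic"`, `"exponential_linear"`.
#' @param a Growth rate (per day); exponential and logistic laws.
#' @param K Carrying capacity (cm^3); logistic law only.
#' @param lambda0 Exponential-phase rate (per day); exponential-linear law.
#' @param lambda1 Linear-phase rate (cm^3 per day); exponential-linear law.
#' @param psi Transition sharpness (dimensionless, >= 1). Default 20; this is
#'   treated as a fixed structural constant and is never fitted.
#' @return An object of class `rg_growth`.
#' @export
#' @examples
#' growth_parameters("exponential", a = 0.0118)
#' growth_parameters("logistic", a = 0.0168, K = 40)
growth_parameters <- function(law = c("exponential", "logistic", "exponential_linear"),
                              a = NULL, K = NULL, lambda0 = NULL, lambda1 = NULL,
                              psi = 20) {
  law <- match.arg(law)
  need <- function(x, nm) {
    if (is.null(x)) {
      stop("growth_parameters: law '", law, "' requires parameter '", nm, "'",
           call. = FALSE)
    }
    if (!is.finite(x) || x <= 0) {
      stop("growth_parameters: '", nm, "' must be finite and strictly positive",
           call. = FALSE)
    }
    as.numeric(x)
  }
  p <- switch(law,
    exponential = list(a = need(a, "a")),
    logistic = list(a = need(a, "a"), K = need(K, "K")),
    exponential_linear = {
      if (!is.finite(psi) || psi < 1) {
        stop("growth_parameters: 'psi' must be >= 1", call. = FALSE)
      }
      list(lambda0 = need(lambda0, "lambda0"),
           lambda1 = need(lambda1, "lambda1"),
           psi = as.numeric(psi))
    }
  )
  structure(c(list(law = law), p), class = "rg_growth")
}

#' Linear-quadratic radiosensitivity parameters
#'
#' Parameters of the linear-quadratic (LQ) cell-survival model,
#' SF = exp(-alpha d - beta d^2) after a fraction of dose `d` Gy, together
#' with the smoothing width of the tanh Heaviside approximation used to turn
#' the per-fraction kill into a continuous death rate.
#'
#' @param alpha Radiosensitivity (Gy^-1), >= 0.
#' @param beta Radiosensitivity (Gy^-2), >= 0. Defaults to `alpha/10`, the
#'   standard alpha/beta = 10 Gy assumption for head-and-neck tumours.
#' @param epsilon Smoothing width of the Heaviside approximation
#'   (dimensionless days); must satisfy 0 < epsilon < 1e-2. Default 1e-5.
#' @return An object of class `rg_radiation`.
#' @export
#' @examples
#' radiation_parameters(alpha = 0.0222)  # beta = 0.00222 implied
radiation_parameters <- function(alpha, beta = alpha / 10, epsilon = 1e-5) {
  if (!is.finite(alpha) || alpha < 0) {
    stop("radiation_parameters: 'alpha' must be >= 0", call. = FALSE)
  }
  if (!is.finite(beta) || beta < 0) {
    stop("radiation_parameters: 'beta' must be >= 0", call. = FALSE)
  }
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1e-2) {
    stop("radiation_parameters: 'epsilon' must satisfy 0 < epsilon < 1e-2",
         call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 epsilon = as.numeric(epsilon)),
            class = "rg_radiation")
}

#' Fractionated treatment protocol
#'
#' An ordered set of treatment times (days, on the model clock that starts at
#' the first volume measurement), the dose per fraction, and the treatment
#' window length `tw` over which each fraction's cell kill is spread.
#'
#' @param dose_gy Dose per fraction (Gy), > 0.
#' @param times_days Strictly increasing treatment times (days).
#' @param tw_days Treatment window length (days), > 0; consecutive treatment
#'   times must be separated by more than `tw_days`. Default 1/96 day
#'   (15 minutes).
#' @return An object of class `rg_protocol`.
#' @export
#' @examples
#' treatment_protocol(2, c(0, 1, 2, 3, 4))
treatment_protocol <- function(dose_gy, times_days, tw_days = 1 / 96) {
  if (!is.finite(dose_gy) || dose_gy < 0) {
    stop("treatment_protocol: 'dose_gy' must be >= 0", call. = FALSE)
  }
  if (!is.finite(tw_days) || tw_days <= 0) {
    stop("treatment_protocol: 'tw_days' must be > 0", call. = FALSE)
  }
  times_days <- as.numeric(times_days)
  if (length(times_days) && any(!is.finite(times_days))) {
    stop("treatment_protocol: non-finite treatment time", call. = FALSE)
  }
  if (length(times_days) > 1) {
    gaps <- diff(times_days)
    if (any(gaps <= 0)) {
      stop("treatment_protocol: treatment times must be strictly increasing (time index ",
           which(gaps <= 0)[1] + 1, ")", call. = FALSE)
    }
    if (any(gaps <= tw_days)) {
      stop("treatment_protocol: treatment windows overlap (times ",
           which(gaps <= tw_days)[1], " and ", which(gaps <= tw_days)[1] + 1,
           " are closer than tw)", call. = FALSE)
    }
  }
  structure(list(dose_gy = as.numeric(dose_gy), times_days = times_days,
                 tw_days = as.numeric(tw_days)),
            class = "rg_protocol")
}

#' Measured tumour-volume time series
#'
#' One patient's (day, volume) measurements. The model clock starts at the
#' first measurement, so `times[1]` must be 0; volumes are cm^3 and strictly
#' positive.
#'
#' @param times Strictly increasing measurement days, starting at 0.
#' @param volumes Measured volumes (cm^3), strictly positive.
#' @return An object of class `rg_series`.
#' @export
#' @examples
#' tumour_series(c(0, 7, 14), c(20, 21.5, 19.8))
tumour_series <- function(times, volumes) {
  times <- as.numeric(times); volumes <- as.numeric(volumes)
  if (length(times) != length(volumes)) {
    stop("tumour_series: 'times' and 'volumes' lengths differ", call. = FALSE)
  }
  if (!length(times)) stop("tumour_series: empty series", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(volumes))) {
    stop("tumour_series: non-finite entry", call. = FALSE)
  }
  if (abs(times[1]) > .Machine$double.eps) {
    stop("tumour_series: first measurement must be at time 0", call. = FALSE)
  }
  bad <- which(diff(times) <= 0)
  if (length(bad)) {
    stop("tumour_series: times must be strictly increasing (row ", bad[1] + 1, ")",
         call. = FALSE)
  }
  bad <- which(volumes <= 0)
  if (length(bad)) {
    stop("tumour_series: volumes must be strictly positive (row ", bad[1], ")",
         call. = FALSE)
  }
  structure(list(times = times, volumes = volumes), class = "rg_series")
}

#' Treated tumour model (growth minus radiation death rate)
#'
#' Binds a growth law, LQ radiosensitivities, and a treatment protocol into a
#' single right-hand side dv/dt = growth(v) - death(t, v). Objects of this
#' class are accepted by [solve_caputo_abm()] and dispatch to the compiled
#' fast path.
#'
#' @param growth An [growth_parameters()] object.
#' @param radiation A [radiation_parameters()] object.
#' @param protocol A [treatment_protocol()] object.
#' @return An object of class `rg_model`.
#' @export
treated_model <- function(growth, radiation, protocol) {
  stopifnot(inherits(growth, "rg_growth"), inherits(radiation, "rg_radiation"),
            inherits(protocol, "rg_protocol"))
  structure(list(growth = growth, radiation = radiation, protocol = protocol),
            class = "rg_model")
}

#' Standard weekday fractionation schedule
#'
#' Builds the conventional curative schedule: `total_dose / dose_per_fraction`
#' fractions delivered once daily on weekdays (5 days on, 2 days off),
#' starting at `start_day`, which is taken to be the first day of a treatment
#' week (a Monday).
#'
#' @param total_dose Total prescribed dose (Gy).
#' @param dose_per_fraction Dose per fraction (Gy); must divide `total_dose`.
#' @param start_day Day (model clock) of the first fraction. Default 0.
#' @param tw_days Treatment window length passed through to the protocol.
#' @return An [treatment_protocol()] object.
#' @export
#' @examples
#' p <- standard_fractionation(66, 2)  # 33 fractions, last on day 44
#' range(p$times_days)
standard_fractionation <- function(total_dose, dose_per_fraction = 2,
                                   start_day = 0, tw_days = 1 / 96) {
  n <- total_dose / dose_per_fraction
  if (!is.finite(n) || abs(n - round(n)) > 1e-9 || n < 1) {
    stop("standard_fractionation: total_dose must be a positive multiple of dose_per_fraction",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  idx <- seq_len(n) - 1L
  days <- (idx %/% 5L) * 7L + (idx %% 5L)
  treatment_protocol(dose_per_fraction, start_day + days, tw_days)
}

#' @export
print.rg_growth <- function(x, ...) {
  ps <- x[setdiff(names(x), "law")]
  cat("<rg_growth> ", x$law, ": ",
      paste(names(ps), signif(unlist(ps), 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.rg_protocol <- function(x, ...) {
  cat("<rg_protocol> ", length(x$times_days), " x ", x$dose_gy,
      " Gy fractions over days [", min(x$times_days), ", ", max(x$times_days),
      "], tw = ", signif(x$tw_days, 4), " day\n", sep = "")
  invisible(x)
}

#' @export
print.rg_series <- function(x, ...) {
  cat("<rg_series> ", length(x$times), " measurements, days ",
      min(x$times), "-", max(x$times), ", volumes ",
      signif(min(x$volumes), 4), "-", signif(max(x$volumes), 4), " cm^3\n",
      sep = "")
  invisible(x)
}

#' @export
print.rg_model <- function(x, ...) {
  cat("<rg_model> law:", x$growth$law, "| alpha:", x$radiation$alpha,
      "| fractions:", length(x$protocol$times_days), "\n")
  invisible(x)
}

#' @export
as.data.frame.rg_series <- function(x, ...) {
  data.frame(day = x$times, volume_cm3 = x$volumes)
}
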