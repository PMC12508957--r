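# Noncompartmental analysis, fold-error validation statistics, and
# steady-state multiple-dose metrics.

#' Fold error of a prediction
#'
#' `FE = predicted / observed`.
#'
#' @param predicted predicted value (same units as observed).
#' @param observed observed value, > 0.
#' @return dimensionless fold error.
#' @export
fold_error <- function(predicted, observed) {
  if (any(observed <= 0)) stopf("observed values must be positive")
  predicted / observed
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10(predicted/observed)))`: below 1 the predictions
#' underestimate on average, above 1 they overestimate.
#'
#' @param predicted,observed numeric vectors of paired values (observed > 0,
#'   predicted > 0).
#' @return dimensionless AFE.
#' @export
afe <- function(predicted, observed) {
  if (!length(predicted)) stopf("at least one pair is required")
  if (length(predicted) != length(observed)) stopf("length mismatch")
  fe <- fold_error(predicted, observed)
  if (any(fe <= 0)) stopf("fold errors must be positive for log averaging")
  10^mean(log10(fe))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10(predicted/observed)|))`; always >= 1 and >= AFE
#' (and >= 1/AFE).
#'
#' @inheritParams afe
#' @return dimensionless AAFE.
#' @export
aafe <- function(predicted, observed) {
  if (!length(predicted)) stopf("at least one pair is required")
  if (length(predicted) != length(observed)) stopf("length mismatch")
  fe <- fold_error(predicted, observed)
  if (any(fe <= 0)) stopf("fold errors must be positive for log averaging")
  10^mean(abs(log10(fe)))
}

#' Fold-error validation report
#'
#' Applies the two-fold acceptance rule: a simulation is successful when
#' every point-wise FE lies in [0.2, 2] and both AFE and AAFE are below 2.
#'
#' @inheritParams afe
#' @param labels optional names for the pairs.
#' @return object of class `validation_report`: per-pair FE, AFE, AAFE,
#'   logical `pass`.
#' @export
validation_report <- function(predicted, observed, labels = NULL) {
  fe <- fold_error(predicted, observed)
  rep <- structure(list(
    fe = stats::setNames(fe, labels),
    afe = afe(predicted, observed),
    aafe = aafe(predicted, observed)
  ), class = "validation_report")
  rep$pass <- all(fe >= 0.2 & fe <= 2) && rep$afe < 2 && rep$aafe < 2
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(round(x$fe, 3))
  cat(sprintf("  AFE %.3f | AAFE %.3f | %s\n", x$afe, x$aafe,
              if (x$pass) "PASS (within 2-fold)" else "FAIL"))
  invisible(x)
}

#' Noncompartmental analysis of a concentration-time profile
#'
#' Cmax/tmax by direct lookup; AUC to the last time point by the
#' linear-up/log-down trapezoid; terminal slope lambda_z by log-linear
#' regression on the last `lambda_z_points` positive concentrations;
#' `AUCinf = AUCt + Clast / lambda_z`. When the terminal phase is not
#' estimable (non-positive or non-decreasing tail), `lambda_z`, `t_half` and
#' `auc_inf` are `NA`.
#'
#' @param time time grid (h), strictly increasing.
#' @param conc concentrations (ng/mL), non-negative.
#' @param dose optional dose (mg) stored in the result.
#' @param lambda_z_points number of terminal points for the lambda_z fit.
#' @return object of class `nca_result` with `cmax`, `tmax`, `auc_t`,
#'   `auc_inf`, `lambda_z`, `t_half`.
#' @export
nca <- function(time, conc, dose = NA_real_, lambda_z_points = 3) {
  if (inherits(time, "sim_result")) { conc <- time$conc; time <- time$time }
  if (length(time) < 2 || length(time) != length(conc))
    stopf("need matched time/concentration vectors with >= 2 points")
  if (any(diff(time) <= 0)) stopf("time must be strictly increasing")
  if (any(conc < -1e-12)) stopf("negative concentrations")
  conc <- pmax(conc, 0)

  i_max <- which.max(conc)
  cmax <- conc[i_max]; tmax <- time[i_max]
  auc_t <- auc_linuplogdown(time, conc)

  lambda_z <- NA_real_
  pos <- which(conc > 0)
  if (length(pos) >= lambda_z_points) {
    tail_i <- utils::tail(pos, lambda_z_points)
    fit <- stats::lm(log(conc[tail_i]) ~ time[tail_i])
    slope <- unname(stats::coef(fit)[2])
    if (is.finite(slope) && slope < 0) lambda_z <- -slope
    # a terminal half-life vastly exceeding the observation span is solver
    # noise on a flat tail, not an estimable terminal phase
    if (is.finite(lambda_z) &&
        log(2) / lambda_z > 50 * (max(time) - min(time)))
      lambda_z <- NA_real_
  }
  auc_inf <- if (is.finite(lambda_z)) {
    clast <- conc[utils::tail(pos, 1)]
    auc_t + clast / lambda_z
  } else NA_real_

  structure(list(cmax = cmax, tmax = tmax, auc_t = auc_t, auc_inf = auc_inf,
                 lambda_z = lambda_z,
                 t_half = if (is.finite(lambda_z)) log(2) / lambda_z else NA_real_,
                 dose = dose),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca> Cmax %.4g @ %.3g h | AUCt %.5g | AUCinf %.5g | t1/2 %.3g h\n",
              x$cmax, x$tmax, x$auc_t, x$auc_inf, x$t_half))
  invisible(x)
}

# linear-up/log-down trapezoidal AUC
auc_linuplogdown <- function(time, conc) {
  dt <- diff(time)
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  seg <- ifelse(c2 < c1 & c2 > 0 & c1 > 0,
                dt * (c1 - c2) / log(c1 / c2),
                dt * (c1 + c2) / 2)
  sum(seg)
}

#' Steady-state metrics over one dosing interval
#'
#' Computes Cmax,ss, Ctrough, Cavg = AUCtau/tau, AUCtau and the fluctuation
#' index `(Cmax,ss - Ctrough) / Cavg * 100` over the final complete dosing
#' interval of the profile. If the AUC over the last two intervals drifts by
#' more than 5%, the profile is flagged as not at steady state (warning
#' attribute, not an error).
#'
#' @param time time grid (h).
#' @param conc concentrations (ng/mL).
#' @param tau dosing interval (h).
#' @return object of class `steady_state_result` with `cmax_ss`, `ctrough`,
#'   `cavg`, `auc_tau`, `fluctuation_index`, `at_steady_state`.
#' @export
steady_state_metrics <- function(time, conc, tau) {
  if (inherits(time, "sim_result")) { conc <- time$conc; time <- time$time }
  check_number(tau, "tau", 0, strict_lower = TRUE)
  t_end <- max(time)
  if (t_end < tau) stopf("profile does not cover one dosing interval")
  win <- time >= t_end - tau - 1e-9
  tt <- time[win]; cc <- conc[win]
  auc_tau <- auc_linuplogdown(tt, cc)
  cavg <- auc_tau / tau
  cmax_ss <- max(cc); ctrough <- min(cc[c(1, length(cc))])
  at_ss <- TRUE
  if (t_end >= 2 * tau) {
    prev <- time >= t_end - 2 * tau - 1e-9 & time <= t_end - tau + 1e-9
    auc_prev <- auc_linuplogdown(time[prev], conc[prev])
    if (auc_prev > 0 && abs(auc_tau - auc_prev) / auc_prev > 0.05) at_ss <- FALSE
  }
  structure(list(cmax_ss = cmax_ss, ctrough = ctrough, cavg = cavg,
                 auc_tau = auc_tau,
                 fluctuation_index = (cmax_ss - ctrough) / cavg * 100,
                 at_steady_state = at_ss),
            class = "steady_state_result")
}
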