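# In vitro profile metrics: dissolution efficiency, f2 similarity factor,
# crystallinity degree.

#' Dissolution efficiency
#'
#' `DE = [trapezoidal AUC of %dissolved from 0 to t_end] / (100 * t_end) * 100`.
#' If the profile does not start at time 0, a (0, 0) point is prepended.
#'
#' @param profile a [dissolution_profile()] (or a list with `times_min`,
#'   `percent_dissolved`).
#' @param t_end upper limit (min); defaults to the last sampling time.
#' @return dissolution efficiency in percent.
#' @export
dissolution_efficiency <- function(profile, t_end = max(profile$times_min)) {
  t <- profile$times_min; y <- profile$percent_dissolved
  if (length(t) < 2) stopf("need at least 2 points")
  if (any(diff(t) <= 0)) stopf("times must be sorted strictly increasing")
  if (t_end > max(t) + 1e-9) stopf("t_end beyond the profile")
  if (t[1] > 0) { t <- c(0, t); y <- c(0, y) }
  keep <- t <= t_end + 1e-9
  t <- t[keep]; y <- y[keep]
  if (abs(t[length(t)] - t_end) > 1e-9) {
    y_end <- stats::approx(profile$times_min, profile$percent_dissolved, t_end)$y
    t <- c(t, t_end); y <- c(y, y_end)
  }
  auc <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  auc / (100 * t_end) * 100
}

#' f2 similarity factor between two dissolution profiles
#'
#' `f2 = 50 * log10(100 * (1 + mean((R - T)^2))^(-1/2))` over a comparison
#' window chosen by the standard plateau rule: all common time points up to
#' and including the first point at which both profiles have reached 85%
#' dissolved (all points if neither reaches 85%). `f2 >= 50` indicates
#' similarity; identical profiles give 100.
#'
#' @param reference,test [dissolution_profile()] objects on a common grid
#'   (differing grids are linearly interpolated onto the shared time range).
#' @param window `"plateau85"` (default rule) or `"all"`.
#' @return dimensionless f2.
#' @export
f2_similarity <- function(reference, test, window = c("plateau85", "all")) {
  window <- match.arg(window)
  tr <- reference$times_min; tt <- test$times_min
  if (!identical(tr, tt)) {
    common <- intersect(tr, tt)
    if (length(common) < 3) stopf("profiles must share (or overlap on) a time grid")
    r <- stats::approx(tr, reference$percent_dissolved, common)$y
    s <- stats::approx(tt, test$percent_dissolved, common)$y
    t <- common
  } else {
    r <- reference$percent_dissolved; s <- test$percent_dissolved; t <- tr
  }
  if (window == "plateau85") {
    past <- which(r >= 85 & s >= 85)
    if (length(past)) {
      cut <- past[1]
      r <- r[seq_len(cut)]; s <- s[seq_len(cut)]
    }
  }
  if (length(r) < 3) stopf("need at least 3 points in the comparison window")
  50 * log10(100 / sqrt(1 + mean((r - s)^2)))
}

#' Degree of crystallinity from enthalpy of fusion
#'
#' `(enthalpy_measured / drug_mass_fraction) / enthalpy_reference * 100`:
#' the measured fusion enthalpy is first corrected for drug content, then
#' referenced to the fusion enthalpy of the fully crystalline drug.
#'
#' @param enthalpy_measured measured enthalpy of fusion (J/g of sample).
#' @param drug_mass_fraction drug content of the sample (0-1].
#' @param enthalpy_reference fusion enthalpy of the pure crystalline drug
#'   (J/g).
#' @return crystallinity degree in percent.
#' @export
crystallinity_degree <- function(enthalpy_measured, drug_mass_fraction,
                                 enthalpy_reference) {
  check_number(enthalpy_measured, "enthalpy_measured", 0, strict_lower = TRUE)
  check_number(drug_mass_fraction, "drug_mass_fraction", 0, 1, strict_lower = TRUE)
  check_number(enthalpy_reference, "enthalpy_reference", 0, strict_lower = TRUE)
  (enthalpy_measured / drug_mass_fraction) / enthalpy_reference * 100
}
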