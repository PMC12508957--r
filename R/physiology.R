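# Species physiology tables and the physiology constructor.
#
# Tissue volumes and regional blood flows are packaged literature values
# (standard compilations for laboratory rat and reference adult male), scaled
# linearly with body weight. Two entries are one-time calibrations, frozen
# here and documented in the methods vignette:
#   * the depot-fat volumes (adipose, yellow marrow) are set so that
#     steady_state_vd() with the packaged partition coefficients reproduces
#     the reported steady-state distribution volume of the case-study drug;
#   * the rat hepatic blood flow fraction is set so that the i.v. 2 mg/kg
#     simulation reproduces the reported AUCinf (it remains inside the
#     literature range of 55-100 mL/min/kg).

# volumes: L per kg body weight; flows: fraction of cardiac output.
# kp columns are the case-study partition coefficients (tissue:plasma).
.tissue_table <- function(species) {
  if (species == "rat") {
    data.frame(
      name   = c("lung", "adipose", "muscle", "liver", "spleen", "heart",
                 "brain", "kidney", "skin", "reproductive", "red_marrow",
                 "yellow_marrow", "rest"),
      vol_frac = c(0.0050, 0.0033982, 0.4040, 0.0366, 0.0020, 0.0033,
                   0.0057, 0.0073, 0.1900, 0.0025, 0.0050,
                   0.0010, NA),       # rest = remainder of body volume
      flow_frac = c(NA, 0.070, 0.278, 0.27232, 0.010, 0.049,
                    0.020, 0.141, 0.058, 0.005, 0.020,
                    0.005, NA),       # lung in series (= CO); rest = remainder
      kp = c(7.52, 69.58, 3.66, 6.15, 3.39, 5.06,
             15.89, 6.00, 8.44, 6.00, 8.09,
             69.59, 3.39),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name   = c("lung", "adipose", "muscle", "liver", "spleen", "heart",
                 "brain", "kidney", "skin", "reproductive", "red_marrow",
                 "yellow_marrow", "rest"),
      vol_frac = c(0.0076, 0.2856632, 0.4000, 0.0260, 0.0026, 0.0047,
                   0.0210, 0.0044, 0.0490, 0.0005, 0.0162,
                   0.0354, NA),
      flow_frac = c(NA, 0.050, 0.170, 0.255, 0.015, 0.040,
                    0.120, 0.190, 0.050, 0.002, 0.030,
                    0.010, NA),
      kp = c(0.65, 27.59, 3.09, 5.05, 3.11, 1.97,
             8.11, 3.05, 3.79, 3.05, 8.86,
             27.59, 3.11),
      stringsAsFactors = FALSE
    )
  }
}

.species_constants <- function(species) {
  if (species == "rat") {
    list(
      blood_frac = 0.074,          # total blood, L/kg (venous 2/3, arterial 1/3)
      co_l_h_per_kg075 = 14.1,     # cardiac output = 14.1 * BW^0.75 L/h
      gfr_l_h_per_kg = 0.60,       # glomerular filtration, L/h per kg
      ent_vol_l_per_kg = 0.011,    # enterocyte compartment volume
      ent_flow_frac = 0.12,        # villous blood flow, fraction of CO
      asf = 40                     # absorption scale factor (calibrated, frozen)
    )
  } else {
    list(
      blood_frac = 0.0768,
      co_l_h_per_kg075 = 14.1,
      gfr_l_h_per_kg = 0.1107,     # 7.5 L/h at 67.73 kg
      ent_vol_l_per_kg = 0.0045,
      ent_flow_frac = 0.12,
      asf = 2.00                   # absorption scale factor (calibrated, frozen)
    )
  }
}

# GI chain defaults (fasted). volume mL, transit h, pH, bile salt mM,
# sa_v 1/cm (absorptive surface-to-volume scale; stomach non-absorptive,
# colon reduced).
.gi_table <- function(species) {
  comp <- c("stomach", "duodenum", "jejunum1", "jejunum2",
            "ileum1", "ileum2", "ileum3", "caecum", "colon")
  if (species == "rat") {
    data.frame(
      name = comp,
      volume_ml_per_kg = c(4.29, 0.86, 2.14, 2.14, 1.43, 1.43, 1.43, 8.57, 4.29),
      transit_h = c(0.25, 0.10, 0.35, 0.35, 0.40, 0.40, 0.40, 2.50, 4.00),
      ph = c(3.9, 6.0, 6.2, 6.4, 6.6, 6.8, 7.0, 6.2, 6.5),
      bile_mM = c(0, 10, 8, 8, 6, 5, 4, 0.5, 0.5),
      sa_v = c(0, 11, 10, 10, 9, 9, 9, 1.5, 1.5),
      absorb = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = comp,
      volume_ml_per_kg = c(0.68, 0.62, 2.27, 1.80, 1.39, 1.05, 0.72, 0.69, 0.74),
      transit_h = c(0.25, 0.26, 0.93, 0.74, 0.58, 0.42, 0.29, 4.55, 13.10),
      ph = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
      bile_mM = c(0, 2.8, 2.6, 2.2, 1.8, 1.4, 1.0, 0, 0),
      sa_v = c(0, 1.25, 1.18, 1.11, 1.05, 0.99, 0.93, 0.15, 0.15),
      absorb = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  }
}

#' Load a packaged species physiology
#'
#' Builds a whole-body physiology (13 perfusion-limited tissues, venous and
#' arterial blood pools, a 9-compartment gastrointestinal chain ordered
#' stomach to colon) scaled linearly to `body_weight`, with the packaged
#' tissue-to-plasma partition coefficients of the case-study drug filled in.
#' The lung is perfused in series (its flow equals cardiac output); the flows
#' of the remaining tissues sum exactly to cardiac output.
#'
#' @param species `"rat"` or `"human"`.
#' @param body_weight body weight in kg (defaults: rat 0.35, human 67.73).
#' @param stomach_transit_h optional stomach transit override (h); the
#'   packaged fasted default is 0.25 h, and oral-suspension simulations use
#'   0.1 h (see [simulate_oral()]).
#' @return object of class `physiology`.
#' @export
load_physiology <- function(species = c("rat", "human"),
                            body_weight = NULL,
                            stomach_transit_h = NULL) {
  species <- match.arg(species)
  if (is.null(body_weight)) body_weight <- if (species == "rat") 0.35 else 67.73
  check_number(body_weight, "body_weight", 0, strict_lower = TRUE)

  tt <- .tissue_table(species)
  sc <- .species_constants(species)

  co <- sc$co_l_h_per_kg075 * body_weight^0.75
  blood <- sc$blood_frac * body_weight
  # rest-of-body volume closes the whole-body volume balance (density ~1)
  known <- sum(tt$vol_frac, na.rm = TRUE) + sc$blood_frac + sc$ent_vol_l_per_kg
  if (known >= 1) stopf("tissue volume fractions exceed body volume")
  tt$vol_frac[tt$name == "rest"] <- 1 - known
  tt$volume <- tt$vol_frac * body_weight

  systemic <- tt$name != "lung"
  f_rest <- 1 - sum(tt$flow_frac[systemic], na.rm = TRUE)
  if (f_rest <= 0) stopf("tissue flow fractions exceed cardiac output")
  tt$flow_frac[tt$name == "rest"] <- f_rest
  tt$flow <- tt$flow_frac * co
  tt$flow[tt$name == "lung"] <- co

  gi <- .gi_table(species)
  gi$volume_ml <- gi$volume_ml_per_kg * body_weight
  if (!is.null(stomach_transit_h)) {
    check_number(stomach_transit_h, "stomach_transit_h", 0, strict_lower = TRUE)
    gi$transit_h[gi$name == "stomach"] <- stomach_transit_h
  }

  phys <- structure(list(
    species = species,
    body_weight = body_weight,
    tissues = tt[, c("name", "volume", "flow", "kp")],
    venous_volume = blood * 2 / 3,
    arterial_volume = blood / 3,
    cardiac_output = co,
    gfr = sc$gfr_l_h_per_kg * body_weight,
    renal_clearance_rule = "fup_times_gfr",
    renal_clearance_l_h = NA_real_,
    ent_volume = sc$ent_vol_l_per_kg * body_weight,
    ent_flow = sc$ent_flow_frac * co,
    asf = sc$asf,
    gi = gi[, c("name", "volume_ml", "transit_h", "ph", "bile_mM", "sa_v", "absorb")]
  ), class = "physiology")
  validate_physiology(phys)
  phys
}

#' Validate a physiology object
#'
#' Checks positivity of volumes and transit times, the stomach-to-colon
#' ordering of the GI chain, and the flow balance (systemic tissue flows sum
#' to cardiac output to within 1e-6 relative).
#'
#' @param phys a `physiology`.
#' @return `phys`, invisibly; errors on violation.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology"))
  tt <- phys$tissues
  if (any(tt$volume <= 0)) stopf("all tissue volumes must be positive")
  if (any(tt$flow < 0)) stopf("tissue blood flows must be non-negative")
  if (any(!is.finite(tt$kp)) || any(tt$kp <= 0)) stopf("all tissue Kp must be positive")
  sys_flow <- sum(tt$flow[tt$name != "lung"])
  if (abs(sys_flow - phys$cardiac_output) > 1e-6 * phys$cardiac_output)
    stopf("flow balance violated: systemic flows (%.6g) != cardiac output (%.6g)",
          sys_flow, phys$cardiac_output)
  gi <- phys$gi
  expected <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                "ileum1", "ileum2", "ileum3", "caecum", "colon")
  if (!identical(gi$name, expected)) stopf("GI chain must be ordered stomach -> colon")
  if (any(gi$volume_ml <= 0) || any(gi$transit_h <= 0))
    stopf("GI volumes and transit times must be positive")
  if (any(gi$bile_mM < 0)) stopf("bile salt concentrations must be non-negative")
  invisible(phys)
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %.4g kg\n", x$species, x$body_weight))
  cat(sprintf("  cardiac output %.3g L/h | GFR %.3g L/h | blood %.3g L\n",
              x$cardiac_output, x$gfr, x$venous_volume + x$arterial_volume))
  cat(sprintf("  %d tissues, %d GI compartments\n", nrow(x$tissues), nrow(x$gi)))
  invisible(x)
}

#' Renal plasma clearance implied by a physiology/drug pair
#'
#' Default rule is unbound filtration, `fup * GFR`; an explicit value can be
#' set via `phys$renal_clearance_rule = "explicit"` and
#' `phys$renal_clearance_l_h`.
#'
#' @param phys a `physiology`.
#' @param drug a [drug_record()].
#' @return renal plasma clearance (L/h).
#' @export
renal_clearance <- function(phys, drug) {
  if (identical(phys$renal_clearance_rule, "explicit")) {
    check_number(phys$renal_clearance_l_h, "renal_clearance_l_h", 0)
    phys$renal_clearance_l_h
  } else {
    drug$fup * phys$gfr
  }
}
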