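#' Construct a drug record
#'
#' A `drug_record` collects the compound-level physicochemical and
#' biopharmaceutical parameters consumed by the PBPK/PBBM simulators:
#' molecular weight, lipophilicity, ionisation, aqueous and biorelevant
#' solubilities, diffusion coefficient, true density, interfacial tension,
#' plasma protein binding, blood-to-plasma ratio, effective intestinal
#' permeability, and enzyme kinetics.
#'
#' Solubilisation in luminal fluid is parameterised by the two biorelevant
#' solubility points (`sol_fassif` at `bile_fassif_mM`, `sol_fessif` at
#' `bile_fessif_mM`); [luminal_solubility()] fits a linear bile-salt
#' solubilisation slope through them. `bile_sr` stores the fitted
#' solubilisation ratio of the source model and acts as a dimensionless
#' multiplier on that slope relative to `bile_sr_ref` (so sweeping `bile_sr`
#' in a sensitivity analysis scales luminal solubilisation proportionally).
#'
#' @param name compound name.
#' @param mw molecular weight (g/mol).
#' @param logp log octanol-water partition coefficient.
#' @param pka acid dissociation constant; `pka_type` is `"acid"` or `"base"`.
#' @param diff_coeff aqueous diffusion coefficient (cm^2/s).
#' @param density true crystal density (g/mL).
#' @param sol_aq intrinsic aqueous solubility (mg/mL) at `sol_aq_ph`.
#' @param sol_fassif,sol_fessif solubility in fasted/fed simulated intestinal
#'   fluid (mg/mL).
#' @param bile_fassif_mM,bile_fessif_mM nominal bile-salt concentrations (mM)
#'   of the two biorelevant media.
#' @param solubilization_factor dimensionless solubilisation factor
#'   (stored; not used by the simulators).
#' @param bile_sr fitted luminal solubilisation ratio (dimensionless).
#' @param bile_sr_ref reference value of `bile_sr` at which the biorelevant
#'   calibration holds.
#' @param interfacial_tension crystal-medium interfacial tension (J/m^2).
#' @param nano_factor flat solubility multiplier (>= 1) applied to particles
#'   at or below `nano_radius_um` when the nano effect is enabled.
#' @param nano_radius_um radius threshold (um) for the nano effect.
#' @param fup fraction unbound in plasma (0-1].
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @param peff effective intestinal permeability (cm/s) for the species the
#'   record parameterises.
#' @param enzymes list of [enzyme_kinetics()] entries.
#' @param kaff surfactant affinity slope (mg/mL/mM), in vitro media only.
#' @return object of class `drug_record`.
#' @seealso [load_drug_record()], [efavirenz_drug()]
#' @export
drug_record <- function(name, mw, logp, pka, pka_type = c("acid", "base"),
                        diff_coeff, density,
                        sol_aq, sol_aq_ph = 7, sol_fassif, sol_fessif,
                        bile_fassif_mM = 3, bile_fessif_mM = 15,
                        solubilization_factor = NA_real_,
                        bile_sr = 1, bile_sr_ref = bile_sr,
                        interfacial_tension = NA_real_,
                        nano_factor = 1, nano_radius_um = 1,
                        fup, bp_ratio, peff,
                        enzymes = list(), kaff = 0) {
  pka_type <- match.arg(pka_type)
  check_number(mw, "mw", 0, strict_lower = TRUE)
  check_number(diff_coeff, "diff_coeff", 0, strict_lower = TRUE)
  check_number(density, "density", 0, strict_lower = TRUE)
  check_number(sol_aq, "sol_aq", 0, strict_lower = TRUE)
  check_number(sol_fassif, "sol_fassif", 0, strict_lower = TRUE)
  check_number(sol_fessif, "sol_fessif", 0, strict_lower = TRUE)
  check_number(fup, "fup", 0, 1, strict_lower = TRUE)
  check_number(bp_ratio, "bp_ratio", 0, strict_lower = TRUE)
  check_number(peff, "peff", 0)
  check_number(nano_factor, "nano_factor", 1)
  check_number(kaff, "kaff", 0)
  if (sol_fassif < sol_aq)
    stopf("solubility ordering violated: sol_fassif (%g) < sol_aq (%g)", sol_fassif, sol_aq)
  if (sol_fessif < sol_fassif)
    stopf("solubility ordering violated: sol_fessif (%g) < sol_fassif (%g)", sol_fessif, sol_fassif)
  if (!is.list(enzymes) || (length(enzymes) && !all(vapply(enzymes, inherits, TRUE, "enzyme_kinetics"))))
    stopf("'enzymes' must be a list of enzyme_kinetics objects")
  structure(list(
    name = as.character(name), mw = mw, logp = logp, pka = pka,
    pka_type = pka_type, diff_coeff = diff_coeff, density = density,
    sol_aq = sol_aq, sol_aq_ph = sol_aq_ph,
    sol_fassif = sol_fassif, sol_fessif = sol_fessif,
    bile_fassif_mM = bile_fassif_mM, bile_fessif_mM = bile_fessif_mM,
    solubilization_factor = solubilization_factor,
    bile_sr = bile_sr, bile_sr_ref = bile_sr_ref,
    interfacial_tension = interfacial_tension,
    nano_factor = nano_factor, nano_radius_um = nano_radius_um,
    fup = fup, bp_ratio = bp_ratio, peff = peff,
    enzymes = enzymes, kaff = kaff
  ), class = "drug_record")
}

#' Enzyme Michaelis-Menten kinetics
#'
#' @param enzyme enzyme name (e.g. `"CYP2B2"`).
#' @param site `"liver"` for systemic-hepatic metabolism or `"gut"` for
#'   enterocyte first-pass metabolism.
#' @param vmax whole-organ maximal rate (mg/s).
#' @param km Michaelis constant (mg/L).
#' @return object of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(enzyme, site = c("liver", "gut"), vmax, km) {
  site <- match.arg(site)
  check_number(vmax, "vmax", 0)
  check_number(km, "km", 0, strict_lower = TRUE)
  structure(list(enzyme = as.character(enzyme), site = site, vmax = vmax, km = km),
            class = "enzyme_kinetics")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s\n", x$name))
  cat(sprintf("  MW %.2f g/mol | logP %.2f | pKa %.2f (%s)\n", x$mw, x$logp, x$pka, x$pka_type))
  cat(sprintf("  sol %.4g mg/mL (pH %.2f) | FaSSIF %.4g | FeSSIF %.4g\n",
              x$sol_aq, x$sol_aq_ph, x$sol_fassif, x$sol_fessif))
  cat(sprintf("  fup %.4g | B:P %.3g | Peff %.4g cm/s | %d enzyme(s)\n",
              x$fup, x$bp_ratio, x$peff, length(x$enzymes)))
  invisible(x)
}

drug_fields_mandatory <- c("name", "mw", "logp", "pka", "diff_coeff", "density",
                           "sol_aq", "sol_fassif", "sol_fessif", "fup",
                           "bp_ratio", "peff")

#' Read a drug record from a YAML configuration file
#'
#' The file holds one mapping with the fields of [drug_record()]; `fup` may be
#' given either as `fup` (fraction) or `fup_percent` (percent unbound, as such
#' values are usually tabulated for highly bound drugs); enzymes are a list of
#' mappings with `enzyme`, `site`, `vmax_mg_s`, `km_mg_l`.
#'
#' @param path path to the YAML file.
#' @return validated [drug_record()].
#' @export
load_drug_record <- function(path) {
  if (!file.exists(path)) stopf("drug config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg[["fup_percent"]]) && is.null(cfg[["fup"]]))
    cfg$fup <- cfg$fup_percent / 100
  # coerce any scientific-notation scalars the YAML parser left as strings
  cfg <- lapply(cfg, function(x)
    if (is.character(x) && length(x) == 1L && grepl("^[0-9.+-]+e[0-9+-]+$", x))
      as.numeric(x) else x)
  missing <- setdiff(drug_fields_mandatory, names(cfg))
  if (length(missing))
    stopf("drug config schema error: missing mandatory field(s): %s",
          paste(missing, collapse = ", "))
  enz <- lapply(cfg$enzymes %||% list(), function(e) {
    enzyme_kinetics(e$enzyme, e$site, e$vmax_mg_s, e$km_mg_l)
  })
  drug_record(
    name = cfg$name, mw = cfg$mw, logp = cfg$logp, pka = cfg$pka,
    pka_type = cfg$pka_type %||% "acid",
    diff_coeff = cfg$diff_coeff, density = cfg$density,
    sol_aq = cfg$sol_aq, sol_aq_ph = cfg$sol_aq_ph %||% 7,
    sol_fassif = cfg$sol_fassif, sol_fessif = cfg$sol_fessif,
    bile_fassif_mM = cfg$bile_fassif_mM %||% 3,
    bile_fessif_mM = cfg$bile_fessif_mM %||% 15,
    solubilization_factor = cfg$solubilization_factor %||% NA_real_,
    bile_sr = cfg$bile_sr %||% 1, bile_sr_ref = cfg$bile_sr_ref %||% cfg$bile_sr %||% 1,
    interfacial_tension = cfg$interfacial_tension %||% NA_real_,
    nano_factor = cfg$nano_factor %||% 1,
    nano_radius_um = cfg$nano_radius_um %||% 1,
    fup = cfg$fup, bp_ratio = cfg$bp_ratio, peff = cfg$peff,
    enzymes = enz, kaff = cfg$kaff %||% 0
  )
}

#' Write a drug record to a YAML configuration file
#'
#' Inverse of [load_drug_record()]; a write-then-read round trip reproduces
#' every field.
#'
#' @param drug a [drug_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_record <- function(drug, path) {
  stopifnot(inherits(drug, "drug_record"))
  cfg <- unclass(drug)
  cfg$enzymes <- lapply(drug$enzymes, function(e)
    list(enzyme = e$enzyme, site = e$site, vmax_mg_s = e$vmax, km_mg_l = e$km))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Packaged efavirenz drug records
#'
#' Returns the efavirenz parameter set used throughout the package's worked
#' example, per species (the two species differ in permeability, plasma
#' binding, blood-to-plasma ratio, and enzyme panel: CYP2B2 + CYP3A9 in rat,
#' CYP2B6 + CYP3A4 in human).
#'
#' @param species `"rat"` or `"human"`.
#' @return a [drug_record()].
#' @export
efavirenz_drug <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("efavirenz_", species, ".yaml"),
                      package = "nanopbpk", mustWork = TRUE)
  load_drug_record(path)
}
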