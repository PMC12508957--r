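# Synthetic-data generators: dissolution-profile fixtures matching the case
# study's printed summary statistics, and noisy "observed" pharmacokinetic
# datasets generated from the model itself.
#
# True observed curves of the source study exist only as figures, so every
# "observed" dataset here is a model-generated stand-in: tests that would
# compare model vs external data become parameter-recovery / self-coverage
# tests. This substitution is documented prominently in the methods vignette.

fixture_psd_specs <- list(
  raw = list(mean = 44.15, sd = 42.5, n_bins = 8, surfactant_mM = 8.7,
             dose = 100, de_band = c(45, 60), min_15min = NA),
  nc = list(mean = 11.4, sd = 7.15, n_bins = 10, surfactant_mM = 8.7,
            dose = 100, de_band = c(85, 95), min_15min = 85),
  tablet = list(mean = 13.77, sd = 27.5, n_bins = 10, surfactant_mM = 17.4,
                dose = 600, de_band = NULL, min_15min = NA)
)

#' Generate a dissolution-profile fixture
#'
#' Simulates the USP II test from the named kind's particle size distribution
#' (raw material 44.15 +/- 42.5 um / 8 bins in 0.25% SLS; nanocrystals
#' 11.4 +/- 7.15 um / 10 bins in 0.25% SLS; IR tablet 13.77 +/- 27.5 um /
#' 10 bins in 0.5% SLS), asserts the kind's summary constraint on the
#' noise-free profile (raw: DE within 45-60%; nanocrystals: >= 85% dissolved
#' at 15 min and DE within 85-95%), then adds multiplicative log-normal
#' noise.
#'
#' @param kind `"raw"`, `"nc"` or `"tablet"`.
#' @param noise_cv noise CV in percent (0 = deterministic profile).
#' @param seed RNG seed.
#' @param drug a [drug_record()]; defaults to the packaged record.
#' @return a [dissolution_profile()]; attributes `kind`, `seed`, `noise_cv`.
#' @export
make_dissolution_fixture <- function(kind = c("raw", "nc", "tablet"),
                                     noise_cv = 1, seed = 42,
                                     drug = efavirenz_drug("rat")) {
  kind <- match.arg(kind)
  sp <- fixture_psd_specs[[kind]]
  medium <- dissolution_medium(900, sp$surfactant_mM, kaff = drug$kaff)
  times <- c(5, 10, 15, 30, 45, 60, 90, 120, 150)
  prof <- simulate_usp2(expand_psd(sp$mean, sp$sd, sp$n_bins), drug, medium,
                        sp$dose, times)
  de <- dissolution_efficiency(prof)
  if (!is.null(sp$de_band) && (de < sp$de_band[1] || de > sp$de_band[2]))
    stopf("fixture '%s' violates its DE constraint: %.1f%% outside [%g, %g]",
          kind, de, sp$de_band[1], sp$de_band[2])
  if (is.finite(sp$min_15min) &&
      prof$percent_dissolved[times == 15] < sp$min_15min)
    stopf("fixture '%s' violates the 15-min constraint (%.1f%% < %g%%)",
          kind, prof$percent_dissolved[times == 15], sp$min_15min)
  if (noise_cv > 0) {
    set.seed(seed)
    noisy <- prof$percent_dissolved * lognormal_deviate(length(times), noise_cv)
    prof$percent_dissolved <- pmin(noisy, 105)
  }
  attr(prof, "kind") <- kind
  attr(prof, "seed") <- seed
  attr(prof, "noise_cv") <- noise_cv
  prof
}

pk_scenarios <- list(
  rat_iv_2 = list(species = "rat", route = "iv", dose_mg_kg = 2,
                  duration = 24),
  rat_iv_5 = list(species = "rat", route = "iv", dose_mg_kg = 5,
                  duration = 24),
  rat_po_raw = list(species = "rat", route = "po", dose_mg_kg = 20,
                    psd = c(44.15, 42.5, 8), nano = FALSE, duration = 10),
  rat_po_nc = list(species = "rat", route = "po", dose_mg_kg = 20,
                   psd = c(11.4, 7.15, 10), nano = TRUE, duration = 10),
  human_po_nc_350 = list(species = "human", route = "po", dose_mg = 350,
                         psd = c(11.4, 7.15, 10), nano = TRUE, duration = 192),
  human_po_tablet_600 = list(species = "human", route = "po", dose_mg = 600,
                             psd = c(13.77, 27.5, 10), nano = FALSE,
                             duration = 192, form = "oral_tablet")
)

# base simulation for a named scenario (shared by fixtures and workflow)
simulate_scenario <- function(scenario) {
  sc <- pk_scenarios[[scenario]]
  if (is.null(sc)) stopf("unknown scenario '%s'", scenario)
  drug <- efavirenz_drug(sc$species)
  phys <- load_physiology(sc$species)
  dose <- if (!is.null(sc[["dose_mg"]])) sc[["dose_mg"]]
          else sc[["dose_mg_kg"]] * phys$body_weight
  if (sc$route == "iv") {
    simulate_iv(drug, phys, dose, sc$duration)
  } else {
    ps <- expand_psd(sc$psd[1], sc$psd[2], sc$psd[3])
    form <- formulation(sc$form %||% "oral_suspension", dose = dose, psd = ps,
                        nano_effect = isTRUE(sc$nano))
    simulate_oral(drug, phys, form, sc$duration)
  }
}

# the blood-sampling schedule of the oral rat study (h)
rat_sampling_times <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 10)
human_sampling_times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 48, 72, 96,
                          120, 144, 168, 192)
rat_iv_sampling_times <- c(0.083, 0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)

#' Generate a synthetic "observed" pharmacokinetic dataset
#'
#' Simulates a named model scenario, samples the profile at the scenario's
#' blood-sampling schedule, and adds per-subject multiplicative log-normal
#' residual noise. With `noise_cv = 0` and one subject the dataset equals the
#' model prediction at the sampling times.
#'
#' @param scenario one of `"rat_iv_2"`, `"rat_iv_5"`, `"rat_po_raw"`,
#'   `"rat_po_nc"`, `"human_po_nc_350"`, `"human_po_tablet_600"`.
#' @param noise_cv residual CV in percent.
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @return long-format data.frame with `subject`, `time_h`, `conc_ng_ml`;
#'   attribute `scenario`.
#' @export
make_observed_pk <- function(scenario, noise_cv = 20, n_subjects = 1,
                             seed = 42) {
  res <- simulate_scenario(scenario)
  sc <- pk_scenarios[[scenario]]
  sched <- if (sc$route == "iv") rat_iv_sampling_times
           else if (sc$species == "rat") rat_sampling_times
           else human_sampling_times
  sched <- sched[sched <= max(res$time) + 1e-9]
  base <- stats::approx(res$time, res$conc, sched)$y
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = s, time_h = sched,
               conc_ng_ml = base * lognormal_deviate(length(base), noise_cv))
  }))
  attr(out, "scenario") <- scenario
  out
}

#' Write/read a concentration-time or dissolution CSV
#'
#' Plain two-column CSV (`time`, `value`) with a unit-bearing header.
#'
#' @param time,value numeric vectors.
#' @param path file path.
#' @param time_unit,value_unit unit strings for the header.
#' @return `path` (write) or a data.frame with `time`, `value` and unit
#'   attributes (read).
#' @export
write_profile_csv <- function(time, value, path, time_unit = "h",
                              value_unit = "ng/mL") {
  df <- data.frame(time, value)
  names(df) <- c(paste0("time_", time_unit),
                 paste0("value_", gsub("[^A-Za-z0-9]+", "_", value_unit)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stopf("expected a two-column time/value CSV")
  out <- data.frame(time = df[[1]], value = df[[2]])
  attr(out, "time_col") <- names(df)[1]
  attr(out, "value_col") <- names(df)[2]
  out
}
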