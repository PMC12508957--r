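# Shared fixtures. Heavy simulations are computed lazily and cached so the
# suite runs each of them once regardless of how many tests consume them.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

rat_drug <- function() cached("rat_drug", efavirenz_drug("rat"))
human_drug <- function() cached("human_drug", efavirenz_drug("human"))
rat_phys <- function() cached("rat_phys", load_physiology("rat"))
human_phys <- function() cached("human_phys", load_physiology("human"))

nc_psd <- function() cached("nc_psd", expand_psd(11.4, 7.15, 10))
raw_psd <- function() cached("raw_psd", expand_psd(44.15, 42.5, 8))

rat_iv <- function(dose_mg_kg = 2) {
  cached(paste0("rat_iv_", dose_mg_kg),
         simulate_iv(rat_drug(), rat_phys(), dose_mg_kg * 0.35, 24))
}

rat_oral_nc <- function() cached("rat_oral_nc", {
  form <- formulation("oral_suspension", dose = 7, psd = nc_psd(),
                      nano_effect = TRUE)
  simulate_oral(rat_drug(), rat_phys(), form, 10)
})

rat_oral_raw <- function() cached("rat_oral_raw", {
  form <- formulation("oral_suspension", dose = 7, psd = raw_psd())
  simulate_oral(rat_drug(), rat_phys(), form, 10)
})

human_oral_nc <- function() cached("human_oral_nc", {
  form <- formulation("oral_suspension", dose = 350, psd = nc_psd(),
                      nano_effect = TRUE)
  simulate_oral(human_drug(), human_phys(), form, 192, dt_out = 0.1)
})

nc_fixture <- function() cached("nc_fixture",
                                make_dissolution_fixture("nc", noise_cv = 0))
raw_fixture <- function() cached("raw_fixture",
                                 make_dissolution_fixture("raw", noise_cv = 0))

# a minimal linear one-compartment reduction of the PBPK model: one dominant
# tissue with Kp = 1, near-instant flows, explicit (linear, renal-slot)
# clearance, no enzymes
one_compartment_setup <- function(cl_l_h = 0.5) {
  drug <- drug_record(
    name = "probe", mw = 300, logp = 2, pka = 7, diff_coeff = 7e-6,
    density = 1.2, sol_aq = 1, sol_fassif = 1, sol_fessif = 1,
    fup = 1, bp_ratio = 1, peff = 1e-4, enzymes = list())
  phys <- load_physiology("rat")
  phys$tissues$kp <- 1
  co <- 5000  # near-instant distribution: the body collapses to one pool
  fl <- phys$tissues$flow
  fl[] <- co * fl / sum(fl[phys$tissues$name != "lung"])
  phys$tissues$flow <- fl
  phys$tissues$flow[phys$tissues$name == "lung"] <-
    sum(fl[phys$tissues$name != "lung"])
  phys$cardiac_output <- sum(fl[phys$tissues$name != "lung"])
  phys$renal_clearance_rule <- "explicit"
  phys$renal_clearance_l_h <- cl_l_h
  list(drug = drug, phys = phys,
       v_total = steady_state_vd(phys, drug))
}
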