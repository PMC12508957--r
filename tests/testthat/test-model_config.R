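# Domain types, readers/validators, physiology tables, PSD discretisation.

test_that("packaged drug records carry the case-study parameters", {
  d <- rat_drug()
  expect_equal(d$mw, 315.67)
  expect_equal(d$logp, 4.6)
  expect_equal(d$pka, 10.2)
  expect_equal(d$diff_coeff, 0.7473e-5)
  expect_equal(d$density, 1.395)
  expect_equal(d$sol_aq, 0.009)
  expect_equal(d$sol_fassif, 0.182)
  expect_equal(d$sol_fessif, 0.847)
  expect_equal(d$nano_factor, 1.381)
  expect_equal(d$fup, 0.0058)   # printed as percent unbound, stored as fraction
  expect_equal(d$bp_ratio, 0.92)
  expect_equal(d$peff, 1.658e-4)
  expect_equal(d$kaff, 0.0755)
  expect_length(d$enzymes, 3)
  h <- human_drug()
  expect_equal(h$fup, 0.0022)
  expect_equal(h$bp_ratio, 0.74)
  expect_equal(h$peff, 7.385e-4)
})

test_that("drug record invariants are enforced", {
  base <- list(name = "x", mw = 300, logp = 2, pka = 7, diff_coeff = 7e-6,
               density = 1.2, sol_aq = 0.01, sol_fassif = 0.1,
               sol_fessif = 0.5, fup = 0.5, bp_ratio = 1, peff = 1e-4)
  mk <- function(...) {
    args <- utils::modifyList(base, list(...))
    do.call(drug_record, args)
  }
  expect_s3_class(mk(), "drug_record")
  expect_error(mk(fup = 0), "fup")
  expect_error(mk(fup = 1.2), "fup")
  expect_error(mk(sol_fassif = 0.005), "ordering")
  expect_error(mk(sol_fessif = 0.05), "ordering")
  expect_error(mk(density = -1), "density")
  expect_error(mk(nano_factor = 0.5), "nano_factor")
})

test_that("drug config reader validates the schema and round-trips", {
  path <- system.file("extdata", "efavirenz_rat.yaml", package = "nanopbpk")
  d <- load_drug_record(path)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_drug_record(d, tmp)
  d2 <- load_drug_record(tmp)
  expect_equal(d2, d)

  cfg <- yaml::read_yaml(path)
  cfg$mw <- NULL
  tmp2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp2)
  expect_error(load_drug_record(tmp2), "mw")
  expect_error(load_drug_record("no/such/file.yaml"), "not found")
})

test_that("species physiologies are scaled, Kp-filled, and flow-balanced", {
  rat <- rat_phys()
  expect_equal(nrow(rat$tissues), 13)
  expect_equal(rat$body_weight, 0.35)
  expect_equal(rat$tissues$kp[rat$tissues$name == "adipose"], 69.58)
  hum <- load_physiology("human", 67.73)
  expect_equal(hum$tissues$kp[hum$tissues$name == "adipose"], 27.59)
  for (p in list(rat, hum)) {
    sys <- p$tissues$name != "lung"
    expect_equal(sum(p$tissues$flow[sys]), p$cardiac_output,
                 tolerance = 1e-9)
    expect_true(all(p$tissues$volume > 0))
    expect_identical(p$gi$name[c(1, 9)], c("stomach", "colon"))
  }
  # linear body-weight scaling
  rat2 <- load_physiology("rat", 0.70)
  expect_equal(rat2$tissues$volume, 2 * rat$tissues$volume)
  expect_error(load_physiology("rat", -1), "body_weight")
})

test_that("expand_psd discretises a log-normal with exact moment recovery", {
  # degenerate: single bin at the mean
  p1 <- expand_psd(10, 1e-9, 1)
  expect_equal(p1$radius_um, 10)
  expect_equal(p1$mass_fraction, 1)

  # moment recovery, checked against the Monte Carlo oracle of the fitted
  # log-normal (1e6 samples, seed 99): mean 44.08, sd 42.33 for the raw PSD
  # and 11.40 / 7.15 for the nanocrystal PSD -- i.e. the continuous law has
  # the requested arithmetic moments; the bins must keep them within 2%.
  for (case in list(c(44.15, 42.5, 8), c(11.4, 7.15, 10), c(13.77, 27.5, 10))) {
    ps <- expand_psd(case[1], case[2], case[3])
    m <- psd_moments(ps)
    expect_equal(unname(m["mean"]), case[1], tolerance = 0.02)
    expect_equal(unname(m["sd"]), case[2], tolerance = 0.02)
    expect_equal(sum(ps$mass_fraction), 1, tolerance = 1e-12)
    expect_true(all(diff(ps$radius_um) > 0))
  }
  expect_error(expand_psd(-1, 1, 5), "mean_radius")
  expect_error(expand_psd(10, 0, 5), "sd_radius")
  expect_error(expand_psd(10, 5, 0), "n_bins")
})

test_that("psd constructor enforces its invariants", {
  expect_error(psd(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(psd(c(2, 1), c(0.5, 0.5)), "increasing")
  expect_error(psd(c(-1, 2), c(0.5, 0.5)), "positive")
  expect_error(formulation("oral_suspension", dose = 10), "psd")
  expect_error(formulation("oral_suspension", dose = -1,
                           psd = expand_psd(10, 5, 4)), "dose")
})
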