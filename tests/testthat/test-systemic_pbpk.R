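# Whole-body PBPK core: kinetics primitives, analytic reductions, mass
# balance, dose linearity.

test_that("Michaelis-Menten rate: limits and half-saturation", {
  expect_equal(michaelis_menten_rate(0.05, 3.914, 1e9), 0.05, tolerance = 1e-6)
  expect_equal(michaelis_menten_rate(0.3, 2, 0), 0)
  # half-saturation: c = Km gives vmax/2
  expect_equal(michaelis_menten_rate(0.0517, 0.9035, 0.9035), 0.02585)
  expect_error(michaelis_menten_rate(-1, 1, 1), "vmax")
  expect_error(michaelis_menten_rate(1, 0, 1), "km")
  expect_error(michaelis_menten_rate(1, 1, -1), "c_unbound")
})

test_that("lumped linear model reproduces the one-compartment solution", {
  setup <- one_compartment_setup(cl_l_h = 0.5)
  dose <- 1
  res <- simulate_iv(setup$drug, setup$phys, dose, duration = 12, dt_out = 0.05)
  v <- setup$v_total
  k <- 0.5 / v
  t <- res$time[res$time >= 0.2]          # past the mixing transient
  analytic <- dose / v * exp(-k * t) * 1000
  expect_equal(res$conc[res$time >= 0.2], analytic, tolerance = 1e-3)

  cs <- clearance_summary(res)
  expect_equal(cs$cl_total_l_h, 0.5, tolerance = 5e-3)
  expect_equal(unname(cs$fraction_renal), 1 - exp(-k * 12), tolerance = 1e-3)
})

test_that("i.v. simulation conserves mass and eliminates monotonically", {
  res <- rat_iv(2)
  expect_lt(res$mass_balance_error, 1e-3)
  pools <- res$pools
  elim <- rowSums(pools[, grep("^met_|^renal$", names(pools)), drop = FALSE])
  in_body <- res$mass_total - elim
  expect_true(all(diff(in_body) <= 1e-9))
  expect_true(all(res$conc >= 0))
  expect_error(simulate_iv(rat_drug(), rat_phys(), -1, 24), "dose")
})

test_that("dose-response: superposition in the linear regime and the
           case-study dose-proportionality ratio", {
  # far below Km the model is linear: doubling dose doubles concentrations
  lo <- simulate_iv(rat_drug(), rat_phys(), 1e-4, 6, dt_out = 0.1)
  hi <- simulate_iv(rat_drug(), rat_phys(), 2e-4, 6, dt_out = 0.1)
  keep <- lo$conc > max(lo$conc) * 1e-6
  expect_equal(hi$conc[keep] / lo$conc[keep], rep(2, sum(keep)),
               tolerance = 1e-4)

  # at study doses mild enzyme saturation makes the 5:2 mg/kg AUC ratio
  # slightly exceed the linear 2.5
  a2 <- nca(rat_iv(2))$auc_inf
  a5 <- nca(rat_iv(5))$auc_inf
  expect_equal(a5 / a2, 2.5, tolerance = 0.01)
})

test_that("steady-state Vd: identity case, case-study values, missing Kp", {
  phys <- rat_phys()
  drug <- rat_drug()
  phys_id <- phys
  phys_id$tissues$kp <- 1
  drug_id <- drug; drug_id$bp_ratio <- 1
  expect_equal(steady_state_vd(phys_id, drug_id),
               sum(phys$tissues$volume) + phys$venous_volume + phys$arterial_volume)
  phys_na <- phys; phys_na$tissues$kp[3] <- NA
  expect_error(steady_state_vd(phys_na, drug), "Kp")
})

test_that("clearance summary flags inestimable AUCinf and route fractions", {
  res <- rat_iv(2)
  cs <- clearance_summary(res)
  expect_lt(cs$fraction_renal, 0.01 * sum(cs$fraction_metabolized))
  expect_equal(sum(cs$fraction_metabolized) + cs$fraction_renal, 1,
               tolerance = 1e-3)

  # zero elimination: flat profile, no terminal slope
  setup <- one_compartment_setup(cl_l_h = 0)
  setup$phys$renal_clearance_rule <- "explicit"
  setup$phys$renal_clearance_l_h <- 0
  res0 <- simulate_iv(setup$drug, setup$phys, 1, 12, dt_out = 0.5)
  expect_error(clearance_summary(res0), "not estimable")
})
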