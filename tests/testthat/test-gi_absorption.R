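# GI absorption stage: luminal solubility, nano effect, particle
# dissolution, and the coupled oral simulation.

test_that("luminal solubility reproduces aqueous and biorelevant points", {
  d <- rat_drug()
  expect_equal(luminal_solubility(d, list(ph = 6.97, bile_mM = 0)), 0.009)
  expect_equal(luminal_solubility(d, list(ph = 6.5, bile_mM = 3)), 0.182,
               tolerance = 1e-3)
  expect_equal(luminal_solubility(d, list(ph = 5.0, bile_mM = 15)), 0.847,
               tolerance = 1e-3)
  # monotone in bile; nano multiplies below the threshold only
  s1 <- luminal_solubility(d, list(ph = 6.5, bile_mM = 5))
  s2 <- luminal_solubility(d, list(ph = 6.5, bile_mM = 10))
  expect_gt(s2, s1)
  expect_equal(luminal_solubility(d, list(ph = 6.5, bile_mM = 3),
                                  radius_um = 0.5, nano_effect = TRUE) /
               luminal_solubility(d, list(ph = 6.5, bile_mM = 3)),
               1.381)
  expect_error(luminal_solubility(d, list(ph = 6.5, bile_mM = -1)),
               "non-negative")
})

test_that("nano solubility factor: flat switch and Ostwald-Freundlich form", {
  d <- rat_drug()
  expect_equal(nano_solubility_factor(5, d, "flat"), 1)
  expect_equal(nano_solubility_factor(0.5, d, "flat"), 1.381)
  # independent closed-form evaluation at r = 100 nm, T = 310 K:
  # exp(2 * 0.02327 * (315.67/1.395 * 1e-6) / (1e-7 * 8.314462618 * 310))
  vm <- 315.67 / 1.395 * 1e-6
  expected <- exp(2 * 0.02327 * vm / (1e-7 * 8.314462618 * 310))
  expect_equal(nano_solubility_factor(0.1, d, "ostwald_freundlich"),
               expected, tolerance = 1e-10)
  expect_equal(expected, 1.0417, tolerance = 1e-4)
  # cap at the flat factor for very small radii
  expect_equal(nano_solubility_factor(0.001, d, "ostwald_freundlich"), 1.381)
  expect_error(nano_solubility_factor(0, d), "radius")
})

test_that("Wang-Flanagan rate: equilibrium, size ordering, depletion oracle", {
  d <- rat_drug()
  expect_equal(particle_dissolution_rate(10, 1, 0.5, 0.5, d, 100), 0)
  r_small <- particle_dissolution_rate(5, 1, 0, 0.5, d, 100)
  r_large <- particle_dissolution_rate(20, 1, 0, 0.5, d, 100)
  expect_gt(r_small, r_large)
  expect_error(particle_dissolution_rate(10, 1, 0, 0, d, 100), "solubility")

  # monodisperse bin under sink conditions: lsoda integration of the rate
  # law vs a brute-force fine-step Euler reference (dt -> 0)
  r0 <- 10; m0 <- 1; cs <- 0.5
  shrink <- function(m) r0 * (m / m0)^(1 / 3)
  rhs <- function(t, y, p) {
    m <- max(y[1], 0)
    if (m < 1e-12) return(list(0))
    list(-particle_dissolution_rate(shrink(m), m, 0, cs, d, 100))
  }
  out <- deSolve::lsoda(m0, seq(0, 0.2, by = 1e-4), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  dec <- c(TRUE, diff(out[, 2]) < 0)   # strictly decreasing part only
  t99_lsoda <- stats::approx(out[dec, 2], out[dec, 1], 0.01 * m0)$y
  m <- m0; t <- 0; dt <- 1e-5
  while (m > 0.01 * m0) {
    m <- m - dt * particle_dissolution_rate(shrink(m), m, 0, cs, d, 100)
    t <- t + dt
  }
  expect_equal(t99_lsoda, t, tolerance = 5e-3)
})

test_that("oral simulation: mass balance, zero-permeability limit, and
           solution dosing as the dissolution-free bound", {
  res <- rat_oral_nc()
  expect_lt(res$mass_balance_error, 1e-3)
  expect_true(all(res$conc >= 0))
  summ <- res$absorption
  expect_true(all(c(summ$fa, summ$fg, summ$fh, summ$f) >= 0 &
                  c(summ$fa, summ$fg, summ$fh, summ$f) <= 1))
  expect_gte(summ$fa, summ$fa * summ$fg)   # Fa bounds the portal fraction

  d0 <- rat_drug(); d0$peff <- 0
  form <- formulation("oral_suspension", dose = 7, psd = nc_psd(),
                      nano_effect = TRUE)
  res0 <- simulate_oral(d0, rat_phys(), form, 10)
  expect_lt(max(res0$conc), 1e-9)
  # everything still in the gut or already excreted, nothing absorbed
  last <- nrow(res0$pools)
  gut_and_feces <- res0$pools$gi_dissolved[last] + res0$pools$gi_solid[last] +
    res0$pools$feces[last]
  expect_equal(gut_and_feces, 7, tolerance = 1e-3)

  sol <- simulate_oral(rat_drug(), rat_phys(),
                       formulation("oral_solution", dose = 7), 10)
  n_sol <- nca(sol$time, sol$conc)
  n_nc <- nca(res$time, res$conc)
  expect_gte(n_sol$cmax * 1.001, n_nc$cmax)
  expect_gte(n_sol$auc_t * 1.001, n_nc$auc_t)
  expect_error(simulate_oral(rat_drug(), rat_phys(),
                             formulation("iv_bolus", dose = 7), 10), "simulate_iv")
})

test_that("exposure ordering: smaller particles and i.v. ceiling", {
  n_nc <- nca(rat_oral_nc())
  n_raw <- nca(rat_oral_raw())
  expect_gt(n_nc$cmax, n_raw$cmax)
  expect_gt(n_nc$auc_t, n_raw$auc_t)

  # oral bioavailability cannot exceed the i.v. reference at equal dose
  iv7 <- simulate_iv(rat_drug(), rat_phys(), 7, 24)
  expect_lt(n_nc$auc_t, nca(iv7)$auc_inf)
})
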