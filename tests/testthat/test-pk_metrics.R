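# NCA, fold-error statistics, steady-state metrics.

test_that("fold error and its aggregates match closed forms", {
  expect_equal(fold_error(560.4, 521.2), 1.07, tolerance = 5e-3)
  expect_equal(fold_error(1086.8, 970.4), 1.12, tolerance = 5e-3)
  expect_equal(fold_error(3, 3), 1)
  expect_error(fold_error(1, 0), "positive")

  expect_equal(afe(c(5, 5), c(5, 5)), 1)
  expect_equal(afe(c(2, 0.5), c(1, 1)), 1)      # geometric cancellation
  expect_equal(aafe(c(2, 0.5), c(1, 1)), 2)     # |log| symmetry
  # direct evaluation for FEs {1.07, 0.97, 0.74}
  expect_equal(afe(c(1.07, 0.97, 0.74), c(1, 1, 1)), 0.916, tolerance = 1e-3)
  expect_error(afe(numeric(0), numeric(0)), "at least one")
})

test_that("AAFE dominates AFE on random pair lists (Jensen property)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    pred <- exp(stats::rnorm(n)); obs <- exp(stats::rnorm(n))
    a <- afe(pred, obs); aa <- aafe(pred, obs)
    expect_gte(aa, 1)
    expect_gte(aa + 1e-12, a)
    expect_gte(aa + 1e-12, 1 / a)
  }
})

test_that("validation report applies the two-fold acceptance rule exactly", {
  rep_ok <- validation_report(c(1.2, 0.8, 1.5), c(1, 1, 1))
  expect_true(rep_ok$pass)
  # one FE outside [0.2, 2] fails even with acceptable AFE/AAFE
  rep_fe <- validation_report(c(2.2, 0.9, 1.0), c(1, 1, 1))
  expect_false(rep_fe$pass)
  # boundary: FE exactly 2 and 0.2 still pass the closed interval
  rep_edge <- validation_report(c(2, 0.2, 1), c(1, 1, 1))
  expect_true(all(rep_edge$fe >= 0.2 & rep_edge$fe <= 2))
  expect_identical(rep_edge$pass, rep_edge$afe < 2 && rep_edge$aafe < 2)
})

test_that("NCA: trapezoid rules, mono-exponential closed form, additivity", {
  # linear-up rule on a rising segment
  r <- nca(c(0, 1), c(0, 100))
  expect_equal(r$auc_t, 50)

  # C = 100 exp(-0.1 t): t1/2 = 6.93 h, AUCinf = C0/k = 1000
  t <- seq(0, 48, by = 0.5)
  r2 <- nca(t, 100 * exp(-0.1 * t))
  expect_equal(r2$t_half, log(2) / 0.1, tolerance = 1e-6)
  expect_equal(r2$auc_inf, 1000, tolerance = 1e-3)
  expect_equal(r2$cmax, 100)
  expect_equal(r2$tmax, 0)

  # AUC is additive over contiguous partitions
  prof <- rat_oral_nc()
  cut <- which.min(abs(prof$time - 4))
  a_full <- nca(prof$time, prof$conc)$auc_t
  a1 <- nca(prof$time[1:cut], prof$conc[1:cut])$auc_t
  a2 <- nca(prof$time[cut:length(prof$time)],
            prof$conc[cut:length(prof$time)])$auc_t
  expect_equal(a1 + a2, a_full, tolerance = 1e-9)

  # non-monotone tail: lambda_z not estimable, AUCinf flagged absent
  r3 <- nca(c(0, 1, 2, 3), c(10, 5, 4, 6))
  expect_true(is.na(r3$auc_inf))
  expect_error(nca(c(0, 1), c(1, -2)), "negative")
  expect_error(nca(c(0, 0), c(1, 1)), "increasing")
})

test_that("steady-state metrics match the analytic superposition profile", {
  # 1-compartment oral q24h at steady state (superposition closed form)
  ka <- 1; ke <- 0.05; tau <- 24; f_d_v <- 100
  css <- function(t) {
    f_d_v * ka / (ka - ke) *
      (exp(-ke * t) / (1 - exp(-ke * tau)) - exp(-ka * t) / (1 - exp(-ka * tau)))
  }
  t <- seq(0, tau, by = 0.05)
  conc <- css(t)
  ss <- steady_state_metrics(t, conc, tau)
  auc_analytic <- f_d_v / ke   # dose/CL per interval at steady state
  expect_equal(ss$auc_tau, auc_analytic, tolerance = 0.01)
  expect_equal(ss$cavg, auc_analytic / tau, tolerance = 0.01)
  expect_equal(ss$cmax_ss, max(conc))
  expect_true(ss$ctrough <= ss$cavg && ss$cavg <= ss$cmax_ss)
  expect_equal(ss$fluctuation_index,
               (max(conc) - conc[1]) / (auc_analytic / tau) * 100,
               tolerance = 0.03)

  # flat profile: zero fluctuation
  flat <- steady_state_metrics(t, rep(50, length(t)), tau)
  expect_equal(flat$fluctuation_index, 0)

  # accumulating (not yet at steady state) profile raises the drift flag
  t2 <- seq(0, 2 * tau, by = 0.1)
  accum <- steady_state_metrics(t2, t2, tau)   # linearly rising
  expect_false(accum$at_steady_state)
})
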