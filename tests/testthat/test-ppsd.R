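# USP II simulator, inverse P-PSD fitting, and in vitro metrics.

test_that("USP II simulator: sink limit, saturation arithmetic, mass
           conservation", {
  d <- rat_drug()
  med <- dissolution_medium(900, 8.7, kaff = 0.0755)
  # saturation solubility in 0.25% SLS: 0.009 + 0.0755 * 8.7 = 0.6659 mg/mL,
  # amply sink for 100 mg in 900 mL
  expect_equal(nanopbpk:::medium_solubility(d, med), 0.66585)

  tiny <- expand_psd(0.2, 0.05, 3)   # sub-micron: dissolves before 1st sample
  prof <- simulate_usp2(tiny, d, med, 100, c(5, 10, 15))
  expect_gt(prof$percent_dissolved[1], 99.9)

  ps <- nc_psd()
  prof2 <- simulate_usp2(ps, d, med, 100, c(5, 30, 150))
  expect_true(all(prof2$percent_dissolved <= 100 + 1e-6))
  expect_true(all(diff(prof2$percent_dissolved) >= -1e-9))
})

test_that("dissolution efficiency: closed forms and collinear invariance", {
  flat <- dissolution_profile(c(0, 50, 150), c(100, 100, 100))
  expect_equal(dissolution_efficiency(flat), 100)
  tri <- dissolution_profile(c(0, 150), c(0, 100))
  expect_equal(dissolution_efficiency(tri), 50)   # triangle area
  # inserting a redundant collinear point does not change DE
  tri2 <- dissolution_profile(c(0, 75, 150), c(0, 50, 100))
  expect_equal(dissolution_efficiency(tri2), 50)
  expect_error(dissolution_efficiency(tri, t_end = 500), "beyond")
})

test_that("f2 similarity: identity, closed-form offset, symmetry, window", {
  t <- c(5, 10, 15, 30, 45, 60)
  a <- dissolution_profile(t, c(10, 30, 50, 65, 75, 80))
  expect_equal(f2_similarity(a, a), 100)
  b <- a; b$percent_dissolved <- a$percent_dissolved + 10
  # constant 10-point offset: 50*log10(100/sqrt(101)) = 49.892
  expect_equal(f2_similarity(a, b), 50 * log10(100 / sqrt(101)))
  expect_equal(f2_similarity(a, b), 49.892, tolerance = 1e-4)
  expect_equal(f2_similarity(a, b), f2_similarity(b, a))
  # plateau rule: points after both profiles reach 85% are excluded
  t2 <- c(5, 10, 15, 30, 45, 60)
  r <- dissolution_profile(t2, c(40, 70, 88, 95, 99, 100))
  s <- dissolution_profile(t2, c(35, 65, 86, 94, 99, 100))
  full <- f2_similarity(r, s, window = "all")
  windowed <- f2_similarity(r, s)
  expect_gt(full, windowed)   # tail agreement no longer inflates similarity
})

test_that("crystallinity degree from fusion enthalpy", {
  expect_equal(crystallinity_degree(51.31, 1.0, 58), 88.46552, tolerance = 1e-5)
  expect_equal(crystallinity_degree(35.14, 0.9, 58), 67.31801, tolerance = 1e-5)
  expect_equal(crystallinity_degree(58, 1.0, 58), 100)
  expect_error(crystallinity_degree(50, 0, 58), "drug_mass_fraction")
})

test_that("P-PSD inversion recovers the generating distribution", {
  d <- rat_drug()
  # zero noise: perfect self-consistency, AFE = AAFE = 1
  fit0 <- fit_ppsd(nc_fixture(), d, n_bins = 10, init = c(20, 20), n_starts = 2)
  expect_equal(fit0$mean_radius, 11.4, tolerance = 0.02)
  expect_equal(fit0$afe, 1, tolerance = 1e-3)
  expect_equal(fit0$aafe, 1, tolerance = 1e-3)

  # 1% multiplicative noise: mean radius recovered within 10%
  noisy <- make_dissolution_fixture("nc", noise_cv = 1, seed = 11)
  fit1 <- fit_ppsd(noisy, d, n_bins = 10, init = c(20, 20), n_starts = 2)
  expect_equal(fit1$mean_radius, 11.4, tolerance = 0.10)

  # slow raw-material-like profile fits a much coarser distribution
  fit_raw <- fit_ppsd(raw_fixture(), d, n_bins = 8, init = c(20, 20),
                      n_starts = 2)
  expect_gt(fit_raw$mean_radius, 2 * fit1$mean_radius)

  flat <- dissolution_profile(c(5, 10, 15, 30), c(0, 0, 0, 0))
  flat$medium <- nc_fixture()$medium; flat$dose <- 100
  expect_error(fit_ppsd(flat, d), "degenerate")
  short <- dissolution_profile(c(5, 10), c(10, 20))
  short$medium <- nc_fixture()$medium; short$dose <- 100
  expect_error(fit_ppsd(short, d), "4 observed")
})
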