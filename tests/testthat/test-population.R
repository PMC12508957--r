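# Virtual-population sampling and band construction.

test_that("virtual-subject sampling: identity at CV=0, determinism,
           flow-balance preservation, sampled-CV accuracy", {
  spec0 <- variability_spec(0, 0, 0, 0, 0, 0)
  subj <- sample_virtual_subject(rat_phys(), rat_drug(), spec0)
  expect_equal(subj$phys$tissues, rat_phys()$tissues)
  expect_equal(subj$drug$peff, rat_drug()$peff)

  spec <- variability_spec()
  set.seed(123)
  s1 <- sample_virtual_subject(rat_phys(), rat_drug(), spec)
  set.seed(123)
  s2 <- sample_virtual_subject(rat_phys(), rat_drug(), spec)
  expect_identical(s1, s2)
  # flow balance survives perturbation
  sys <- s1$phys$tissues$name != "lung"
  expect_equal(sum(s1$phys$tissues$flow[sys]), s1$phys$cardiac_output,
               tolerance = 1e-9)
  expect_true(all(s1$phys$tissues$volume > 0))

  # Monte Carlo moment check: sampled CV of a 30% log-normal within 1%
  set.seed(7)
  x <- nanopbpk:::lognormal_deviate(1e4, 30)
  expect_equal(stats::sd(x) / mean(x), 0.30, tolerance = 0.01 / 0.30)
  expect_equal(mean(x), 1, tolerance = 0.01)
})

test_that("population bands: collapse at CV=0, nesting, reproducibility", {
  form <- formulation("oral_suspension", dose = 7, psd = nc_psd(),
                      nano_effect = TRUE)
  spec0 <- variability_spec(0, 0, 0, 0, 0, 0)
  pop0 <- run_population(rat_drug(), rat_phys(), form, n = 1, repeats = 1,
                         spec = spec0, duration = 10, seed = 5)
  expect_equal(pop0$bands$p5, pop0$bands$p95, tolerance = 1e-9)

  pop <- run_population(rat_drug(), rat_phys(), form, n = 3, repeats = 2,
                        duration = 10, seed = 5,
                        probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  b <- pop$bands
  expect_true(all(b$p5 <= b$p25 & b$p25 <= b$p50 &
                  b$p50 <= b$p75 & b$p75 <= b$p95))
  expect_equal(nrow(b), 150)
  pop2 <- run_population(rat_drug(), rat_phys(), form, n = 3, repeats = 2,
                         duration = 10, seed = 5,
                         probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_identical(pop$profiles, pop2$profiles)

  # coverage endpoints: the median band is inside; a shifted dataset is out
  med <- b$p50[c(20, 60, 100)]
  tt <- b$time[c(20, 60, 100)]
  expect_equal(coverage_check(tt, med, pop), 1)
  expect_equal(coverage_check(tt, med * 100, pop), 0)
  expect_error(coverage_check(numeric(0), numeric(0), pop), "empty")
  expect_error(coverage_check(c(-5), c(1), pop), "outside")
})
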