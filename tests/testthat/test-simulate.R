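# Cohort and consortium generation: mediation structure, calibration,
# reproducibility, and the summary-statistic sampling contract.

test_that("identical configs give bitwise-identical cohorts", {
  d1 <- simulate_cohort(tiny_config(seed = 5), 1)
  d2 <- simulate_cohort(tiny_config(seed = 5), 1)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(tiny_config(seed = 6), 1)
  expect_false(identical(d1, d3))
  # per-study substreams: study 2 is unchanged by generating study 1 first
  expect_identical(simulate_cohort(tiny_config(seed = 5), 2),
                   simulate_cohorts(tiny_config(seed = 5))[[2]])
})

test_that("null traits are independent of genotype", {
  cfg <- one_snp_config(seed = 3, n = 20000, theta = 0)
  d <- simulate_cohort(cfg, 1)
  f <- fit_linear_additive(d$snpA, d$glucose)
  expect_lt(abs(f$beta), 3 * f$se)
})

test_that("the noiseless mediation chain is exact", {
  cfg <- one_snp_config(seed = 4, n = 3000, theta = 0.09,
                        noise_sd = 1e-9, ldl_noise_sd = 1e-9)
  d <- simulate_cohort(cfg, 1)
  f <- fit_linear_additive(d$snpA, d$glucose)
  # glucose rises by theta * |beta_ldl| per LDL-lowering allele
  expect_lt(abs(f$beta - 0.09 * 0.3), 1e-6)
})

test_that("marginal per-allele trait effects equal theta * |beta_ldl|", {
  cfg <- one_snp_config(seed = 9, n = 150000)
  d <- simulate_cohort(cfg, 1)
  f_ldl <- fit_linear_additive(d$snpA, d$ldl)
  f_glu <- fit_linear_additive(d$snpA, d$glucose)
  expect_lt(abs(f_ldl$beta - (-0.3)), 3 * f_ldl$se)
  expect_lt(abs(f_glu$beta - 0.09 * 0.3), 3 * f_glu$se)
})

test_that("structural coefficients reproduce marginal targets under LD", {
  cfg <- sim_config(n_studies = 1, n_per_study = 200000, seed = 31,
                    traits = default_traits()["t2d"])
  b <- structural_betas(cfg)
  # no-LD limit: structural equals marginal
  cfg0 <- sim_config(n_studies = 1, n_per_study = 100,
                     ld_r2 = diag(4), seed = 1)
  expect_equal(unname(structural_betas(cfg0)),
               vapply(cfg0$variants, `[[`, 0, "beta_ldl"))
  # with LD: univariable fits recover the marginal targets
  d <- simulate_cohort(cfg, 1)
  for (v in cfg$variants) {
    f <- fit_linear_additive(d[[v$snp_id]], d$ldl)
    expect_lt(abs(f$beta - v$beta_ldl), 3.5 * f$se)
  }
  # and the multivariable fit recovers the structural coefficients
  snp_ids <- vapply(cfg$variants, `[[`, "", "snp_id")
  m <- fit_multivariable(d[, snp_ids], d$ldl, "gaussian")
  expect_true(all(abs(m$beta - b[m$snp_id]) < 3.5 * m$se))
})

test_that("diabetes cases always carry a case type", {
  d <- simulate_cohort(tiny_config(seed = 12, n = 4000), 1)
  expect_true(all(d$case_type[d$t2d == 1] %in% c("incident", "prevalent")))
  expect_true(all(d$case_type[d$t2d == 0] == "none"))
  frac_prev <- mean(d$case_type[d$t2d == 1] == "prevalent")
  expect_lt(abs(frac_prev - 0.5), 0.15)
})

test_that("BMI is weight over height squared", {
  d <- simulate_cohort(tiny_config(seed = 13, n = 500), 1)
  expect_equal(d$bmi, d$weight / d$height^2)
})

test_that("missingness injection is honoured and absent by default", {
  d0 <- simulate_cohort(tiny_config(seed = 14, n = 2000), 1)
  expect_false(anyNA(d0))
  cfg <- tiny_config(seed = 14, n = 2000, missing_rate = 0.1)
  d <- simulate_cohort(cfg, 1)
  expect_gt(mean(is.na(d$ldl)), 0.05)
  expect_lt(mean(is.na(d$ldl)), 0.15)
  # genotypes are never missing from the generator
  expect_false(anyNA(d$rs2479409))
})

test_that("consortium se follows the stated sampling-variance formula", {
  cfg <- one_snp_config(seed = 21, maf = 0.5, noise_sd = 1)
  rec <- emit_consortium_summary(cfg, "MAGIC", n_effective = 2000,
                                 traits = "glucose")
  expect_equal(rec$se, 1 / sqrt(1000), tolerance = 1e-12)
})

test_that("consortium beta converges to truth as n_effective grows", {
  cfg <- one_snp_config(seed = 22)
  rec <- emit_consortium_summary(cfg, "GLGC", n_effective = 1e12,
                                 traits = "ldl")
  expect_lt(abs(rec$beta - (-0.3)), 1e-4)
})

test_that("emitted beta dispersion matches the emitted se", {
  cfg <- one_snp_config(seed = 1)
  betas <- vapply(1:2000, function(i) {
    c2 <- cfg; c2$seed <- i
    emit_consortium_summary(c2, "GIANT", n_effective = 5000,
                            traits = "glucose")$beta
  }, 0)
  se <- emit_consortium_summary(cfg, "GIANT", 5000, traits = "glucose")$se
  expect_lt(abs(sd(betas) / se - 1), 0.05)
})

test_that("cohort TSV round-trips through the interchange format", {
  d <- simulate_cohort(tiny_config(seed = 17, n = 300), 1)
  dir <- tempfile(); dir.create(dir)
  p <- write_cohort_tsv(d, dir)
  d2 <- read_cohort_tsv(p)
  expect_identical(names(d2), names(d))
  expect_identical(d2$iid, d$iid)
  expect_identical(d2[[3]], d[[3]])                # dosage column, integer
  expect_equal(d2$ldl, signif(d$ldl, 6))           # 6-sig-digit float policy
})

test_that("config JSON round-trips", {
  cfg <- tiny_config(seed = 19, hwe_inbreeding = c(S02 = 0.1))
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$ld_r2, cfg$ld_r2)
  expect_equal(cfg2$hwe_inbreeding, cfg$hwe_inbreeding)
  expect_identical(simulate_cohort(cfg2, 1), simulate_cohort(cfg, 1))
})

test_that("invalid configurations are rejected with aggregated messages", {
  expect_error(sim_config(n_studies = 2, n_per_study = c(10, 10, 10)),
               "n_per_study")
  expect_error(sim_config(prevalent_fraction = 1.5), "prevalent_fraction")
  expect_error(one_snp_config(noise_sd = -1), "noise_sd")
  bad <- tiny_config()
  bad$ld_r2[1, 2] <- 0.5  # asymmetric
  expect_error(validate_sim_config(bad), "symmetric")
})
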