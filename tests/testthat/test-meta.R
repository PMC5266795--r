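# Pooling machinery: hand-computed oracles, algebraic invariants, and the
# bookkeeping of exclusions and source merging.

test_that("IVW fixed-effect matches the worked two-study example", {
  p <- ivw_fixed(c(0.10, 0.20), c(0.05, 0.10))
  expect_equal(p$beta, 0.12, tolerance = 1e-12)
  expect_equal(p$se, sqrt(1 / 500), tolerance = 1e-12)
  expect_equal(p$ci_low, 0.12 - 1.959964 * p$se, tolerance = 1e-12)
})

test_that("a single estimate is returned unchanged", {
  p <- ivw_fixed(0.3, 0.07)
  expect_equal(p$beta, 0.3)
  expect_equal(p$se, 0.07)
  expect_equal(p$k, 1L)
})

test_that("pooling is order-invariant and associative over sub-pools", {
  set.seed(10)
  beta <- rnorm(9); se <- runif(9, 0.05, 0.3)
  full <- ivw_fixed(beta, se)
  perm <- sample(9)
  expect_equal(ivw_fixed(beta[perm], se[perm]), full)
  # split into sub-pools, pool the sub-pool results: exact associativity
  a <- ivw_fixed(beta[1:4], se[1:4]); b <- ivw_fixed(beta[5:9], se[5:9])
  two <- ivw_fixed(c(a$beta, b$beta), c(a$se, b$se))
  expect_equal(two$beta, full$beta, tolerance = 1e-12)
  expect_equal(two$se, full$se, tolerance = 1e-12)
})

test_that("fixed-effect pooled se never exceeds the smallest input se", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    se <- runif(k, 0.01, 0.5)
    expect_lte(ivw_fixed(rnorm(k), se)$se, min(se))
  }
})

test_that("Cochran Q matches the worked example and homogeneity boundary", {
  expect_equal(cochran_q(c(0.10, 0.20), c(0.05, 0.10))$Q, 0.8,
               tolerance = 1e-12)
  h <- cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(h$Q, 0, tolerance = 1e-12)
  expect_equal(h$p_Q, 1)
  expect_true(is.na(cochran_q(0.1, 0.05)$Q))
})

test_that("I-squared point estimate and upper bound behave as specified", {
  i <- i_squared(4, 2)
  expect_equal(i$I2, 75)
  expect_gte(i$I2_upper, i$I2)
  expect_equal(i_squared(0, 5)$I2, 0)
  # k = 2 with Q <= k: upper bound undefined with reason
  low <- i_squared(1.5, 2)
  expect_true(is.na(low$I2_upper))
  expect_match(low$reason, "undefined")
  # bound ordering whenever defined
  set.seed(12)
  for (i in 1:20) {
    k <- sample(3:10, 1); Q <- runif(1, 0, 30)
    r <- i_squared(Q, k)
    if (!is.na(r$I2_upper)) expect_gte(r$I2_upper, r$I2)
  }
})

test_that("DerSimonian-Laird matches the worked example and boundaries", {
  r <- dl_random(c(0, 1), c(0.1, 0.1))
  expect_equal(r$tau2, 0.49, tolerance = 1e-12)
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  expect_equal(r$se, 0.5, tolerance = 1e-12)
  # Q <= k-1: tau2 = 0, random equals fixed exactly
  b <- c(0.1, 0.11, 0.09); s <- c(0.1, 0.1, 0.1)
  r0 <- dl_random(b, s); f0 <- ivw_fixed(b, s)
  expect_equal(r0$tau2, 0)
  expect_equal(r0$beta, f0$beta)
  expect_equal(r0$se, f0$se)
})

test_that("random-effects se is never below fixed-effect se", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    b <- rnorm(k, sd = 0.5); s <- runif(k, 0.05, 0.3)
    expect_gte(dl_random(b, s)$se, ivw_fixed(b, s)$se - 1e-12)
  }
})

test_that("Fisher's method matches the worked example and identities", {
  f <- fisher_combine(c(0.01, 0.04))
  expect_equal(f$X, -2 * (log(0.01) + log(0.04)), tolerance = 1e-12)
  expect_equal(f$X, 15.64809, tolerance = 1e-4)
  expect_equal(f$df, 4L)
  expect_equal(f$p, pchisq(f$X, 4, lower.tail = FALSE))
  expect_equal(fisher_combine(1)$p, 1)
  expect_equal(fisher_combine(0.37)$p, 0.37, tolerance = 1e-12)
  expect_warning(fisher_combine(c(0, 0.5)), "clipped")
})

test_that("merge_sources keeps bookkeeping and rejects ambiguity", {
  est <- data.frame(study_id = paste0("S", 1:5), snp_id = "rsX",
                    trait = "ldl", beta = c(0.1, 0.2, 0.15, 0.12, 0.18),
                    se = rep(0.05, 5), n = rep(1000, 5))
  # no overlap declared: everything pools together
  m0 <- merge_sources(est, NULL, list())
  expect_equal(nrow(m0$pooling), 5)
  expect_equal(nrow(m0$exclusions), 0)
  # consortium subsuming S1, S2: k = (5 - 2) + 1
  cons <- data.frame(source_id = "GLGC", snp_id = "rsX", trait = "ldl",
                     beta = 0.14, se = 0.02, n = 50000)
  m1 <- merge_sources(est, cons, list(GLGC = c("S1", "S2")))
  expect_equal(nrow(m1$pooling), 4)
  expect_setequal(m1$pooling$source, c("S3", "S4", "S5", "GLGC"))
  expect_equal(nrow(m1$exclusions), 2)
  expect_match(m1$exclusions$rule[1], "GLGC")
  # same study claimed by two sources: configuration error
  expect_error(
    merge_sources(est, cons, list(GLGC = "S1", DIAGRAM = "S1")),
    "ambiguous provenance")
})

test_that("excluding a pool-mean study keeps beta and inflates se", {
  beta <- c(0.1, 0.2, 0.15); se <- c(0.05, 0.05, 0.05)
  full <- ivw_fixed(beta, se)
  expect_equal(full$beta, 0.15, tolerance = 1e-12)
  drop <- ivw_fixed(beta[-3], se[-3])  # S3 sits exactly at the pool mean
  expect_equal(drop$beta, full$beta, tolerance = 1e-12)
  expect_gt(drop$se, full$se)
})

test_that("HWE filter removes violating (study, SNP) pairs only", {
  est <- expand.grid(study_id = c("S1", "S2"), snp_id = c("a", "b"),
                     trait = c("ldl", "t2d"), stringsAsFactors = FALSE)
  est$beta <- 0.1; est$se <- 0.05; est$n <- 100
  hwe <- data.frame(study_id = c("S1", "S1", "S2", "S2"),
                    snp_id = c("a", "b", "a", "b"),
                    p = c(0.5, 1e-9, 0.7, 0.2))
  hf <- hwe_filter(est, hwe, threshold_p = 1e-6)
  expect_equal(nrow(hf$estimates), 6)  # S1/b dropped for both traits
  expect_false(any(hf$estimates$study_id == "S1" &
                     hf$estimates$snp_id == "b"))
  expect_equal(nrow(hf$exclusions), 1)
  # all in HWE: no-op
  hwe_ok <- transform(hwe, p = pmax(p, 0.1))
  expect_equal(nrow(hwe_filter(est, hwe_ok, 1e-6)$estimates), nrow(est))
  # near-degenerate threshold draws a warning
  expect_warning(hwe_filter(est, hwe_ok, threshold_p = 0.99), "exclude")
  # strict mode errors on missing HWE results
  expect_error(hwe_filter(est, hwe[-1, ], 1e-6), "no HWE result")
  expect_warning(hwe_filter(est, hwe[-1, ], 1e-6, strict = FALSE),
                 "no HWE result")
})

test_that("an inbreeding-violating study is caught and excluded end-to-end", {
  cfg <- sim_config(n_studies = 3, n_per_study = 5000, seed = 77,
                    traits = default_traits()["t2d"],
                    hwe_inbreeding = c(S02 = 0.2))
  cohorts <- simulate_cohorts(cfg)
  assoc <- associate_cohorts(cohorts, cfg, strata = FALSE)
  hwe <- assoc$hwe
  # the injected study fails HWE for the common SNPs at n = 5000
  bad <- hwe[hwe$study_id == "S02" & hwe$snp_id == "rs2479409", ]
  expect_lt(bad$p, 1e-6)
  pooled <- pool_all(assoc$estimates, hwe, hwe_threshold_p = 1e-6)
  expect_true(any(pooled$exclusions$study_id == "S02" &
                    grepl("hwe", pooled$exclusions$rule)))
  # clean studies (F = 0) are retained
  expect_false(any(pooled$exclusions$study_id == "S01" &
                     grepl("hwe", pooled$exclusions$rule)))
})
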