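# Per-study fits and quality tests, checked against hand-solved oracles,
# reference implementations (lm/glm), and a brute-force likelihood search.

test_that("OLS slope matches the hand-solved 3-point oracle", {
  f <- fit_linear_additive(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f$beta, 1.5, tolerance = 1e-12)
})

test_that("a noiseless line gives an exact fit with flagged zero se", {
  f <- fit_linear_additive(c(0, 1, 2, 1, 0), 2 * c(0, 1, 2, 1, 0))
  expect_equal(f$beta, 2, tolerance = 1e-12)
  expect_equal(f$se, 0)
  expect_equal(f$flag, "se_boundary")
})

test_that("closed-form OLS agrees with lm() on random data", {
  set.seed(101)
  for (i in 1:5) {
    g <- sample(0:2, 80, replace = TRUE)
    y <- 0.3 * g + rnorm(80)
    f <- fit_linear_additive(g, y)
    ref <- summary(lm(y ~ g))$coefficients
    expect_equal(f$beta, ref[2, 1], tolerance = 1e-10)
    expect_equal(f$se, ref[2, 2], tolerance = 1e-10)
  }
})

test_that("degenerate linear designs are rejected", {
  expect_error(fit_linear_additive(c(1, 1, 1, 1), rnorm(4)), "constant")
  expect_error(fit_linear_additive(c(0, 1), c(0, 1)), "insufficient")
})

test_that("saturated logistic fit equals the 2x2 contingency log-odds", {
  g <- rep(c(0, 1), times = c(100, 100))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80))
  f <- fit_logistic_additive(g, y)
  expect_equal(f$beta, log(2.25), tolerance = 1e-6)
})

test_that("logistic fit agrees with glm and a brute-force optimiser", {
  set.seed(202)
  g <- sample(0:2, 150, replace = TRUE)
  y <- rbinom(150, 1, plogis(-1 + 0.4 * g))
  f <- fit_logistic_additive(g, y)
  ref <- glm(y ~ g, family = binomial)
  expect_equal(f$beta, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(f$se, unname(summary(ref)$coefficients[2, 2]),
               tolerance = 1e-6)
  # independent route: direct likelihood maximisation
  nll <- function(par) -sum(dbinom(y, 1, plogis(par[1] + par[2] * g),
                                   log = TRUE))
  opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$beta, opt$par[2], tolerance = 1e-5)
})

test_that("allele-coding flips negate betas and preserve ses", {
  set.seed(303)
  g <- sample(0:2, 400, replace = TRUE)
  y <- rbinom(400, 1, plogis(-1 + 0.3 * g))
  f1 <- fit_logistic_additive(g, y)
  f2 <- fit_logistic_additive(2L - g, y)
  expect_equal(f1$beta, -f2$beta, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
  yc <- 0.2 * g + rnorm(400)
  l1 <- fit_linear_additive(g, yc)
  l2 <- fit_linear_additive(2L - g, yc)
  expect_equal(l1$beta, -l2$beta, tolerance = 1e-12)
  expect_equal(l1$se, l2$se, tolerance = 1e-12)
})

test_that("recode_to_ldl_lowering orients and validates dosages", {
  r <- recode_to_ldl_lowering(c(0L, 1L, 2L), beta_ldl = -0.1)
  expect_identical(r$dosages, c(0L, 1L, 2L))
  expect_false(r$flipped)
  r2 <- recode_to_ldl_lowering(c(0L, 1L, 2L), beta_ldl = 0.1)
  expect_identical(r2$dosages, c(2L, 1L, 0L))
  expect_true(r2$flipped)
  expect_equal(r2$beta_ldl, -0.1)
  expect_error(recode_to_ldl_lowering(c(0L, 3L), -0.1), "rejected")
})

test_that("available-case handling equals explicit row deletion", {
  set.seed(404)
  g <- sample(0:2, 120, replace = TRUE)
  y <- 0.2 * g + rnorm(120)
  y[sample(120, 15)] <- NA
  g[sample(120, 10)] <- NA
  keep <- !(is.na(g) | is.na(y))
  f_int <- fit_linear_additive(g, y)
  f_del <- fit_linear_additive(g[keep], y[keep])
  expect_identical(f_int, f_del)
})

test_that("HWE test matches hand-computed chi-squares", {
  exact <- hwe_test(c(25, 50, 25))
  expect_equal(exact$chi2, 0, tolerance = 1e-12)
  expect_equal(exact$p, 1)
  off <- hwe_test(c(30, 40, 30))
  expect_equal(off$chi2, 4, tolerance = 1e-12)
  expect_equal(off$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  mono <- hwe_test(c(50, 0, 0))
  expect_true(is.na(mono$p))
  expect_match(mono$reason, "monomorphic")
})

test_that("additivity LRT is non-negative and detects dominance", {
  set.seed(505)
  # additive data: valid chi-square behaviour, stat >= 0
  for (i in 1:5) {
    g <- sample(0:2, 300, replace = TRUE)
    y <- 0.2 * g + rnorm(300)
    l <- additivity_lrt(g, y, "gaussian")
    expect_gte(l$stat, 0)
    expect_equal(l$df, 1L)
  }
  # purely dominant effect: strong rejection at large n
  g <- sample(0:2, 20000, replace = TRUE)
  y <- 0.3 * (g >= 1) + rnorm(20000)
  expect_lt(additivity_lrt(g, y, "gaussian")$p, 1e-3)
  # binary family agrees with glm-based LRT
  yb <- rbinom(300, 1, plogis(-0.5 + 0.5 * (g[1:300] >= 1)))
  lb <- additivity_lrt(g[1:300], yb, "binomial")
  ref <- anova(glm(yb ~ g[1:300], family = binomial),
               glm(yb ~ factor(g[1:300]), family = binomial))
  expect_equal(lb$stat, ref$Deviance[2], tolerance = 1e-8)
})

test_that("LRT is skipped with a reason when a genotype class is absent", {
  l <- additivity_lrt(c(0, 0, 1, 1, 1, 0), rnorm(6), "gaussian")
  expect_true(is.na(l$p))
  expect_match(l$reason, "genotype class")
})

test_that("multivariable fit matches lm and flags exact collinearity", {
  set.seed(606)
  G <- cbind(a = sample(0:2, 200, TRUE), b = sample(0:2, 200, TRUE))
  y <- 0.2 * G[, 1] - 0.1 * G[, 2] + rnorm(200)
  m <- fit_multivariable(G, y, "gaussian")
  ref <- summary(lm(y ~ G))$coefficients
  expect_equal(m$beta, unname(ref[2:3, 1]), tolerance = 1e-10)
  expect_equal(m$se, unname(ref[2:3, 2]), tolerance = 1e-10)
  G2 <- cbind(G, c = G[, 1])
  expect_error(fit_multivariable(G2, y, "gaussian"), "collinear.*c")
})

test_that("orthogonal SNPs give matching univariable and multivariable betas", {
  set.seed(707)
  G <- cbind(a = sample(0:2, 5000, TRUE), b = sample(0:2, 5000, TRUE))
  y <- 0.15 * G[, 1] + 0.1 * G[, 2] + rnorm(5000)
  m <- fit_multivariable(G, y, "gaussian")
  for (j in 1:2) {
    u <- fit_linear_additive(G[, j], y)
    expect_lt(abs(u$beta - m$beta[j]), 3 * u$se)
  }
})

test_that("pairwise_r2 handles identity, independence, constant columns", {
  set.seed(808)
  G <- cbind(a = sample(0:2, 5000, TRUE), b = sample(0:2, 5000, TRUE),
             c = rep(1L, 5000))
  r2 <- pairwise_r2(G)
  expect_equal(r2["a", "a"], 1)
  expect_lt(r2["a", "b"], 0.01)
  expect_true(is.na(r2["a", "c"]))
})

test_that("sparse-cell binary fits are flagged and rare SNPs skipped cleanly", {
  cfg <- tiny_config(seed = 23, n_studies = 1, n = 2000)
  d <- simulate_cohort(cfg, 1)
  res <- associate_study(d, vapply(cfg$variants, `[[`, "", "snp_id"),
                         targetmr:::trait_info(cfg))
  est <- res$estimates
  # the rare variant (maf 0.01) cannot fill all diabetes cells at n=2000
  rare_t2d <- est[est$snp_id == "rs11591147" & est$trait == "t2d", ]
  if (nrow(rare_t2d)) expect_equal(rare_t2d$flag, "sparse_cells")
  # continuous fits are unflagged
  expect_true(all(est$flag[est$trait == "ldl"] == ""))
  # estimator consistency across studies is tested at acceptance level
  expect_true(all(c("estimates", "hwe", "lrt", "multivariable",
                    "skipped") %in% names(res)))
})
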