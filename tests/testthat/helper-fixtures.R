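# shared fixtures: small configurations used across test files

tiny_config <- function(seed = 42, n_studies = 2, n = 2000, ...) {
  sim_config(n_studies = n_studies, n_per_study = n, seed = seed, ...)
}

# single common variant, one continuous trait: the minimal mediation world
one_snp_config <- function(seed = 7, n = 5000, maf = 0.3, beta_ldl = -0.3,
                           theta = 0.09, noise_sd = 0.8,
                           ldl_noise_sd = 0.9) {
  sim_config(
    n_studies = 1, n_per_study = n,
    variants = list(variant_spec("snpA", maf = maf, beta_ldl = beta_ldl)),
    ld_r2 = matrix(1, 1, 1, dimnames = list("snpA", "snpA")),
    traits = list(glucose = trait_model("glucose", "continuous",
                                        theta = theta, baseline_mean = 5.38,
                                        noise_sd = noise_sd)),
    baseline_ldl_mean = 3.41, ldl_noise_sd = ldl_noise_sd,
    fasting_fraction = 1, seed = seed)
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("|%s - %s| <= %g", format(object),
                              format(expected), tol))
}
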