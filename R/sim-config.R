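#' Define a genetic variant used as an instrument
#'
#' A variant is identified by its id, minor allele frequency, and true
#' per-allele effect on LDL cholesterol. By convention the counted (minor)
#' allele is the LDL-lowering one, so `beta_ldl` is non-positive.
#'
#' @param snp_id character variant identifier.
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta_ldl per-allele LDL change, mmol/L (<= 0).
#' @return a `variant_spec` list.
#' @examples
#' variant_spec("rs11591147", maf = 0.01, beta_ldl = -0.34)
#' @export
variant_spec <- function(snp_id, maf, beta_ldl) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L)
  if (!is.finite(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]: ", snp_id)
  if (!is.finite(beta_ldl) || beta_ldl > 0)
    stop("beta_ldl must be <= 0 (minor allele coded as LDL-lowering): ",
         snp_id)
  structure(list(snp_id = snp_id, maf = maf, beta_ldl = beta_ldl),
            class = "variant_spec")
}

#' Default PCSK9 instrument panel
#'
#' Four approximately independent PCSK9 variants with the minor allele
#' frequencies 0.14, 0.01, 0.36 and 0.17. Per-allele LDL effects for the
#' first two variants are -0.02 and -0.34 mmol/L; the remaining two are
#' plausible mid-range values (-0.06 and -0.10 mmol/L) chosen for the
#' simulated world.
#'
#' @return list of [variant_spec()] objects.
#' @export
default_variants <- function() {
  list(
    variant_spec("rs11583680", maf = 0.14, beta_ldl = -0.02),
    variant_spec("rs11591147", maf = 0.01, beta_ldl = -0.34),
    variant_spec("rs2479409",  maf = 0.36, beta_ldl = -0.06),
    variant_spec("rs11206510", maf = 0.17, beta_ldl = -0.10)
  )
}

#' Define an outcome trait model
#'
#' `theta` is the causal effect of 1 mmol/L LOWER LDL cholesterol on the
#' trait (trait units for continuous traits, log-odds for binary), the
#' estimand the whole pipeline is built to recover.
#'
#' @param trait_name character name (column name in cohort files).
#' @param kind `"continuous"` or `"binary"`.
#' @param theta effect per 1 mmol/L lower LDL.
#' @param baseline_mean trait mean (continuous) or baseline log-odds (binary)
#'   at the reference LDL level.
#' @param noise_sd residual SD, trait units (continuous only, > 0).
#' @param fasting_only logical; analyse only fasting-flagged individuals.
#' @return a `trait_model` list.
#' @export
trait_model <- function(trait_name, kind = c("continuous", "binary"),
                        theta, baseline_mean, noise_sd = NULL,
                        fasting_only = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(trait_name), length(trait_name) == 1L)
  if (!is.finite(theta) || !is.finite(baseline_mean))
    stop("non-finite trait parameters for ", trait_name)
  if (kind == "continuous") {
    if (is.null(noise_sd) || !is.finite(noise_sd) || noise_sd <= 0)
      stop("continuous trait ", trait_name, " needs noise_sd > 0")
  } else {
    if (!is.null(noise_sd)) stop("binary trait ", trait_name,
                                 " must not carry noise_sd")
  }
  structure(list(trait_name = trait_name, kind = kind, theta = theta,
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 fasting_only = fasting_only),
            class = "trait_model")
}

#' Default trait panel calibrated to the PCSK9 study world
#'
#' True effects per 1 mmol/L lower LDL: fasting glucose +0.09 mmol/L,
#' HbA1c +0.03%, log fasting insulin 0, bodyweight +1.03 kg, height
#' +0.008 m, waist-to-hip ratio +0.006, and type 2 diabetes log-odds
#' ln(1.29). BMI is not a model of its own: it is computed from simulated
#' weight and height.
#'
#' @return named list of [trait_model()] objects.
#' @export
default_traits <- function() {
  tm <- list(
    trait_model("glucose", "continuous", theta = 0.09,
                baseline_mean = 5.38, noise_sd = 0.8, fasting_only = TRUE),
    trait_model("hba1c", "continuous", theta = 0.03,
                baseline_mean = 5.50, noise_sd = 0.55),
    trait_model("log_insulin", "continuous", theta = 0,
                baseline_mean = 4.0, noise_sd = 0.6, fasting_only = TRUE),
    trait_model("weight", "continuous", theta = 1.03,
                baseline_mean = 78, noise_sd = 15),
    trait_model("height", "continuous", theta = 0.008,
                baseline_mean = 1.70, noise_sd = 0.095),
    trait_model("whr", "continuous", theta = 0.006,
                baseline_mean = 0.87, noise_sd = 0.07),
    trait_model("t2d", "binary", theta = log(1.29), baseline_mean = -2.30)
  )
  names(tm) <- vapply(tm, `[[`, "", "trait_name")
  tm
}

#' Default target genotypic r-squared matrix
#'
#' One common-variant pair carries the maximum residual correlation
#' (r^2 = 0.26); all other pairs are independent, so every variant keeps a
#' genuine conditional LDL effect (the smallest-effect variant would
#' otherwise be conditionally null, contradicting the premise that LD
#' correction leaves estimates similar).
#'
#' @return 4 x 4 symmetric matrix named by the default panel's SNP ids.
#' @export
default_ld_r2 <- function() {
  ids <- vapply(default_variants(), `[[`, "", "snp_id")
  m <- diag(4)
  dimnames(m) <- list(ids, ids)
  m["rs2479409", "rs11206510"] <- m["rs11206510", "rs2479409"] <- 0.26
  m
}

#' Build a full simulation configuration
#'
#' The default configuration is the calibrated stated world: 20 studies of
#' 10 000 individuals, the four-variant PCSK9 panel, residual pairwise LD up
#' to r^2 = 0.26 (all below 0.30), marginal mean LDL 3.41 mmol/L, diabetes
#' prevalence about 9.1%, and outcome effects fully mediated through LDL.
#'
#' @param n_studies number of cohorts.
#' @param n_per_study integer vector of study sizes (recycled if scalar).
#' @param variants list of [variant_spec()].
#' @param ld_r2 symmetric target genotypic r-squared matrix (diagonal 1,
#'   off-diagonal < 0.30 in the default world).
#' @param traits named list of [trait_model()].
#' @param baseline_ldl_mean LDL mean at zero minor-allele dosage, mmol/L.
#'   The default (3.4699) is chosen so the marginal population mean under
#'   the default variant panel is 3.41 mmol/L after allele effects.
#' @param ldl_noise_sd individual-level LDL residual SD, mmol/L.
#' @param hwe_inbreeding named numeric map study id -> inbreeding
#'   coefficient F in `[0, 1)`; studies not named have F = 0.
#' @param prevalent_fraction fraction of diabetes cases flagged prevalent.
#' @param fasting_fraction fraction of individuals with fasting measures.
#' @param missing_rate MCAR missingness rate per analysis variable.
#' @param pleiotropy named numeric map trait -> direct per-allele genotype
#'   effect bypassing LDL (defaults to none; the MR identifying assumption).
#' @param seed integer seed expanded into per-study substreams.
#' @return a `sim_config` list.
#' @examples
#' cfg <- sim_config(n_studies = 2, n_per_study = 500, seed = 1)
#' @export
sim_config <- function(n_studies = 20,
                       n_per_study = 10000,
                       variants = default_variants(),
                       ld_r2 = NULL,
                       traits = default_traits(),
                       baseline_ldl_mean = 3.4699,
                       ldl_noise_sd = 0.9,
                       hwe_inbreeding = NULL,
                       prevalent_fraction = 0.5,
                       fasting_fraction = 0.7,
                       missing_rate = 0,
                       pleiotropy = NULL,
                       seed = 1L) {
  if (length(n_per_study) == 1L) n_per_study <- rep(n_per_study, n_studies)
  ids <- vapply(variants, `[[`, "", "snp_id")
  if (is.null(ld_r2)) {
    if (identical(ids, vapply(default_variants(), `[[`, "", "snp_id"))) {
      ld_r2 <- default_ld_r2()
    } else {
      ld_r2 <- diag(length(ids)); dimnames(ld_r2) <- list(ids, ids)
    }
  }
  cfg <- structure(list(
    n_studies = as.integer(n_studies),
    n_per_study = as.integer(n_per_study),
    variants = variants,
    ld_r2 = ld_r2,
    traits = traits,
    baseline_ldl_mean = baseline_ldl_mean,
    ldl_noise_sd = ldl_noise_sd,
    hwe_inbreeding = hwe_inbreeding %||% stats::setNames(numeric(0), character(0)),
    prevalent_fraction = prevalent_fraction,
    fasting_fraction = fasting_fraction,
    missing_rate = missing_rate,
    pleiotropy = pleiotropy %||% stats::setNames(numeric(0), character(0)),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every cross-field invariant (dimensions, LD matrix symmetry and
#' positive semi-definiteness of the implied latent correlation, parameter
#' ranges) and returns the config, or raises an aggregate error listing all
#' violations.
#'
#' @param cfg a `sim_config`.
#' @return the validated config, invisibly classed as before.
#' @export
validate_sim_config <- function(cfg) {
  errs <- character(0)
  p <- length(cfg$variants)
  if (length(cfg$n_per_study) != cfg$n_studies)
    errs <- c(errs, "length(n_per_study) must equal n_studies")
  if (any(cfg$n_per_study < 1))
    errs <- c(errs, "n_per_study entries must be >= 1")
  if (!is.matrix(cfg$ld_r2) || !all(dim(cfg$ld_r2) == p))
    errs <- c(errs, "ld_r2 must be a p x p matrix matching variants")
  else {
    if (any(abs(cfg$ld_r2 - t(cfg$ld_r2)) > 1e-12))
      errs <- c(errs, "ld_r2 must be symmetric")
    if (any(abs(diag(cfg$ld_r2) - 1) > 1e-12))
      errs <- c(errs, "ld_r2 diagonal must be 1")
    off <- cfg$ld_r2[upper.tri(cfg$ld_r2)]
    if (any(off < 0 | off >= 1))
      errs <- c(errs, "off-diagonal ld_r2 must lie in [0, 1)")
  }
  if (!is.finite(cfg$baseline_ldl_mean))
    errs <- c(errs, "baseline_ldl_mean must be finite")
  if (!is.finite(cfg$ldl_noise_sd) || cfg$ldl_noise_sd <= 0)
    errs <- c(errs, "ldl_noise_sd must be > 0")
  if (cfg$prevalent_fraction < 0 || cfg$prevalent_fraction > 1)
    errs <- c(errs, "prevalent_fraction must lie in [0, 1]")
  if (cfg$fasting_fraction < 0 || cfg$fasting_fraction > 1)
    errs <- c(errs, "fasting_fraction must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    errs <- c(errs, "missing_rate must lie in [0, 1)")
  if (length(cfg$hwe_inbreeding) &&
      (any(cfg$hwe_inbreeding < 0) || any(cfg$hwe_inbreeding >= 1)))
    errs <- c(errs, "hwe_inbreeding values must lie in [0, 1)")
  if (length(errs)) stop("invalid sim_config:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' Serialise / restore a simulation configuration
#'
#' JSON is the native format; YAML is read when the optional `yaml` package
#' is installed. Field names match the configuration constructor exactly.
#'
#' @param cfg a `sim_config`.
#' @param path file path (`.json`, `.yaml`, or `.yml`).
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  # named numeric vectors must become objects, not arrays, in JSON/YAML
  x$hwe_inbreeding <- as.list(x$hwe_inbreeding)
  x$pleiotropy <- as.list(x$pleiotropy)
  x$variants <- lapply(x$variants, unclass)
  x$traits <- lapply(unname(x$traits), unclass)
  x$ld_r2 <- list(snp_ids = colnames(cfg$ld_r2) %||%
                    vapply(cfg$variants, `[[`, "", "snp_id"),
                  values = as.vector(cfg$ld_r2))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not installed; use JSON")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not installed; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  variants <- lapply(x$variants, function(v)
    variant_spec(v$snp_id, v$maf, v$beta_ldl))
  traits <- lapply(x$traits, function(tr)
    trait_model(tr$trait_name, tr$kind, tr$theta, tr$baseline_mean,
                tr$noise_sd, isTRUE(tr$fasting_only)))
  names(traits) <- vapply(traits, `[[`, "", "trait_name")
  ids <- unlist(x$ld_r2$snp_ids)
  m <- matrix(unlist(x$ld_r2$values), length(ids), length(ids),
              dimnames = list(ids, ids))
  sim_config(n_studies = x$n_studies, n_per_study = unlist(x$n_per_study),
             variants = variants, ld_r2 = m, traits = traits,
             baseline_ldl_mean = x$baseline_ldl_mean,
             ldl_noise_sd = x$ldl_noise_sd,
             hwe_inbreeding = unlist(x$hwe_inbreeding) %||% NULL,
             prevalent_fraction = x$prevalent_fraction,
             fasting_fraction = x$fasting_fraction,
             missing_rate = x$missing_rate,
             pleiotropy = unlist(x$pleiotropy) %||% NULL,
             seed = x$seed)
}
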