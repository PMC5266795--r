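#' Structural LDL coefficients reproducing target marginal effects
#'
#' Each variant's `beta_ldl` is the target MARGINAL (univariable) per-allele
#' LDL effect -- the quantity per-SNP regressions estimate and forest tables
#' print. Under residual LD a marginal effect absorbs contamination from
#' correlated causal variants, so the structural coefficients entering the
#' LDL-generating equation are solved from the dosage covariance implied by
#' the configuration: `beta_struct = C^{-1} (v * m)` with `C` the dosage
#' covariance (at F = 0), `v` the dosage variances and `m` the marginal
#' targets. With no LD the two coincide.
#'
#' @param config a [sim_config()].
#' @return numeric vector of structural per-allele coefficients.
#' @export
structural_betas <- function(config) {
  m <- vapply(config$variants, `[[`, 0, "beta_ldl")
  mafs <- vapply(config$variants, `[[`, 0, "maf")
  v <- 2 * mafs * (1 - mafs)
  r <- sqrt(config$ld_r2)
  C <- r * tcrossprod(sqrt(v))
  b <- solve(C, v * m)
  stats::setNames(b, vapply(config$variants, `[[`, "", "snp_id"))
}

#' Simulate one cohort study
#'
#' Generates an individual-level dataset under the fully LDL-mediated causal
#' model: per-individual LDL is baseline plus additive allele effects plus
#' Gaussian noise; every downstream trait responds only to the realised LDL
#' deficit (`baseline_ldl_mean - LDL`), so the per-1-mmol/L-lower-LDL effect
#' `theta` is the recoverable estimand. Diabetes is a Bernoulli draw from a
#' logistic liability; cases are flagged incident or prevalent.
#'
#' @param config a [sim_config()].
#' @param study_index 1-based study number (`<= n_studies`).
#' @return data frame with columns `iid`, one dosage column per SNP, `ldl`,
#'   each configured trait (plus `bmi` when weight and height are present),
#'   `t2d`, `case_type` (`"incident"`, `"prevalent"`, `"none"`) and
#'   `fasting`; `study_id` is carried as an attribute column `study_id`.
#' @examples
#' d <- simulate_cohort(sim_config(n_studies = 1, n_per_study = 200, seed = 7), 1)
#' @export
simulate_cohort <- function(config, study_index) {
  validate_sim_config(config)
  stopifnot(study_index >= 1, study_index <= config$n_studies)
  n <- config$n_per_study[study_index]
  study_id <- sprintf("S%02d", study_index)
  Fco <- config$hwe_inbreeding[study_id]
  if (is.na(Fco) || is.null(Fco)) Fco <- 0
  set.seed(substream_seed(config$seed, "cohort", study_index))

  G <- sample_genotypes(config$variants, config$ld_r2, n, inbreeding_F = Fco)
  beta <- structural_betas(config)
  ldl <- config$baseline_ldl_mean + drop(G %*% beta) +
    stats::rnorm(n, 0, config$ldl_noise_sd)
  deficit <- config$baseline_ldl_mean - ldl  # mmol/L LOWER than baseline

  out <- data.frame(study_id = study_id,
                    iid = sprintf("%s_%05d", study_id, seq_len(n)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(G))
  out$ldl <- ldl

  pleio <- config$pleiotropy
  for (tm in config$traits) {
    direct <- if (tm$trait_name %in% names(pleio))
      pleio[[tm$trait_name]] * rowSums(G) else 0
    if (tm$kind == "continuous") {
      out[[tm$trait_name]] <- tm$baseline_mean + tm$theta * deficit +
        direct + stats::rnorm(n, 0, tm$noise_sd)
    } else {
      pr <- stats::plogis(tm$baseline_mean + tm$theta * deficit + direct)
      out[[tm$trait_name]] <- stats::rbinom(n, 1L, pr)
    }
  }
  if (all(c("weight", "height") %in% names(out)))
    out$bmi <- out$weight / out$height^2

  if ("t2d" %in% names(out)) {
    out$case_type <- "none"
    cases <- which(out$t2d == 1L)
    prev <- cases[stats::runif(length(cases)) < config$prevalent_fraction]
    out$case_type[cases] <- "incident"
    out$case_type[prev] <- "prevalent"
  }
  out$fasting <- as.integer(stats::runif(n) < config$fasting_fraction)

  if (config$missing_rate > 0) {
    meas <- setdiff(names(out), c("study_id", "iid", "t2d", "case_type",
                                  "fasting",
                                  vapply(config$variants, `[[`, "", "snp_id")))
    for (v in meas)
      out[[v]][stats::runif(n) < config$missing_rate] <- NA
  }
  out
}

#' Simulate every cohort in a configuration
#'
#' @param config a [sim_config()].
#' @return named list of cohort data frames (one per study). Each study's
#'   draws come from its own seed substream, so results do not depend on
#'   generation order.
#' @export
simulate_cohorts <- function(config) {
  out <- lapply(seq_len(config$n_studies), function(i)
    simulate_cohort(config, i))
  names(out) <- vapply(out, function(d) d$study_id[1], "")
  out
}

#' Emit consortium-style summary statistics
#'
#' Rather than simulating millions of individuals, consortium records are
#' drawn directly from the sampling distribution of the per-allele
#' regression estimator: `beta ~ Normal(true effect, se^2)` with
#' `se^2 = sigma_resid^2 / (2 maf (1-maf) n_effective)` for continuous
#' traits, and the analogous logistic large-sample approximation
#' `se^2 = 1 / (2 maf (1-maf) n_effective p0 (1-p0))` (baseline prevalence
#' `p0`) for binary traits.
#'
#' @param config a [sim_config()].
#' @param source_id consortium label (e.g. `"GLGC"`).
#' @param n_effective effective sample size behind each record.
#' @param traits character vector of trait names to emit (default: LDL plus
#'   all configured traits).
#' @return data frame with columns `source_id`, `snp_id`, `trait`,
#'   `effect_allele`, `beta`, `se`, `n`.
#' @export
emit_consortium_summary <- function(config, source_id, n_effective,
                                    traits = NULL) {
  validate_sim_config(config)
  stopifnot(n_effective > 0)
  set.seed(substream_seed(config$seed, "consortium",
                          index = sum(utf8ToInt(source_id))))
  traits <- traits %||% c("ldl", names(config$traits))
  rows <- list()
  for (tr in traits) {
    for (v in config$variants) {
      if (tr == "ldl") {
        true_beta <- v$beta_ldl
        sigma2 <- config$ldl_noise_sd^2
        se <- sqrt(sigma2 / (2 * v$maf * (1 - v$maf) * n_effective))
      } else {
        tm <- config$traits[[tr]]
        true_beta <- tm$theta * abs(v$beta_ldl)
        if (tm$kind == "continuous") {
          se <- sqrt(tm$noise_sd^2 /
                       (2 * v$maf * (1 - v$maf) * n_effective))
        } else {
          p0 <- stats::plogis(tm$baseline_mean)
          se <- sqrt(1 / (2 * v$maf * (1 - v$maf) * n_effective *
                            p0 * (1 - p0)))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = source_id, snp_id = v$snp_id, trait = tr,
        effect_allele = "minor", beta = stats::rnorm(1, true_beta, se),
        se = se, n = n_effective, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write / read cohort files
#'
#' Cohorts are interchanged as one TSV per study with the fixed column
#' order: `iid`, one integer dosage column per SNP, `ldl`, `glucose`,
#' `hba1c`, `log_insulin`, `weight`, `height`, `bmi`, `whr`, `t2d`,
#' `case_type`, `fasting` (columns for unconfigured traits are simply
#' absent).
#'
#' @param cohort cohort data frame from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the written path (`write_cohort_tsv`) or a cohort data frame
#'   (`read_cohort_tsv`).
#' @export
write_cohort_tsv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(cohort$study_id[1], ".tsv"))
  write_tsv_table(cohort[setdiff(names(cohort), "study_id")], path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @param path a study TSV path.
#' @export
read_cohort_tsv <- function(path) {
  d <- read_tsv_table(path)
  d <- cbind(study_id = sub("\\.tsv$", "", basename(path)), d,
             stringsAsFactors = FALSE)
  d
}
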