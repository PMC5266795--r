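# Per-study association estimation: the computation each cohort runs under
# the common analysis plan. All models are crude (unadjusted) additive
# per-allele regressions; rows with missing outcome or dosage are dropped
# (available-case analysis, assuming MCAR).

#' Orient dosages to count the LDL-lowering allele
#'
#' All analyses count the LDL-lowering allele, so per-allele LDL effects are
#' negative by convention. If the supplied orientation has a positive LDL
#' effect, dosages are flipped (`g -> 2 - g`) and the effect sign convention
#' reversed.
#'
#' @param dosages integer vector with values in \{0, 1, 2\}.
#' @param beta_ldl per-allele LDL effect under the supplied orientation.
#' @return list with `dosages` (oriented), `beta_ldl` (sign-consistent,
#'   `<= 0`) and `flipped` (logical).
#' @export
recode_to_ldl_lowering <- function(dosages, beta_ldl) {
  ok <- is.na(dosages) | dosages %in% c(0L, 1L, 2L)
  if (!all(ok))
    stop("dosages outside {0,1,2}: rejected ", sum(!ok), " record(s)")
  if (beta_ldl > 0) {
    list(dosages = 2L - dosages, beta_ldl = -beta_ldl, flipped = TRUE)
  } else {
    list(dosages = dosages, beta_ldl = beta_ldl, flipped = FALSE)
  }
}

#' Additive linear model for a continuous trait
#'
#' Ordinary least squares of the trait on minor-allele dosage with an
#' intercept, solved from the closed-form normal equations.
#'
#' @param g dosage vector (0/1/2, NAs dropped pairwise with `y`).
#' @param y continuous outcome.
#' @return list with `beta`, `se`, `n`, and `flag` (`"se_boundary"` when the
#'   fit is exact and the standard error degenerates to 0).
#' @examples
#' fit_linear_additive(c(0, 1, 2), c(0, 1, 3))$beta  # 1.5
#' @export
fit_linear_additive <- function(g, y) {
  keep <- !(is.na(g) | is.na(y))
  g <- as.numeric(g[keep]); y <- y[keep]
  n <- length(g)
  if (n < 3) stop("insufficient data: ", n, " complete observations (< 3)")
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) stop("degenerate design: dosage constant")
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (g - mean(g)))^2)
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  list(beta = beta, se = se, n = n,
       flag = if (se == 0) "se_boundary" else "")
}

#' Additive logistic model for a binary trait
#'
#' Maximum-likelihood log-odds per allele via iteratively reweighted least
#' squares, with an explicit complete-separation guard (diverging
#' `|beta| > 15`). The standard error comes from the inverse observed
#' information.
#'
#' @param g dosage vector (0/1/2).
#' @param y 0/1 case indicator.
#' @return list with `beta`, `se`, `n`, `flag`.
#' @export
fit_logistic_additive <- function(g, y) {
  keep <- !(is.na(g) | is.na(y))
  g <- as.numeric(g[keep]); y <- y[keep]
  n <- length(g)
  if (length(unique(y)) < 2) stop("only one outcome class present")
  if (stats::var(g) == 0) stop("degenerate design: dosage constant")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, g), y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 50L)))
  beta <- fit$coefficients[2]
  if (!fit$converged)
    stop("IRLS did not converge in 50 iterations (last beta ",
         format(beta), ")")
  if (abs(beta) > 15)
    stop("complete separation detected (|beta| = ", format(abs(beta)), ")")
  # observed information from the final IRLS weights
  X <- cbind(1, g)
  info <- crossprod(X * sqrt(fit$weights))
  se <- sqrt(solve(info)[2, 2])
  list(beta = unname(beta), se = unname(se), n = n, flag = "")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' the Hardy-Weinberg expectations computed from the sample allele
#' frequency.
#'
#' @param counts integer vector `(n0, n1, n2)` of dosage counts.
#' @return list with `counts`, `chi2`, `p`, and `reason` (non-empty when the
#'   test is skipped for a monomorphic SNP).
#' @examples
#' hwe_test(c(30, 40, 30))$chi2  # 4
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(counts = counts, chi2 = NA_real_, p = NA_real_,
                reason = "monomorphic: expected count zero"))
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - e)^2 / e)
  list(counts = counts, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), reason = "")
}

#' Likelihood-ratio test of additivity
#'
#' Compares the additive (dosage-as-number) model to a genotypic
#' (dosage-as-factor) model allowing dominance or recessiveness;
#' `stat = 2 (loglik_genotypic - loglik_additive)` on 1 df.
#'
#' @param g dosage vector.
#' @param y outcome.
#' @param family `"gaussian"` or `"binomial"`.
#' @return list with `stat`, `df`, `p`, `reason` (non-empty when a genotype
#'   class has fewer than 2 observations and the test is skipped).
#' @export
additivity_lrt <- function(g, y, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  keep <- !(is.na(g) | is.na(y))
  g <- as.numeric(g[keep]); y <- y[keep]
  tab <- table(factor(g, levels = 0:2))
  if (any(tab < 2))
    return(list(stat = NA_real_, df = 1L, p = NA_real_,
                reason = paste0("genotype class(es) ",
                                paste(names(tab)[tab < 2], collapse = ","),
                                " with < 2 observations")))
  if (family == "gaussian") {
    rss_add <- sum(stats::lm.fit(cbind(1, g), y)$residuals^2)
    rss_gen <- sum(stats::lm.fit(stats::model.matrix(~ factor(g)),
                                 y)$residuals^2)
    stat <- length(y) * log(rss_add / rss_gen)
  } else {
    dev_add <- suppressWarnings(
      stats::glm.fit(cbind(1, g), y, family = stats::binomial()))$deviance
    dev_gen <- suppressWarnings(
      stats::glm.fit(stats::model.matrix(~ factor(g)), y,
                     family = stats::binomial()))$deviance
    stat <- dev_add - dev_gen
  }
  if (stat < -1e-8) stop("genotypic model fit worse than additive")
  stat <- max(stat, 0)
  list(stat = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE), reason = "")
}

#' Multivariable (mutually adjusted) per-allele model
#'
#' Fits all SNPs in one model, yielding conditional per-allele estimates
#' that correct for residual linkage disequilibrium.
#'
#' @param G dosage matrix (one column per SNP).
#' @param y outcome.
#' @param family `"gaussian"` or `"binomial"`.
#' @return data frame with one row per SNP: `snp_id`, `beta`, `se`, `n`.
#' @export
fit_multivariable <- function(G, y, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  keep <- stats::complete.cases(G, y)
  G <- as.matrix(G[keep, , drop = FALSE]); y <- y[keep]
  X <- cbind(`(Intercept)` = 1, G)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    V <- chol2inv(qr.R(qx)) * rss / (length(y) - ncol(X))
    beta <- fit$coefficients
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = list(epsilon = 1e-10, maxit = 50L)))
    if (!fit$converged) stop("IRLS did not converge (multivariable)")
    V <- solve(crossprod(X * sqrt(fit$weights)))
    beta <- fit$coefficients
  }
  data.frame(snp_id = colnames(G), beta = unname(beta[-1]),
             se = sqrt(diag(V))[-1], n = length(y),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise genotypic r-squared
#'
#' Squared Pearson correlation of dosage columns (composite genotypic LD).
#' Constant columns yield `NA` entries (undefined, not zero).
#'
#' @param G dosage matrix.
#' @return symmetric matrix of r-squared values.
#' @export
pairwise_r2 <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  v <- apply(G, 2, stats::var)
  r2 <- suppressWarnings(stats::cor(G)^2)
  r2[v == 0, ] <- NA_real_
  r2[, v == 0] <- NA_real_
  diag(r2)[v > 0] <- 1
  r2
}

# trait metadata table used to route fits; BMI is a derived column
# (weight/height^2) analysed like any other continuous trait
trait_info <- function(config) {
  ti <- data.frame(
    trait = c("ldl", names(config$traits)),
    kind = c("continuous",
             vapply(config$traits, `[[`, "", "kind")),
    fasting_only = c(FALSE,
                     vapply(config$traits, function(t)
                       isTRUE(t$fasting_only), TRUE)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (all(c("weight", "height") %in% ti$trait))
    ti <- rbind(ti, data.frame(trait = "bmi", kind = "continuous",
                               fasting_only = FALSE))
  ti
}

#' Run the full per-study analysis script
#'
#' For one cohort: HWE tests per SNP, univariable additive fits for every
#' (SNP, trait) including LDL and the incident/prevalent diabetes strata,
#' additivity likelihood-ratio tests, and the multivariable
#' (LD-correcting) model per trait. Binary fits with any genotype-by-
#' outcome cell below `min_cell` are flagged `sparse_cells` (excluded from
#' pooling downstream by default). Fasting-only traits use fasting-flagged
#' individuals.
#'
#' @param cohort cohort data frame (see [simulate_cohort()]).
#' @param snp_ids SNP column names.
#' @param traits trait metadata data frame (`trait`, `kind`,
#'   `fasting_only`), e.g. from a `sim_config`.
#' @param min_cell sparse-cell threshold for binary fits.
#' @param strata also fit incident- and prevalent-restricted diabetes
#'   models (requires a `case_type` column).
#' @return list of data frames: `estimates`, `hwe`, `lrt`,
#'   `multivariable`, `skipped`.
#' @export
associate_study <- function(cohort, snp_ids, traits, min_cell = 5,
                            strata = TRUE) {
  study_id <- cohort$study_id[1]
  est <- list(); lrt <- list(); multi <- list(); skipped <- list()

  hwe <- do.call(rbind, lapply(snp_ids, function(s) {
    counts <- as.integer(table(factor(cohort[[s]], levels = 0:2)))
    h <- hwe_test(counts)
    data.frame(study_id = study_id, snp_id = s,
               n0 = counts[1], n1 = counts[2], n2 = counts[3],
               chi2 = h$chi2, p = h$p, reason = h$reason,
               stringsAsFactors = FALSE)
  }))

  outcome_sets <- lapply(seq_len(nrow(traits)), function(i) {
    tr <- traits$trait[i]
    rows <- if (traits$fasting_only[i] && "fasting" %in% names(cohort))
      cohort$fasting == 1L else rep(TRUE, nrow(cohort))
    list(trait = tr, kind = traits$kind[i], rows = rows, y = cohort[[tr]])
  })
  if (strata && "t2d" %in% traits$trait && "case_type" %in% names(cohort)) {
    for (st in c("incident", "prevalent")) {
      keep <- cohort$case_type %in% c("none", st)
      outcome_sets[[length(outcome_sets) + 1L]] <-
        list(trait = paste0("t2d_", st), kind = "binary",
             rows = keep, y = cohort$t2d)
    }
  }

  for (os in outcome_sets) {
    y_all <- os$y[os$rows]
    for (s in snp_ids) {
      g <- cohort[[s]][os$rows]
      res <- tryCatch({
        if (os$kind == "continuous") {
          f <- fit_linear_additive(g, y_all)
        } else {
          f <- fit_logistic_additive(g, y_all)
          cells <- table(factor(g, levels = 0:2), factor(y_all, levels = 0:1))
          present <- rowSums(cells) > 0
          if (any(cells[present, ] < min_cell)) f$flag <- "sparse_cells"
        }
        data.frame(study_id = study_id, snp_id = s, trait = os$trait,
                   beta = f$beta, se = f$se, n = f$n, model = "additive",
                   scale = "per-allele", flag = f$flag,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          study_id = study_id, snp_id = s, trait = os$trait,
          reason = conditionMessage(e), stringsAsFactors = FALSE)
        NULL
      })
      if (!is.null(res)) est[[length(est) + 1L]] <- res
      if (!startsWith(os$trait, "t2d_")) {
        l <- additivity_lrt(g, y_all,
                            if (os$kind == "continuous") "gaussian"
                            else "binomial")
        lrt[[length(lrt) + 1L]] <- data.frame(
          study_id = study_id, snp_id = s, trait = os$trait,
          stat = l$stat, df = l$df, p = l$p, reason = l$reason,
          stringsAsFactors = FALSE)
      }
    }
    if (!startsWith(os$trait, "t2d_")) {
      m <- tryCatch(
        fit_multivariable(cohort[os$rows, snp_ids, drop = FALSE], y_all,
                          if (os$kind == "continuous") "gaussian"
                          else "binomial"),
        error = function(e) NULL)
      if (!is.null(m)) {
        m$study_id <- study_id; m$trait <- os$trait
        m$model <- "multivariable"; m$scale <- "per-allele"; m$flag <- ""
        multi[[length(multi) + 1L]] <-
          m[c("study_id", "snp_id", "trait", "beta", "se", "n",
              "model", "scale", "flag")]
      }
    }
  }

  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(
    estimates = bind(est, data.frame()),
    hwe = hwe,
    lrt = bind(lrt, data.frame()),
    multivariable = bind(multi, data.frame()),
    skipped = bind(skipped, data.frame())
  )
}

#' Run the analysis script over every cohort
#'
#' @param cohorts named list of cohort data frames.
#' @param config the [sim_config()] that describes SNPs and traits (used
#'   only for metadata; the data come from `cohorts`).
#' @param min_cell,strata passed to [associate_study()].
#' @return list of row-bound data frames across studies, same components as
#'   [associate_study()].
#' @export
associate_cohorts <- function(cohorts, config, min_cell = 5, strata = TRUE) {
  snp_ids <- vapply(config$variants, `[[`, "", "snp_id")
  traits <- trait_info(config)
  per <- lapply(cohorts, associate_study, snp_ids = snp_ids,
                traits = traits, min_cell = min_cell, strata = strata)
  comp <- c("estimates", "hwe", "lrt", "multivariable", "skipped")
  out <- lapply(comp, function(k)
    do.call(rbind, c(lapply(per, `[[`, k), list(make.row.names = FALSE))))
  names(out) <- comp
  out
}
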