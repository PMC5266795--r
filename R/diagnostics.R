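# Cross-cutting sensitivity checks: dose-response proportionality between
# per-allele LDL effects and diabetes log-odds, leave-one-SNP-out score
# stability, additivity summaries, LD-correction comparison, and the
# incident/prevalent case-definition split.

#' Weighted dose-response relation between LDL and diabetes effects
#'
#' Inverse-variance-weighted Pearson correlation and weighted-least-squares
#' regression of per-allele diabetes log-odds on per-allele LDL effects,
#' with weights `1/var(logOR)`, plus a leave-one-SNP-out recomputation of
#' the correlation. The slope p-value uses normal theory with `k - 2` error
#' degrees of freedom.
#'
#' @param ldl_betas per-allele LDL effects (mmol/L).
#' @param t2d_logors per-allele diabetes log-odds.
#' @param t2d_vars variances of the log-odds (> 0).
#' @param snp_ids optional labels for the leave-one-out entries.
#' @return list with `r_weighted`, `slope`, `intercept`, `slope_ci`,
#'   `p_slope`, `weights`, and `loo` (named vector of correlations, one per
#'   left-out SNP; `NA` with fewer than 3 remaining points).
#' @export
weighted_dose_response <- function(ldl_betas, t2d_logors, t2d_vars,
                                   snp_ids = NULL) {
  k <- length(ldl_betas)
  stopifnot(length(t2d_logors) == k, length(t2d_vars) == k,
            all(t2d_vars > 0))
  if (k < 3) stop("need at least 3 SNPs for a defined correlation")
  snp_ids <- snp_ids %||% paste0("snp", seq_len(k))
  w <- 1 / t2d_vars

  core <- function(x, y, w) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
    cxy <- sum(w * (x - mx) * (y - my))
    list(r = cxy / sqrt(cxx * cyy), slope = cxy / cxx,
         intercept = my - (cxy / cxx) * mx, sxx_w = cxx)
  }
  fit <- core(ldl_betas, t2d_logors, w)
  # WLS slope se: sigma2_hat = sum(w e^2)/(k-2); invariant to rescaling w
  res <- t2d_logors - fit$intercept - fit$slope * ldl_betas
  s2 <- sum(w * res^2) / (k - 2)
  se_slope <- sqrt(s2 / fit$sxx_w)
  tq <- stats::qt(0.975, df = k - 2)
  p_slope <- 2 * stats::pt(abs(fit$slope / se_slope), df = k - 2,
                           lower.tail = FALSE)
  loo <- vapply(seq_len(k), function(i) {
    if (k - 1 < 3) return(NA_real_)
    core(ldl_betas[-i], t2d_logors[-i], w[-i])$r
  }, 0)
  names(loo) <- snp_ids
  list(r_weighted = fit$r, slope = fit$slope, intercept = fit$intercept,
       slope_ci = c(fit$slope - tq * se_slope, fit$slope + tq * se_slope),
       p_slope = p_slope, weights = w, loo = loo)
}

#' Leave-one-SNP-out gene-centric score
#'
#' Recomputes the score k times, each omitting one SNP, to show whether any
#' single variant (in particular the large-LDL-effect one) drives the
#' combined estimate.
#'
#' @param scaled per-mmol scaled estimates (`snp_id`, `beta`, `se`).
#' @param trait trait label.
#' @param binary odds-ratio reporting.
#' @return data frame with one fixed-effect row per omitted SNP
#'   (`omitted`, `beta`, `se`, `ci_low`, `ci_high`, `k`, and `or` columns
#'   for binary traits).
#' @export
leave_one_out_gs <- function(scaled, trait = NA_character_,
                             binary = FALSE) {
  stopifnot(nrow(scaled) >= 2)
  do.call(rbind, lapply(seq_len(nrow(scaled)), function(i) {
    gs <- gene_score(scaled[-i, , drop = FALSE], trait = trait,
                     binary = binary)
    gs <- gs[gs$method == "fixed", ]
    cbind(data.frame(omitted = scaled$snp_id[i], stringsAsFactors = FALSE),
          gs[setdiff(names(gs), c("snp_id", "method"))])
  }))
}

#' Per-SNP additivity summary across studies
#'
#' Fisher-combines the per-study additivity likelihood-ratio p-values for
#' each (SNP, trait).
#'
#' @param lrt_results LRT table from [associate_cohorts()] (`study_id`,
#'   `snp_id`, `trait`, `p`; skipped tests have `NA` p).
#' @return data frame with `snp_id`, `trait`, `k_studies`, `X`, `df`, `p`.
#' @export
additivity_summary <- function(lrt_results) {
  keys <- unique(lrt_results[c("snp_id", "trait")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- lrt_results$snp_id == keys$snp_id[i] &
      lrt_results$trait == keys$trait[i] & !is.na(lrt_results$p)
    p <- lrt_results$p[sel]
    if (!length(p))
      return(data.frame(snp_id = keys$snp_id[i], trait = keys$trait[i],
                        k_studies = 0L, X = NA_real_, df = NA_integer_,
                        p = NA_real_, stringsAsFactors = FALSE))
    fc <- fisher_combine(p)
    data.frame(snp_id = keys$snp_id[i], trait = keys$trait[i],
               k_studies = length(p), X = fc$X, df = fc$df, p = fc$p,
               stringsAsFactors = FALSE)
  }))
}

#' Incident / prevalent diabetes stratification
#'
#' Reruns pooling, Wald scaling and the gene-centric score with cases
#' restricted to one stratum (all non-cases retained as the comparison
#' group; the per-study stratified fits are produced by
#' [associate_study()] as traits `t2d_incident` / `t2d_prevalent`).
#'
#' @param pooled pooled per-allele table containing `t2d_incident` and/or
#'   `t2d_prevalent` rows alongside `ldl` rows.
#' @param stratum `"incident"` or `"prevalent"`.
#' @param weak_floor weak-instrument floor.
#' @return list as from [run_trait_analysis()], or `NULL` (with a message)
#'   when the stratum has no pooled estimates.
#' @export
stratified_t2d <- function(pooled, stratum = c("incident", "prevalent"),
                           weak_floor = 0.005) {
  stratum <- match.arg(stratum)
  tr <- paste0("t2d_", stratum)
  if (!any(pooled$trait == tr)) {
    message("no pooled estimates for stratum ", stratum, "; skipped")
    return(NULL)
  }
  run_trait_analysis(pooled, tr, binary = TRUE, weak_floor = weak_floor)
}

#' Linkage-disequilibrium correction report
#'
#' Compares pairwise (univariable) and multivariable (mutually adjusted)
#' analyses of the same individual-level data on the causal
#' per-1-mmol/L-lower-LDL scale: each route's outcome estimate is Wald-
#' scaled by that route's own LDL estimate. On the per-allele scale,
#' marginal and conditional coefficients differ mechanically whenever
#' residual LD and several causal variants coexist; under the mediation
#' model that contamination cancels in the Wald ratio, so similarity on
#' the causal scale is the meaningful invariance check.
#'
#' @param uni_pooled pooled univariable table (fixed-effect rows used;
#'   must include `ldl` rows).
#' @param multi_estimates per-study multivariable estimates (from
#'   [associate_cohorts()]; must include `ldl` rows).
#' @param weak_floor weak-instrument floor for both scalings.
#' @return data frame with `snp_id`, `trait`, `beta_uni`, `se_uni`,
#'   `beta_multi`, `se_multi`, `delta`, `delta_per_se` (per-mmol scale).
#' @export
ld_correction_report <- function(uni_pooled, multi_estimates,
                                 weak_floor = 0.005) {
  uni <- uni_pooled[uni_pooled$method == "fixed", ]
  pool_multi <- function(snp, trait) {
    sel <- multi_estimates$snp_id == snp & multi_estimates$trait == trait
    if (!any(sel)) return(NULL)
    ivw_fixed(multi_estimates$beta[sel], multi_estimates$se[sel])
  }
  mk <- unique(multi_estimates[multi_estimates$trait != "ldl",
                               c("snp_id", "trait")])
  out <- lapply(seq_len(nrow(mk)), function(i) {
    snp <- mk$snp_id[i]; tr <- mk$trait[i]
    u <- uni[uni$snp_id == snp & uni$trait == tr, ]
    u_ldl <- uni[uni$snp_id == snp & uni$trait == "ldl", ]
    m <- pool_multi(snp, tr); m_ldl <- pool_multi(snp, "ldl")
    # combinations vanish from a route when quality filters removed every
    # contributing study, or when an LDL denominator is too weak to scale
    if (!nrow(u) || !nrow(u_ldl) || is.null(m) || is.null(m_ldl))
      return(NULL)
    if (abs(u_ldl$beta) < weak_floor || abs(m_ldl$beta) < weak_floor)
      return(NULL)
    us <- wald_scale(u$beta, u$se, u_ldl$beta, weak_floor, snp)
    ms <- wald_scale(m$beta, m$se, m_ldl$beta, weak_floor, snp)
    data.frame(snp_id = snp, trait = tr,
               beta_uni = us$beta, se_uni = us$se,
               beta_multi = ms$beta, se_multi = ms$se,
               delta = ms$beta - us$beta,
               delta_per_se = (ms$beta - us$beta) / us$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
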