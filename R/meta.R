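# Inverse-variance-weighted meta-analysis with heterogeneity statistics.
# These closed forms are the level-1 (across studies) and level-2 (across
# SNPs, for the gene score) pooling machinery.

#' Fixed-effect inverse-variance-weighted pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled `beta = sum(w b) / sum(w)`,
#' `se = sqrt(1/sum(w))`, 95% CI `beta +/- 1.959964 se`.
#'
#' @param beta numeric vector of estimates.
#' @param se positive standard errors (same length).
#' @return list with `beta`, `se`, `ci_low`, `ci_high`, `k`.
#' @examples
#' ivw_fixed(c(0.10, 0.20), c(0.05, 0.10))  # beta 0.12, se 0.04472
#' @export
ivw_fixed <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (length(beta) == 0) stop("empty input: nothing to pool")
  if (any(!is.finite(se) | se <= 0))
    stop("all standard errors must be finite and > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  list(beta = b, se = s, ci_low = b - .z975 * s, ci_high = b + .z975 * s,
       k = length(beta))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i (b_i - beta_fixed)^2)` referred to chi-square(k-1).
#'
#' @inheritParams ivw_fixed
#' @return list with `Q` and `p_Q` (both `NA` when `k < 2`).
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2) return(list(Q = NA_real_, p_Q = NA_real_))
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  list(Q = Q, p_Q = stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' I-squared with one-sided upper 97.5% bound
#'
#' `I2 = max(0, (Q - (k-1))/Q) * 100`. The upper bound is the test-based
#' (Higgins-Thompson) interval on `ln H` with `H^2 = Q/(k-1)`:
#' `se(ln H) = (ln Q - ln(k-1)) / (2 (sqrt(2Q) - sqrt(2k-3)))` when
#' `Q > k`, else `sqrt(1/(2(k-2)) (1 - 1/(3(k-2)^2)))`; only the upper
#' 97.5% limit is reported, floored at the point estimate.
#'
#' @param Q Cochran's Q (>= 0).
#' @param k number of pooled estimates (>= 2).
#' @return list with `I2` and `I2_upper` (percent; `I2_upper` is `NA` with
#'   an explanatory `reason` when `k = 2` and `Q <= k`).
#' @export
i_squared <- function(Q, k) {
  stopifnot(k >= 2, Q >= 0)
  I2 <- max(0, (Q - (k - 1)) / Q) * 100
  if (Q == 0) I2 <- 0
  if (Q > k) {
    se_lnH <- (log(Q) - log(k - 1)) / (2 * (sqrt(2 * Q) - sqrt(2 * k - 3)))
  } else if (k > 2) {
    se_lnH <- sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    return(list(I2 = I2, I2_upper = NA_real_,
                reason = "upper bound undefined for k = 2 with Q <= k"))
  }
  H <- sqrt(max(Q / (k - 1), 1))
  Hu <- exp(log(H) + .z975 * se_lnH)
  I2u <- max(100 * (Hu^2 - 1) / Hu^2, I2)
  list(I2 = I2, I2_upper = I2u, reason = "")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with re-weighting `w*_i = 1/(se_i^2 + tau2)`.
#'
#' @inheritParams ivw_fixed
#' @return list with `beta`, `se`, `ci_low`, `ci_high`, `k`, `tau2`.
#' @examples
#' dl_random(c(0, 1), c(0.1, 0.1))  # tau2 0.49, beta 0.5, se 0.5
#' @export
dl_random <- function(beta, se) {
  k <- length(beta)
  if (k < 2) {
    out <- ivw_fixed(beta, se); out$tau2 <- 0; return(out)
  }
  if (any(!is.finite(se) | se <= 0))
    stop("all standard errors must be finite and > 0")
  w <- 1 / se^2
  Q <- cochran_q(beta, se)$Q
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- sqrt(1 / sum(ws))
  list(beta = b, se = s, ci_low = b - .z975 * s, ci_high = b + .z975 * s,
       k = k, tau2 = tau2)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum(ln p_i)` referred to chi-square(2k).
#'
#' @param p p-values in (0, 1]; exact zeros are clipped to the smallest
#'   positive double with a warning.
#' @return list with `X`, `df`, `p`.
#' @examples
#' fisher_combine(c(0.01, 0.04))  # X 15.648, df 4
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop("no p-values to combine")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no non-missing p-values to combine")
  if (any(p == 0)) {
    warning("p = 0 clipped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(X = X, df = df, p = stats::pchisq(X, df = df, lower.tail = FALSE))
}

#' Pool a set of estimates with full heterogeneity reporting
#'
#' Convenience wrapper producing one row per method (fixed and
#' DerSimonian-Laird random) with Q, I-squared and its one-sided upper
#' 97.5% bound.
#'
#' @param beta,se numeric vectors of estimates and standard errors.
#' @param snp_id,trait optional identifiers carried into the output.
#' @return data frame with columns `snp_id`, `trait`, `method`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `k`, `Q`, `p_Q`, `I2`, `I2_upper`, `tau2`.
#' @export
pool_estimates <- function(beta, se, snp_id = NA_character_,
                           trait = NA_character_) {
  fx <- ivw_fixed(beta, se)
  het <- cochran_q(beta, se)
  i2 <- if (fx$k >= 2) i_squared(het$Q, fx$k)
        else list(I2 = NA_real_, I2_upper = NA_real_)
  rd <- dl_random(beta, se)
  data.frame(
    snp_id = snp_id, trait = trait,
    method = c("fixed", "random"),
    beta = c(fx$beta, rd$beta), se = c(fx$se, rd$se),
    ci_low = c(fx$ci_low, rd$ci_low), ci_high = c(fx$ci_high, rd$ci_high),
    k = fx$k, Q = het$Q, p_Q = het$p_Q,
    I2 = i2$I2, I2_upper = i2$I2_upper,
    tau2 = c(NA_real_, rd$tau2),
    stringsAsFactors = FALSE)
}

#' Exclude estimates from studies violating Hardy-Weinberg equilibrium
#'
#' Removes every (study, SNP) pair whose HWE test p-value falls below the
#' threshold from all trait pooling for that pair, and logs each removal.
#'
#' @param estimates association-estimate data frame (needs `study_id`,
#'   `snp_id`).
#' @param hwe_results HWE data frame (`study_id`, `snp_id`, `p`).
#' @param threshold_p exclusion threshold in (0, 1); the conventional GWAS
#'   default is `1e-6`.
#' @param strict error (`TRUE`, default) or keep-with-warning (`FALSE`)
#'   when a (study, SNP) pair has no HWE result.
#' @return list with `estimates` (filtered) and `exclusions` (log data
#'   frame: `study_id`, `snp_id`, `rule`, `p`).
#' @export
hwe_filter <- function(estimates, hwe_results, threshold_p = 1e-6,
                       strict = TRUE) {
  stopifnot(threshold_p > 0, threshold_p < 1)
  if (threshold_p >= 0.5)
    warning("hwe threshold ", threshold_p,
            " will exclude most studies; is this intended?")
  key <- function(d) paste(d$study_id, d$snp_id)
  hk <- key(hwe_results)
  ek <- key(estimates)
  missing <- setdiff(unique(ek), hk)
  if (length(missing)) {
    msg <- paste("no HWE result for:", paste(missing, collapse = "; "))
    if (strict) stop(msg) else warning(msg)
  }
  bad <- hwe_results[!is.na(hwe_results$p) &
                       hwe_results$p < threshold_p, , drop = FALSE]
  drop <- ek %in% key(bad)
  exclusions <- if (nrow(bad)) data.frame(
    study_id = bad$study_id, snp_id = bad$snp_id,
    rule = sprintf("hwe_p<%g", threshold_p), p = bad$p,
    stringsAsFactors = FALSE) else
      data.frame(study_id = character(0), snp_id = character(0),
                 rule = character(0), p = numeric(0))
  list(estimates = estimates[!drop, , drop = FALSE],
       exclusions = exclusions)
}

#' Merge study-level and consortium-level evidence without double counting
#'
#' Consortium summary records subsume some contributing studies; those
#' studies' own estimates must not be pooled alongside the consortium
#' record. Overlap is declared explicitly (provenance knowledge cannot be
#' inferred from the data).
#'
#' @param study_estimates data frame of per-study estimates (`study_id`,
#'   `snp_id`, `trait`, `beta`, `se`, `n`).
#' @param consortium_records data frame of summary records (`source_id`,
#'   `snp_id`, `trait`, `beta`, `se`, `n`); may be `NULL` or empty.
#' @param overlap_exclusions named list: consortium `source_id` -> character
#'   vector of subsumed `study_id`s.
#' @return list with `pooling` (merged data frame with a `source` column)
#'   and `exclusions` (log of dropped study estimates with their rule).
#' @export
merge_sources <- function(study_estimates, consortium_records = NULL,
                          overlap_exclusions = list()) {
  if (length(overlap_exclusions) > 1) {
    all_sub <- unlist(overlap_exclusions, use.names = FALSE)
    dup <- unique(all_sub[duplicated(all_sub)])
    if (length(dup))
      stop("ambiguous provenance: study subsumed by two sources: ",
           paste(dup, collapse = ", "))
  }
  st <- study_estimates
  st$source <- st$study_id
  subsumed <- unlist(overlap_exclusions, use.names = FALSE)
  drop <- st$study_id %in% subsumed
  exclusions <- if (any(drop)) {
    rule <- vapply(st$study_id[drop], function(s) {
      src <- names(overlap_exclusions)[vapply(overlap_exclusions,
                                              function(v) s %in% v, TRUE)]
      sprintf("subsumed_by:%s", src[1])
    }, "")
    data.frame(study_id = st$study_id[drop], snp_id = st$snp_id[drop],
               rule = rule, p = NA_real_, stringsAsFactors = FALSE)
  } else data.frame(study_id = character(0), snp_id = character(0),
                    rule = character(0), p = numeric(0))
  keep_cols <- c("source", "snp_id", "trait", "beta", "se", "n")
  merged <- st[!drop, intersect(c(keep_cols, names(st)), names(st))]
  merged <- merged[, keep_cols[keep_cols %in% names(merged)], drop = FALSE]
  if (!is.null(consortium_records) && nrow(consortium_records)) {
    cr <- consortium_records
    cr$source <- cr$source_id
    cr <- cr[, keep_cols[keep_cols %in% names(cr)], drop = FALSE]
    merged <- rbind(merged, cr)
  }
  list(pooling = merged, exclusions = exclusions)
}

#' Pool per-allele estimates for every (SNP, trait)
#'
#' Applies the HWE filter and the sparse-cell quality filter, merges any
#' consortium records, and runs fixed- and random-effects IVW pooling per
#' (SNP, trait).
#'
#' @param estimates per-study association estimates (from
#'   [associate_cohorts()]).
#' @param hwe_results HWE table; `NULL` skips the filter.
#' @param consortium_records,overlap_exclusions see [merge_sources()].
#' @param hwe_threshold_p HWE exclusion threshold.
#' @param drop_flagged exclude estimates carrying a non-empty quality flag
#'   (default `TRUE`).
#' @return list with `pooled` (data frame, one row per SNP x trait x
#'   method) and `exclusions` (all removal log rows).
#' @export
pool_all <- function(estimates, hwe_results = NULL,
                     consortium_records = NULL,
                     overlap_exclusions = list(),
                     hwe_threshold_p = 1e-6,
                     drop_flagged = TRUE) {
  excl <- list()
  est <- estimates
  if (drop_flagged && "flag" %in% names(est)) {
    fl <- est$flag != ""
    if (any(fl))
      excl[[length(excl) + 1L]] <- data.frame(
        study_id = est$study_id[fl], snp_id = est$snp_id[fl],
        rule = paste0("flag:", est$flag[fl]), p = NA_real_,
        stringsAsFactors = FALSE)
    est <- est[!fl, , drop = FALSE]
  }
  if (!is.null(hwe_results)) {
    hf <- hwe_filter(est, hwe_results, hwe_threshold_p)
    est <- hf$estimates
    if (nrow(hf$exclusions)) excl[[length(excl) + 1L]] <- hf$exclusions
  }
  ms <- merge_sources(est, consortium_records, overlap_exclusions)
  if (nrow(ms$exclusions)) excl[[length(excl) + 1L]] <- ms$exclusions
  pooling <- ms$pooling
  keys <- unique(pooling[c("snp_id", "trait")])
  pooled <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- pooling$snp_id == keys$snp_id[i] & pooling$trait == keys$trait[i]
    pool_estimates(pooling$beta[sel], pooling$se[sel],
                   snp_id = keys$snp_id[i], trait = keys$trait[i])
  }))
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(study_id = character(0), snp_id = character(0),
               rule = character(0), p = numeric(0))
  list(pooled = pooled, exclusions = exclusions)
}
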