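# Wald-ratio scaling and the weighted gene-centric score: level 2 of the
# inference. Per-SNP pooled per-allele effects are first rescaled to a
# per-1-mmol/L-LOWER-LDL basis using each SNP's own pooled LDL effect, then
# combined across SNPs by inverse-variance weighting.

#' Scale a per-allele estimate to a per-1-mmol/L-lower-LDL basis
#'
#' Wald-ratio scaling: `beta_per_mmol = outcome_beta / |ldl_beta|` and
#' `se_per_mmol = outcome_se / |ldl_beta|` (the delta-method first-order
#' result; the LDL denominator is treated as fixed, with no second-order
#' uncertainty term). Orientation is per 1 mmol/L LOWER LDL, so an
#' outcome-raising association of an LDL-lowering allele yields a positive
#' scaled effect.
#'
#' @param outcome_beta,outcome_se per-allele outcome estimate.
#' @param ldl_beta per-allele LDL effect (mmol/L; negative under the
#'   LDL-lowering-allele convention).
#' @param weak_floor weak-instrument floor on `|ldl_beta|` (mmol/L).
#' @param snp_id used in error messages.
#' @return list with `beta`, `se` on the per-mmol scale.
#' @examples
#' wald_scale(0.0255, 0.010, -0.10)  # beta 0.255 -> OR exp(0.255) ~ 1.29
#' @export
wald_scale <- function(outcome_beta, outcome_se, ldl_beta,
                       weak_floor = 0.005, snp_id = "") {
  if (abs(ldl_beta) < weak_floor)
    stop("weak instrument: |ldl_beta| = ", format(abs(ldl_beta)),
         " below floor ", weak_floor,
         if (nzchar(snp_id)) paste0(" for ", snp_id) else "")
  list(beta = outcome_beta / abs(ldl_beta),
       se = outcome_se / abs(ldl_beta))
}

#' Combine scaled per-SNP estimates into the gene-centric score
#'
#' Inverse-variance-weighted pooling of the per-mmol per-SNP estimates
#' (fixed effect and DerSimonian-Laird random effects) with between-SNP Q,
#' I-squared and its one-sided upper 97.5% bound. Binary traits are
#' additionally reported on the odds-ratio scale.
#'
#' @param scaled data frame with columns `snp_id`, `beta`, `se` on the
#'   per-mmol scale.
#' @param trait trait name carried into the output.
#' @param binary exponentiate to odds ratios as well.
#' @return data frame with one row per method (`fixed`, `random`), columns
#'   as in [pool_estimates()] plus `or`, `or_low`, `or_high` for binary
#'   traits.
#' @export
gene_score <- function(scaled, trait = NA_character_, binary = FALSE) {
  stopifnot(nrow(scaled) >= 1)
  out <- pool_estimates(scaled$beta, scaled$se, snp_id = "GS",
                        trait = trait)
  if (binary) {
    out$or <- exp(out$beta)
    out$or_low <- exp(out$ci_low)
    out$or_high <- exp(out$ci_high)
  }
  out
}

#' Full two-level analysis for one trait
#'
#' The order is fixed: (1) pool per-allele estimates across studies per
#' SNP, (2) scale each SNP by its own pooled LDL effect, (3) pool the
#' scaled estimates across SNPs into the gene-centric score. All three
#' layers are returned.
#'
#' @param pooled pooled per-allele table from [pool_all()] (must contain
#'   rows for `trait` and for the LDL exposure trait).
#' @param trait outcome trait name.
#' @param binary is the trait binary (log-odds scale)?
#' @param ldl_trait name of the exposure rows (default `"ldl"`).
#' @param weak_floor weak-instrument floor passed to [wald_scale()]. SNPs
#'   whose pooled LDL effect falls below the floor are dropped from the
#'   score (recorded in the `weak_dropped` element) rather than aborting
#'   the trait; the analysis errors only if no usable instrument remains.
#' @return list with `snp_per_allele`, `snp_per_mmol` (both fixed-effect
#'   per-SNP rows), `gs` (fixed and random rows) and `weak_dropped`
#'   (character vector of excluded SNP ids).
#' @export
run_trait_analysis <- function(pooled, trait, binary = FALSE,
                               ldl_trait = "ldl", weak_floor = 0.005) {
  ldl <- pooled[pooled$trait == ldl_trait & pooled$method == "fixed", ]
  out <- pooled[pooled$trait == trait & pooled$method == "fixed", ]
  if (!nrow(out)) stop("no pooled estimates for trait ", trait)
  miss <- setdiff(out$snp_id, ldl$snp_id)
  if (length(miss))
    stop("no pooled LDL estimate for SNP(s): ", paste(miss, collapse = ", "))
  weak <- character(0)
  scaled <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    lb <- ldl$beta[ldl$snp_id == out$snp_id[i]]
    if (abs(lb) < weak_floor) {
      weak <<- c(weak, out$snp_id[i])
      return(NULL)
    }
    ws <- wald_scale(out$beta[i], out$se[i], lb, weak_floor,
                     snp_id = out$snp_id[i])
    data.frame(snp_id = out$snp_id[i], trait = trait, beta = ws$beta,
               se = ws$se, ci_low = ws$beta - .z975 * ws$se,
               ci_high = ws$beta + .z975 * ws$se, k = out$k[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(scaled) || !nrow(scaled))
    stop("no usable instrument for trait ", trait,
         ": all pooled LDL effects below the weak-instrument floor")
  gs <- gene_score(scaled, trait = trait, binary = binary)
  list(snp_per_allele = out, snp_per_mmol = scaled, gs = gs,
       weak_dropped = weak)
}

#' Build the forest table for a set of traits
#'
#' The tabular equivalent of the study's forest plots: one row per (trait,
#' level) with level in `study`-pooled per-allele per SNP, per-mmol per
#' SNP, and the fixed- and random-effects gene-centric score.
#'
#' @param pooled pooled per-allele table from [pool_all()].
#' @param traits character vector of outcome trait names.
#' @param binary_traits subset of `traits` on the log-odds scale.
#' @param weak_floor weak-instrument floor.
#' @return data frame with columns `trait`, `level`, `snp_id`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `or`, `or_low`, `or_high`, `k`, `Q`,
#'   `p_Q`, `I2`, `I2_upper`, `tau2`.
#' @export
forest_table <- function(pooled, traits, binary_traits = "t2d",
                         weak_floor = 0.005) {
  rows <- list()
  template <- c("trait", "level", "snp_id", "beta", "se", "ci_low",
                "ci_high", "or", "or_low", "or_high", "k", "Q", "p_Q",
                "I2", "I2_upper", "tau2")
  pad <- function(d, level) {
    d$level <- level
    for (col in setdiff(template, names(d))) d[[col]] <- NA_real_
    if (d$trait[1] %in% binary_traits && all(is.na(d$or))) {
      d$or <- exp(d$beta); d$or_low <- exp(d$ci_low)
      d$or_high <- exp(d$ci_high)
    }
    d[template]
  }
  for (tr in traits) {
    res <- run_trait_analysis(pooled, tr, binary = tr %in% binary_traits,
                              weak_floor = weak_floor)
    rows[[length(rows) + 1L]] <- pad(res$snp_per_allele, "snp_per_allele")
    rows[[length(rows) + 1L]] <- pad(res$snp_per_mmol, "snp_per_mmol")
    gs <- res$gs
    gs$level <- ifelse(gs$method == "fixed", "GS_fixed", "GS_random")
    gs$method <- NULL
    rows[[length(rows) + 1L]] <- pad(gs[gs$level == "GS_fixed", ],
                                     "GS_fixed")
    rows[[length(rows) + 1L]] <- pad(gs[gs$level == "GS_random", ],
                                     "GS_random")
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
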