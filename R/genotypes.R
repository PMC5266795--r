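# Gaussian-copula genotype generation.
#
# Each SNP's dosage is produced by double-thresholding one latent standard
# normal: g = 1{Z >= t1} + 1{Z >= t2}, with thresholds chosen so the
# genotype probabilities are the (possibly inbreeding-adjusted)
# Hardy-Weinberg proportions. Cross-SNP dependence comes from correlating
# the latent normals; the latent correlation is solved numerically so the
# realised genotypic r^2 hits its target. This supports arbitrary MAF
# combinations without haplotype-phase bookkeeping, at the price of a
# copula-attainable ceiling on r^2 for unequal MAFs (checked explicitly).

# genotype probabilities (P0, P1, P2) for minor-allele dosage, with
# inbreeding coefficient F: heterozygote deficit P1 = 2pq(1-F).
hwe_probs <- function(maf, F = 0) {
  p <- maf; q <- 1 - maf
  c(q^2 + F * p * q, 2 * p * q * (1 - F), p^2 + F * p * q)
}

geno_thresholds <- function(maf, F = 0) {
  pr <- hwe_probs(maf, F)
  c(t1 = stats::qnorm(pr[1]), t2 = stats::qnorm(pr[1] + pr[2]))
}

# P(Z1 >= a, Z2 >= b) for standard bivariate normal with correlation rho,
# by 1-D quadrature (no bivariate-normal package dependency).
binorm_upper <- function(a, b, rho) {
  if (rho == 0) return(stats::pnorm(a, lower.tail = FALSE) *
                         stats::pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((b - rho * z) / s, lower.tail = FALSE)
  stats::integrate(f, lower = max(a, -8.5), upper = 8.5,
                   rel.tol = 1e-10, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}

# Pearson correlation of the two dosages implied by latent correlation rho.
# Since g = sum of threshold indicators, E[g1 g2] is a sum of four upper
# rectangle probabilities.
geno_cor_from_latent <- function(rho, maf1, maf2, F1 = 0, F2 = 0) {
  t <- geno_thresholds(maf1, F1)
  s <- geno_thresholds(maf2, F2)
  eg12 <- binorm_upper(t[1], s[1], rho) + binorm_upper(t[1], s[2], rho) +
    binorm_upper(t[2], s[1], rho) + binorm_upper(t[2], s[2], rho)
  v1 <- 2 * maf1 * (1 - maf1) * (1 + F1)
  v2 <- 2 * maf2 * (1 - maf2) * (1 + F2)
  (eg12 - 4 * maf1 * maf2) / sqrt(v1 * v2)
}

#' Copula-attainable upper bound on pairwise genotypic r-squared
#'
#' The Gaussian-copula construction cannot produce arbitrarily high dosage
#' correlation when minor allele frequencies differ; this returns the
#' maximum achievable r^2 for a MAF pair (latent correlation -> 1).
#'
#' @param maf1,maf2 minor allele frequencies.
#' @return upper bound on r^2 in `[0, 1]`.
#' @export
attainable_r2 <- function(maf1, maf2) {
  geno_cor_from_latent(0.99995, maf1, maf2)^2
}

solve_latent_rho <- function(maf1, maf2, target_r2) {
  if (target_r2 == 0) return(0)
  target_r <- sqrt(target_r2)
  rmax <- geno_cor_from_latent(0.99995, maf1, maf2)
  if (target_r > rmax)
    stop(sprintf(paste0("target r^2 %.4g exceeds the copula-attainable ",
                        "bound %.4g for mafs (%.3g, %.3g)"),
                 target_r2, rmax^2, maf1, maf2), call. = FALSE)
  stats::uniroot(function(r) geno_cor_from_latent(r, maf1, maf2) - target_r,
                 interval = c(0, 0.99995), tol = 1e-9)$root
}

# cache of solved latent correlation matrices (solving needs ~40 quadrature
# calls per pair; the same matrix is reused across every study in a run)
.latent_cache <- new.env(parent = emptyenv())

latent_corr_matrix <- function(variants, ld_r2) {
  mafs <- vapply(variants, `[[`, 0, "maf")
  key <- paste(format(c(mafs, ld_r2), digits = 12), collapse = ",")
  if (!is.null(.latent_cache[[key]])) return(.latent_cache[[key]])
  p <- length(variants)
  R <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    R[i, j] <- R[j, i] <- solve_latent_rho(mafs[i], mafs[j], ld_r2[i, j])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf(paste0("latent correlation matrix not positive ",
                        "semi-definite after copula adjustment ",
                        "(smallest eigenvalue %.3g)"), min(ev)),
         call. = FALSE)
  .latent_cache[[key]] <- R
  R
}

#' Sample correlated genotype dosages
#'
#' Draws an `n x p` integer dosage matrix (minor-allele counts 0/1/2) whose
#' marginal genotype frequencies follow Hardy-Weinberg proportions (with
#' optional inbreeding-driven heterozygote deficit) and whose pairwise
#' dosage r-squared converges to the target `ld_r2`. Uses the ambient RNG
#' stream; call [set.seed()] (or let the cohort simulator manage
#' substreams) for reproducibility.
#'
#' @param variants list of [variant_spec()].
#' @param ld_r2 symmetric target genotypic r-squared matrix.
#' @param n number of individuals.
#' @param inbreeding_F inbreeding coefficient F in `[0, 1)` (or exactly 1
#'   for the degenerate all-homozygote case); shifts thresholds so
#'   P(het) = 2pq(1-F).
#' @return integer matrix with one column per SNP, named by `snp_id`, and a
#'   `"attainable_r2"` attribute carrying the pairwise copula bounds.
#' @examples
#' g <- sample_genotypes(default_variants(), default_ld_r2(), n = 100)
#' @export
sample_genotypes <- function(variants, ld_r2, n, inbreeding_F = 0) {
  stopifnot(n >= 1, inbreeding_F >= 0, inbreeding_F <= 1)
  p <- length(variants)
  R <- latent_corr_matrix(variants, ld_r2)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (p > 1) Z <- Z %*% chol(R)
  G <- matrix(0L, n, p,
              dimnames = list(NULL, vapply(variants, `[[`, "", "snp_id")))
  bounds <- matrix(1, p, p)
  for (j in seq_len(p)) {
    th <- geno_thresholds(variants[[j]]$maf, inbreeding_F)
    G[, j] <- (Z[, j] >= th[1]) + (Z[, j] >= th[2])
  }
  # generation-time LD sanity check: realised r^2 must not exceed the
  # copula-attainable maximum beyond sampling slack
  if (p > 1 && n >= 1000) {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      bounds[i, j] <- bounds[j, i] <-
        attainable_r2(variants[[i]]$maf, variants[[j]]$maf)
      if (stats::var(G[, i]) > 0 && stats::var(G[, j]) > 0) {
        r2 <- stats::cor(G[, i], G[, j])^2
        if (r2 > bounds[i, j] + 6 / sqrt(n))
          warning(sprintf("realised r^2 %.3g exceeds attainable bound %.3g",
                          r2, bounds[i, j]))
      }
    }
  }
  attr(G, "attainable_r2") <- bounds
  G
}
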