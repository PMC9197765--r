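# Replicate single-SNP experiments measuring the sampling variance of the
# family-based estimators, used to validate the closed-form efficiency and
# bias results against simulation.

#' Sibling-pair estimator comparison over simulation replicates
#'
#' Each replicate simulates independent sibling-pair families at one SNP and
#' computes, from the same data: the direct effect and average NTC from the
#' GLS regression of both siblings' phenotypes on (own genotype, imputed
#' parental sum) with phased-resolved imputation and, optionally, unphased
#' imputation; the sibling-difference direct-effect estimate; the
#' no-imputation baseline (regression on own and sibling genotype, with
#' `alpha = 3/2 x` the sibling-genotype coefficient); and the structure-robust
#' split estimate (separate regressions by IBD state, inverse-variance
#' combined).
#'
#' @param n_reps Number of replicates.
#' @param n_families Families per replicate.
#' @param r Sibling residual correlation (the GLS uses the true value).
#' @param f Allele-1 frequency.
#' @param delta,alpha True direct effect and average NTC (defaults 0: the
#'   sampling variance of the estimators does not depend on them).
#' @param unphased Also compute the unphased-imputation estimates.
#' @param split Also compute the robust split estimate.
#' @return Tibble with one row per replicate and one column per estimator.
#' @export
sib_efficiency_experiment <- function(n_reps, n_families, r = 0, f = 0.25,
                                      delta = 0, alpha = 0,
                                      unphased = FALSE, split = FALSE) {
  vc <- list(sigma2_F = r, sigma2_e = 1 - r)
  out <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    d <- simulate_snp_families(n_families, f, delta = delta,
                               alpha_p = alpha, alpha_m = alpha, r = r)
    y <- c(d$y1, d$y2)
    g_own <- c(d$g1, d$g2); g_sib <- c(d$g2, d$g1)
    fam <- c(d$family_id, d$family_id)
    imp <- impute_parsum_sibs(d$g1, d$g2, d$ibd, f, d$ns2)
    gpar_hat <- rep(as.numeric(imp), 2)
    fit_imp <- estimate_snp_effects(y, cbind(delta = g_own, alpha = gpar_hat), fam, vc)
    fit_base <- estimate_snp_effects(y, cbind(delta = g_own, b_sib = g_sib), fam, vc)
    sd_est <- sibdiff_estimate(d$y1, d$y2, d$g1, d$g2)
    row <- tibble(
      delta_imp = fit_imp$estimates["delta"],
      alpha_imp = fit_imp$estimates["alpha"],
      se_delta_imp = sqrt(fit_imp$vcov["delta", "delta"]),
      se_alpha_imp = sqrt(fit_imp$vcov["alpha", "alpha"]),
      delta_sibdiff = sd_est$estimate,
      alpha_base = 1.5 * fit_base$estimates["b_sib"])
    if (unphased) {
      impu <- impute_parsum_sibs(d$g1, d$g2, d$ibd, f)
      fit_u <- estimate_snp_effects(y, cbind(delta = g_own,
                                             alpha = rep(as.numeric(impu), 2)), fam, vc)
      row$delta_unphased <- fit_u$estimates["delta"]
      row$alpha_unphased <- fit_u$estimates["alpha"]
    }
    if (split) {
      rs <- suppressWarnings(robust_split_estimate(
        y, g_own, gpar_hat, fam, rep(4L - d$ibd, 2), vc))
      row$delta_split <- rs$delta
    }
    out[[rep]] <- row
  }
  bind_rows(out)
}

#' Parent-offspring versus trio estimator comparison over replicates
#'
#' Each replicate simulates families at one SNP and estimates the direct
#' effect twice from the same families: from the full trio regression
#' (offspring, father, mother all observed) and from the parent-offspring
#' regression in which the father is imputed from the offspring-mother pair
#' (phased: the paternally transmitted allele is known; unphased: doubly
#' heterozygous cases are averaged).
#'
#' @param n_reps Number of replicates.
#' @param n_families Families per replicate.
#' @param f Allele-1 frequency.
#' @param phased Whether the parent-offspring imputation is phase-resolved.
#' @return Tibble with `delta_trio` and `delta_po` per replicate.
#' @export
po_efficiency_experiment <- function(n_reps, n_families, f = 0.5, phased = TRUE) {
  vc <- list(sigma2_F = 0, sigma2_e = 1)
  out <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    d <- simulate_snp_families(n_families, f)
    imp <- impute_parent_from_parent_offspring(
      d$g1, d$gm, f, transmitted = if (phased) d$a_p1 else NA)
    fit_trio <- estimate_snp_effects(
      d$y1, cbind(delta = d$g1, alpha_p = d$gp, alpha_m = d$gm), d$family_id, vc)
    fit_po <- estimate_snp_effects(
      d$y1, cbind(delta = d$g1, alpha_p = as.numeric(imp), alpha_m = d$gm),
      d$family_id, vc)
    out[[rep]] <- tibble(delta_trio = fit_trio$estimates["delta"],
                         delta_po = fit_po$estimates["delta"])
  }
  bind_rows(out)
}

#' Variance ratio of two estimators with a block-jackknife standard error
#'
#' The effective-sample-size ratio of estimator B relative to estimator A is
#' `var(A)/var(B)` over replicates. The standard error comes from a
#' delete-one-block jackknife over contiguous replicate blocks.
#'
#' @param a,b Replicate estimate vectors (numerator variance: `a`).
#' @param n_blocks Number of jackknife blocks.
#' @return Tibble with `ratio` and `se`.
#' @export
variance_ratio <- function(a, b, n_blocks = 50) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  blk <- cut(seq_len(n), n_blocks, labels = FALSE)
  full <- var(a) / var(b)
  loo <- vapply(seq_len(n_blocks), function(k) {
    i <- blk != k
    var(a[i]) / var(b[i])
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((loo - mean(loo))^2))
  tibble(ratio = full, se = se)
}
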