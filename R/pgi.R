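# Polygenic-index scoring and the PGI-level direct/NTC model, including the
# adjustment of NTC estimates for imputation bias under assortative mating.

#' Score polygenic indices from a weight file
#'
#' `PGI = sum_l w_l x` (dosage of the effect allele at SNP l). SNPs are
#' matched by ID; when the effect allele is allele "0" the dosage is flipped
#' (`ploidy - g`). Strand-ambiguous weight SNPs (A/T, C/G) are dropped by
#' default; unmatched SNPs are dropped with a reported count, and more than
#' 50% unmatched is an error.
#'
#' @param dosages Matrix (individuals or families x SNPs) of allele-1
#'   dosages; columns named by SNP ID (e.g. from [genotypes()], or imputed
#'   parental dosages).
#' @param variants Variant tibble with `snp_id`, `allele0`, `allele1`.
#' @param weights Tibble from [read_pgi_weights()].
#' @param ploidy Dosage scale: 2 for individuals, 4 for imputed parental sums.
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) weight SNPs.
#' @return Numeric vector of PGI values (one per row of `dosages`), with
#'   attribute `n_matched`.
#' @export
score_pgi <- function(dosages, variants, weights, ploidy = 2, drop_ambiguous = TRUE) {
  w <- weights
  if (drop_ambiguous) {
    v <- variants[match(w$snp_id, variants$snp_id), ]
    amb <- !is.na(v$allele0) &
      paste0(pmin(v$allele0, v$allele1), pmax(v$allele0, v$allele1)) %in% c("AT", "CG")
    if (any(amb)) {
      inform(sprintf("dropping %d strand-ambiguous weight SNP(s)", sum(amb)))
      w <- w[!amb, ]
    }
  }
  if (nrow(w) == 0) abort("no usable weight SNPs after filtering")
  idx <- match(w$snp_id, variants$snp_id)
  matched <- !is.na(idx)
  ok_allele <- matched &
    (w$effect_allele == variants$allele1[idx] | w$effect_allele == variants$allele0[idx])
  if (mean(ok_allele) < 0.5) {
    abort(sprintf("only %d/%d weight SNPs matched the variant set", sum(ok_allele), nrow(w)))
  }
  if (any(!ok_allele)) {
    inform(sprintf("%d weight SNP(s) unmatched and dropped", sum(!ok_allele)))
  }
  w <- w[ok_allele, ]; idx <- idx[ok_allele]
  flip <- w$effect_allele == variants$allele0[idx]
  D <- dosages[, variants$snp_id[idx], drop = FALSE]
  eff <- sweep(D, 2, ifelse(flip, -1, 1) * w$weight, `*`)
  pgi <- rowSums(eff) + sum(w$weight[flip]) * ploidy
  structure(pgi, n_matched = nrow(w))
}

# profile log-likelihood over the sibling residual correlation with the fixed
# effects and total variance profiled out; used for joint ML of theta and the
# variance components
joint_ml_fit <- function(y, X, fam, r_max = 0.99) {
  n <- length(y)
  m <- table(as.character(fam))
  prof <- function(r) {
    fit <- fit_family_gls(y, X, fam, sigma2_F = r, sigma2_e = 1 - r)
    e <- y - drop(X %*% fit$coefficients)
    Se <- rowsum(e, as.character(fam))
    a_fam <- 1 + (as.numeric(m) - 1) * r
    Q <- (sum(e^2) - sum(r * Se^2 / a_fam)) / (1 - r)
    s2 <- Q / n
    ld <- sum((as.numeric(m) - 1) * log(1 - r) + log(a_fam))
    -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
  }
  opt <- optimize(prof, c(0, r_max), maximum = TRUE, tol = 1e-8)
  r <- if (prof(1e-12) > opt$objective) 0 else opt$maximum
  fit <- fit_family_gls(y, X, fam, sigma2_F = r, sigma2_e = 1 - r)
  e <- y - drop(X %*% fit$coefficients)
  Se <- rowsum(e, as.character(fam))
  a_fam <- 1 + (as.numeric(m) - 1) * r
  s2 <- ((sum(e^2) - sum(r * Se^2 / a_fam)) / (1 - r)) / n
  vc <- structure(list(sigma2_F = r * s2, sigma2_e = (1 - r) * s2, r = r,
                       loglik = max(opt$objective, prof(1e-12)),
                       n = n, n_families = length(m)),
                  class = "fam_varcomps")
  list(vc = vc, sigma2 = s2)
}

#' Fit the PGI-level direct/NTC model
#'
#' Joint maximum likelihood of the variance components and fixed effects for
#' a regression of the phenotype on the proband's PGI, optionally the mean
#' PGI of the siblings, and the parents' (observed or imputed) PGIs — or the
#' imputed parental-sum PGI for sibling-pair data. The variance parameters
#' are estimated jointly with the effects because a PGI may explain a
#' substantial fraction of phenotypic variance. PGIs are standardized by the
#' proband-PGI standard deviation, so effects are per proband-PGI SD.
#'
#' @param y Phenotype vector (one row per proband).
#' @param pgi_proband Proband PGI.
#' @param family_id Family identifier.
#' @param pgi_father,pgi_mother Parental PGIs (observed or imputed), or `NULL`.
#' @param pgi_parsum Imputed parental-sum PGI (sibling-pair families), or
#'   `NULL`.
#' @param pgi_sib Mean sibling PGI (required for `model = "with_sib_ige"`).
#' @param model `"no_sib_ige"` or `"with_sib_ige"`.
#' @param standardize Standardize by the proband-PGI SD.
#' @return An `effect_estimate` with the fitted `fam_varcomps` attached as
#'   attribute `varcomps`.
#' @export
fit_pgi_model <- function(y, pgi_proband, family_id,
                          pgi_father = NULL, pgi_mother = NULL,
                          pgi_parsum = NULL, pgi_sib = NULL,
                          model = c("no_sib_ige", "with_sib_ige"),
                          standardize = TRUE) {
  model <- match.arg(model)
  s <- if (standardize) sd(pgi_proband) else 1
  fd <- tibble(y = y, family_id = family_id, g = pgi_proband / s,
               g_sib = if (is.null(pgi_sib)) NA_real_ else pgi_sib / s,
               g_father = if (is.null(pgi_father)) NA_real_ else pgi_father / s,
               g_mother = if (is.null(pgi_mother)) NA_real_ else pgi_mother / s,
               g_parsum = if (is.null(pgi_parsum)) NA_real_ else pgi_parsum / s)
  des <- assemble_design(fd, model)
  Xi <- cbind(`(Intercept)` = 1, scale(des$X, center = TRUE, scale = FALSE))
  jf <- joint_ml_fit(des$y, Xi, des$family_id)
  fit <- fit_family_gls(des$y, Xi, des$family_id, jf$vc$sigma2_F, jf$vc$sigma2_e)
  est <- structure(list(estimates = fit$coefficients[-1],
                        vcov = fit$vcov[-1, -1, drop = FALSE],
                        n_individuals = fit$n, n_families = fit$n_families),
                   class = "effect_estimate")
  attr(est, "varcomps") <- jf$vc
  est
}

#' Spousal PGI correlation from genotyped parent pairs
#'
#' The equilibrium spousal PGI correlation `r_am` feeding
#' [adjust_ntc_for_am()], estimated as the Pearson correlation of parental
#' PGIs among families where both parents are genotyped.
#'
#' @param pgi_father,pgi_mother PGIs of genotyped parent couples.
#' @return Scalar correlation.
#' @export
estimate_r_am <- function(pgi_father, pgi_mother) {
  ok <- complete.cases(pgi_father, pgi_mother)
  if (sum(ok) < 3) abort("no (or too few) fully genotyped parent pairs; supply r_am explicitly")
  cor(pgi_father[ok], pgi_mother[ok])
}

#' Adjust NTC estimates for imputation bias under assortative mating
#'
#' Under equilibrium assortative mating with spousal PGI correlation `r_am`,
#' per-SNP (or per-PGI) imputation from phased sibling pairs inflates the
#' average-NTC estimate by `(1 + r_am)/(1 + r_am/2)` while leaving the direct
#' effect unbiased. This divides the NTC estimate(s), their standard errors
#' and the corresponding covariance entries by that factor.
#'
#' @param est An `effect_estimate`.
#' @param r_am Spousal PGI correlation in (-1, 1).
#' @param imputation_class Design class the estimates came from; the
#'   correction is derived for `"SIB_PAIRS_NO_PARENTS"` (phased) and a
#'   warning is emitted for other classes, which are returned unchanged.
#' @return The adjusted `effect_estimate`, with attribute `am_inflation`.
#' @export
adjust_ntc_for_am <- function(est, r_am, imputation_class = "SIB_PAIRS_NO_PARENTS") {
  if (!is.finite(r_am) || r_am <= -1 || r_am >= 1) abort("r_am must be in (-1, 1)")
  if (!identical(imputation_class, "SIB_PAIRS_NO_PARENTS")) {
    warn("AM inflation factor is derived for phased sibling-pair imputation only; estimates returned unchanged")
    return(est)
  }
  factor <- (1 + r_am) / (1 + r_am / 2)
  labs <- intersect(c("alpha", "alpha_par", "alpha_p", "alpha_m"), names(est$estimates))
  if (length(labs) == 0) {
    warn("no NTC terms to adjust")
    return(est)
  }
  scale <- setNames(rep(1, length(est$estimates)), names(est$estimates))
  scale[labs] <- 1 / factor
  est$estimates <- est$estimates * scale
  est$vcov <- diag(scale) %*% est$vcov %*% diag(scale)
  dimnames(est$vcov) <- list(names(est$estimates), names(est$estimates))
  attr(est, "am_inflation") <- factor
  est
}
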