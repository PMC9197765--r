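# SNP-effect estimation under the family random-effect linear mixed model:
# Y_ij = X_ij theta + mu_i + e_ij, mu_i ~ N(0, sigma_F^2), e_ij ~ N(0, sigma_e^2).
# All solves exploit the family block structure: no n x n matrix is ever formed
# and the per-SNP cost is linear in the number of individuals.

#' Fit null-model variance components by maximum likelihood
#'
#' Fits the family random-effect model with no fixed effects beyond a grand
#' mean, by profile maximum likelihood over the sibling residual correlation
#' `r = sigma_F^2 / (sigma_F^2 + sigma_e^2)` (the total variance and the mean
#' are profiled out analytically, so each likelihood evaluation is O(n)).
#'
#' @param y Numeric phenotype vector (finite values only).
#' @param family_id Family identifier per observation.
#' @param r_max Upper bound of the optimizer's search interval for `r`.
#' @return Object of class `fam_varcomps` with elements `sigma2_F`,
#'   `sigma2_e`, `r`, `loglik`, `n`, `n_families`.
#' @export
fit_null_varcomps <- function(y, family_id, r_max = 0.99) {
  if (any(!is.finite(y))) abort("non-finite phenotype values")
  fam <- as.character(family_id)
  m <- table(fam)
  n <- length(y)
  if (sum(m >= 2) < 2) {
    warn("fewer than 2 families with 2+ phenotyped members; sigma2_F set to 0")
    s2 <- var(y) * (n - 1) / n
    return(structure(list(sigma2_F = 0, sigma2_e = s2, r = 0,
                          loglik = sum(stats::dnorm(y, mean(y), sqrt(s2), log = TRUE)),
                          n = n, n_families = length(m)),
                     class = "fam_varcomps"))
  }
  mi <- as.numeric(m[fam])
  prof <- function(r) {
    a <- 1 + (mi - 1) * r           # per observation, a of its family
    S <- rowsum(y, fam)             # family sums
    a_fam <- 1 + (as.numeric(m) - 1) * r
    mu <- sum(S / a_fam) / sum(as.numeric(m) / a_fam)
    e <- y - mu
    Se <- rowsum(e, fam)
    Q <- (sum(e^2) - sum(r * Se^2 / a_fam)) / (1 - r)
    s2 <- Q / n
    ld <- sum((as.numeric(m) - 1) * log(1 - r) + log(a_fam))
    -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
  }
  opt <- optimize(prof, c(0, r_max), maximum = TRUE, tol = 1e-8)
  r <- opt$maximum
  # recover the profiled total variance at the optimum
  a_fam <- 1 + (as.numeric(m) - 1) * r
  S <- rowsum(y, fam)
  mu <- sum(S / a_fam) / sum(as.numeric(m) / a_fam)
  e <- y - mu
  Se <- rowsum(e, fam)
  s2 <- (sum(e^2) - sum(r * Se^2 / a_fam)) / ((1 - r) * n)
  # boundary polish: r = 0 profile can beat the interior optimum
  if (prof(1e-12) > opt$objective) { r <- 0; s2 <- sum(e^2) / n }
  structure(list(sigma2_F = r * s2, sigma2_e = (1 - r) * s2, r = r,
                 loglik = max(opt$objective, prof(1e-12)), n = n,
                 n_families = length(m)),
            class = "fam_varcomps")
}

#' @export
print.fam_varcomps <- function(x, ...) {
  cat(sprintf("<fam_varcomps> sigma2_F = %.4f, sigma2_e = %.4f (r = %.3f), %d individuals in %d families\n",
              x$sigma2_F, x$sigma2_e, x$r, x$n, x$n_families))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fam_varcomps <- function(x, ...) {
  tibble(component = c("sigma2_F", "sigma2_e", "r"),
         estimate = c(x$sigma2_F, x$sigma2_e, x$r))
}

#' @exportS3Method generics::glance
glance.fam_varcomps <- function(x, ...) {
  tibble(sigma2_F = x$sigma2_F, sigma2_e = x$sigma2_e, r = x$r,
         logLik = x$loglik, n = x$n, n_families = x$n_families)
}

# Family-block GLS core. Returns coefficient vector and its sampling
# covariance (X' V^-1 X)^-1 under V = sigma2_e I + sigma2_F J per family.
fit_family_gls <- function(y, X, fam, sigma2_F, sigma2_e) {
  X <- as.matrix(X)
  if (sigma2_F == 0) {
    # independent residuals: ordinary weighted crossproducts
    XtVX <- crossprod(X) / sigma2_e
    XtVy <- crossprod(X, y) / sigma2_e
    nfam <- length(unique(fam))
  } else {
    f <- factor(fam)
    m <- tabulate(f)
    k <- sigma2_F / (sigma2_e + m * sigma2_F)  # per family
    S <- rowsum(X, f)
    Sy <- rowsum(y, f)
    sk <- sqrt(k)
    XtVX <- (crossprod(X) - crossprod(S * sk)) / sigma2_e
    XtVy <- (crossprod(X, y) - crossprod(S * sk, Sy * sk)) / sigma2_e
    nfam <- length(m)
  }
  qrx <- qr(XtVX)
  if (qrx$rank < ncol(X)) abort("rank-deficient design (collinear columns)")
  vcov <- solve(XtVX)
  est <- drop(vcov %*% XtVy)
  list(coefficients = setNames(est, colnames(X)),
       vcov = vcov, n = length(y), n_families = nfam)
}

#' Estimate SNP effects by GLS under the family mixed model
#'
#' Generalized least squares with the variance components fixed (typically at
#' their null-model maximum-likelihood estimates). Genotype columns are
#' mean-centered; an intercept is fitted internally and dropped from the
#' output. The sampling covariance of the estimates is `(X' V^-1 X)^-1`.
#'
#' @param y Phenotype vector.
#' @param X Design matrix with named columns (see [assemble_design()]).
#' @param family_id Family identifier per row.
#' @param vc A `fam_varcomps` object (or list with `sigma2_F`, `sigma2_e`).
#' @param center Mean-center the design columns (default `TRUE`).
#' @return Object of class `effect_estimate`: `estimates` (named vector),
#'   `vcov`, `n_individuals`, `n_families`.
#' @export
estimate_snp_effects <- function(y, X, family_id, vc, center = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(colMeans(X^2) - colMeans(X)^2 <= 0)) {
    abort("monomorphic (zero-variance) design column")
  }
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- fit_family_gls(y, Xi, family_id, vc$sigma2_F, vc$sigma2_e)
  keep <- -1
  structure(list(estimates = fit$coefficients[keep],
                 vcov = fit$vcov[keep, keep, drop = FALSE],
                 n_individuals = fit$n, n_families = fit$n_families),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate>\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.effect_estimate <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = sqrt(diag(x$vcov)),
         statistic = unname(x$estimates) / sqrt(diag(x$vcov)),
         p.value = 2 * pnorm(-abs(unname(x$estimates) / sqrt(diag(x$vcov)))))
}

#' @exportS3Method generics::glance
glance.effect_estimate <- function(x, ...) {
  pe <- population_effect(x)
  tibble(n_individuals = x$n_individuals, n_families = x$n_families,
         beta_pop = pe$beta, se_beta_pop = pe$se)
}

#' Derive the population effect from a fitted effect estimate
#'
#' The population effect is the direct effect plus the average NTC:
#' `beta = delta + (alpha_p + alpha_m)/2` when both parental NTCs are fitted,
#' `beta = delta + alpha` when a combined average NTC is fitted, and
#' `beta = delta + alpha_par + eta_s/2` for the sibling-pair parametrization
#' with a sibling indirect effect. The variance comes from the delta method
#' on the stored sampling covariance.
#'
#' @param est An `effect_estimate`.
#' @return Tibble with `beta` and `se`.
#' @export
population_effect <- function(est) {
  wvec <- pop_effect_weights(names(est$estimates))
  beta <- sum(wvec * est$estimates)
  v <- drop(t(wvec) %*% est$vcov %*% wvec)
  tibble(beta = beta, se = sqrt(v),
         cov_delta_beta = drop(est$vcov["delta", , drop = FALSE] %*% wvec))
}

pop_effect_weights <- function(labs) {
  wvec <- setNames(rep(0, length(labs)), labs)
  if (!"delta" %in% labs) abort("no direct-effect (delta) term fitted")
  wvec["delta"] <- 1
  if (all(c("alpha_p", "alpha_m") %in% labs)) {
    wvec[c("alpha_p", "alpha_m")] <- 0.5
  } else if ("alpha" %in% labs) {
    wvec["alpha"] <- 1
  } else if ("alpha_par" %in% labs) {
    wvec["alpha_par"] <- 1
    if ("eta_s" %in% labs) wvec["eta_s"] <- 0.5
  } else {
    abort("no NTC term fitted; population effect undefined")
  }
  wvec
}

#' Sibling-difference estimator of delta - eta_s
#'
#' Regression of within-pair phenotype differences on genotype differences,
#' the classical family-based baseline. Unbiased for `delta - eta_s`.
#'
#' @param y1,y2 Phenotypes of the two siblings per family.
#' @param g1,g2 Their genotypes.
#' @return Tibble with `estimate` and `se`.
#' @export
sibdiff_estimate <- function(y1, y2, g1, g2) {
  dg <- g1 - g2
  if (var(dg) == 0) abort("no within-pair genotype variation; estimator undefined")
  dy <- y1 - y2
  dgc <- dg - mean(dg); dyc <- dy - mean(dy)
  sxx <- sum(dgc^2)
  slope <- sum(dgc * dyc) / sxx
  rss <- sum((dyc - slope * dgc)^2)
  tibble(estimate = slope, se = sqrt(rss / (length(dg) - 2) / sxx))
}

#' Structure-robust split estimator of the direct effect
#'
#' Splits the regression by the number of observed parental alleles (for
#' sibling pairs, `4 - IBD`), fits each group separately with its own NTC
#' column, and combines the group direct-effect estimates by inverse-variance
#' weighting. Because no group mixes imputations with different numbers of
#' observed alleles, the combined estimate is unbiased under population
#' structure. Groups smaller than `min_group` families are merged into the
#' nearest group.
#'
#' @param y Phenotype vector (proband rows, or both sibs' rows).
#' @param g Proband genotype per row.
#' @param g_imp Imputed parental quantity per row (e.g. the parental sum).
#' @param family_id Family identifier per row.
#' @param group Number of observed parental alleles per row.
#' @param vc A `fam_varcomps` object.
#' @param min_group Minimum families per group.
#' @return Tibble with `delta`, `se`, `n_groups`, plus a `groups` attribute
#'   with the per-group fits.
#' @export
robust_split_estimate <- function(y, g, g_imp, family_id, group, vc, min_group = 30) {
  group <- as.numeric(group)
  repeat {
    sizes <- tapply(as.character(family_id), group, function(x) length(unique(x)))
    small <- names(sizes)[sizes < min_group]
    if (length(small) == 0 || length(sizes) == 1) break
    s <- as.numeric(small[1])
    others <- as.numeric(setdiff(names(sizes), small[1]))
    nearest <- others[which.min(abs(others - s))]
    warn(sprintf("merging group %s (%d families) into group %s",
                 small[1], sizes[small[1]], nearest))
    group[group == s] <- nearest
  }
  fits <- lapply(sort(unique(group)), function(gr) {
    idx <- group == gr
    # groups where the imputation is an affine function of the proband
    # genotype (e.g. sibling pairs in IBD2) carry no direct-effect
    # information and are dropped
    est <- tryCatch(
      estimate_snp_effects(y[idx],
                           cbind(delta = g[idx], alpha_par = g_imp[idx]),
                           family_id[idx], vc),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    tibble(group = gr, delta = unname(est$estimates["delta"]),
           var_delta = est$vcov["delta", "delta"],
           n_families = est$n_families)
  })
  fits <- bind_rows(fits)
  if (nrow(fits) == 0) abort("no group carries direct-effect information")
  w <- 1 / fits$var_delta
  out <- tibble(delta = sum(w * fits$delta) / sum(w),
                se = sqrt(1 / sum(w)), n_groups = nrow(fits))
  attr(out, "groups") <- fits
  out
}

#' Assemble a per-SNP regression design across family classes
#'
#' Builds the combined design: all rows share the direct-effect column (and,
#' in the sibling-IGE model, the sibling column); families with observed or
#' individually imputed parents contribute father/mother columns
#' (`alpha_p`/`alpha_m`), while families where only the parental sum is
#' imputable contribute a separate parental-sum column (`alpha_par` under the
#' sibling-IGE model, `alpha` otherwise) so that parental-sum families never
#' receive separate father/mother columns. Class-specific columns are zero
#' outside their class and centered within it.
#'
#' @param fam_data Tibble with one row per phenotyped, genotyped proband:
#'   columns `y`, `family_id`, `g`, and optionally `g_sib` (mean genotype of
#'   the proband's genotyped siblings), `g_father`, `g_mother` (observed or
#'   imputed), `g_parsum` (imputed parental sum).
#' @param model `"no_sib_ige"` (drops the sibling column) or `"with_sib_ige"`.
#' @return List with `y`, `X` (named, centered), `family_id`, `labels`.
#' @export
assemble_design <- function(fam_data, model = c("no_sib_ige", "with_sib_ige")) {
  model <- match.arg(model)
  d <- fam_data
  keep <- !is.na(d$g)
  if (model == "with_sib_ige") {
    if (is.null(d$g_sib) || all(is.na(d$g_sib))) {
      abort("sibling-IGE model requires g_sib")
    }
    keep <- keep & !is.na(d$g_sib)
  }
  d <- lapply(setNames(nm = c("y", "family_id", "g", "g_sib", "g_father",
                              "g_mother", "g_parsum")),
              function(nm) {
                col <- fam_data[[nm]]
                if (is.null(col)) NULL else col[keep]
              })
  cols <- list(delta = d$g)
  if (model == "with_sib_ige") cols$eta_s <- d$g_sib
  has_pm <- !is.null(d$g_father) && !is.null(d$g_mother) &&
    any(!is.na(d$g_father) & !is.na(d$g_mother))
  has_ps <- !is.null(d$g_parsum) && any(!is.na(d$g_parsum))
  if (has_pm) {
    pm <- !is.na(d$g_father) & !is.na(d$g_mother)
    cols$alpha_p <- ifelse(pm, d$g_father, 0)
    cols$alpha_m <- ifelse(pm, d$g_mother, 0)
  }
  if (has_ps) {
    ps <- !is.na(d$g_parsum)
    nm <- if (model == "with_sib_ige") "alpha_par" else "alpha"
    cols[[nm]] <- ifelse(ps, d$g_parsum, 0)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # shared columns centered globally; class-specific columns within class
  X[, "delta"] <- X[, "delta"] - mean(X[, "delta"])
  if ("eta_s" %in% colnames(X)) X[, "eta_s"] <- X[, "eta_s"] - mean(X[, "eta_s"])
  for (nm in intersect(c("alpha_p", "alpha_m", "alpha", "alpha_par"), colnames(X))) {
    mask <- if (nm %in% c("alpha_p", "alpha_m")) {
      !is.na(d$g_father) & !is.na(d$g_mother)
    } else !is.na(d$g_parsum)
    X[mask, nm] <- X[mask, nm] - mean(X[mask, nm])
    X[!mask, nm] <- 0
  }
  list(y = d$y, X = X, family_id = d$family_id, labels = colnames(X))
}

#' Genome-wide family-based association scan
#'
#' Per-SNP GLS under the family mixed model, combining the supplied family
#' classes in one regression (see [assemble_design()]). Returns a summary
#' statistic tibble ready for [write_sumstats()] or [moment_correlation()].
#'
#' @param geno A [phased_geno()] object.
#' @param families Family tibble from [build_families()].
#' @param imputed Imputation tibble from [mendelian_impute()] (may be `NULL`
#'   if every family has both parents genotyped).
#' @param pheno Tibble with `individual_id` and `y` (pre-adjusted phenotype).
#' @param model `"no_sib_ige"` or `"with_sib_ige"`.
#' @param vc Optional `fam_varcomps`; fitted on the null model if `NULL`.
#' @return Tibble with one row per SNP: variant metadata, `est_*`/`se_*`
#'   columns, `cov_*` sampling covariances, `beta_pop`, `se_beta_pop`,
#'   `n_eff` (number of probands).
#' @export
family_gwas <- function(geno, families, imputed, pheno,
                        model = c("no_sib_ige", "with_sib_ige"), vc = NULL) {
  model <- match.arg(model)
  v <- geno$variants
  g <- genotypes(geno)
  ymap <- setNames(pheno$y, pheno$individual_id)

  # static per-proband scaffolding
  rows <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families[i, ]
    # proband-only families carry no parental information and would bias the
    # combined regression; they are excluded from the scan
    if (fam$design_class %in% c("PROBAND_ONLY", "NOT_IMPUTABLE")) next
    sibs <- intersect(fam$offspring_ids[[1]][fam$offspring_genotyped[[1]]], geno$ids)
    probands <- sibs[sibs %in% names(ymap)[!is.na(ymap)]]
    for (p in probands) {
      rows[[length(rows) + 1]] <- tibble(
        family_id = fam$family_id, proband = p,
        sib_ids = list(setdiff(sibs, p)),
        father_obs = if (fam$father_genotyped) fam$father_id else NA_character_,
        mother_obs = if (fam$mother_genotyped) fam$mother_id else NA_character_,
        class = fam$design_class)
    }
  }
  scaffold <- bind_rows(rows)
  if (nrow(scaffold) == 0) abort("no phenotyped, genotyped probands")
  yv <- unname(ymap[scaffold$proband])

  if (is.null(vc)) {
    vc <- fit_null_varcomps(yv, scaffold$family_id)
  }

  imp <- pivot_imputed(imputed, v$snp_id)

  # static index vectors so the per-SNP work is pure matrix indexing
  pr_idx <- match(scaffold$proband, geno$ids)
  sib_n <- lengths(scaffold$sib_ids)
  sib1_idx <- vapply(scaffold$sib_ids,
                     function(s) if (length(s) == 1) match(s, geno$ids) else NA_integer_,
                     integer(1))
  multi_sib <- which(sib_n > 1)
  multi_idx <- lapply(scaffold$sib_ids[multi_sib], match, table = geno$ids)
  fa_idx <- match(scaffold$father_obs, geno$ids)
  mo_idx <- match(scaffold$mother_obs, geno$ids)
  impF_row <- if (!is.null(imp$FATHER)) match(scaffold$family_id, rownames(imp$FATHER)) else NULL
  impM_row <- if (!is.null(imp$MOTHER)) match(scaffold$family_id, rownames(imp$MOTHER)) else NULL
  impP_row <- if (!is.null(imp$PAR_SUM)) match(scaffold$family_id, rownames(imp$PAR_SUM)) else NULL
  fetch <- function(m, rows, l) {
    if (is.null(m)) return(rep(NA_real_, nrow(scaffold)))
    out <- rep(NA_real_, nrow(scaffold))
    ok <- !is.na(rows)
    out[ok] <- m[cbind(rows[ok], l)]
    out
  }
  nr <- nrow(scaffold)
  res <- vector("list", nrow(v))
  for (l in seq_len(nrow(v))) {
    gl <- g[, l]
    g_sib <- rep(NA_real_, nr)
    ok <- !is.na(sib1_idx)
    g_sib[ok] <- gl[sib1_idx[ok]]
    for (k in seq_along(multi_sib)) g_sib[multi_sib[k]] <- mean(gl[multi_idx[[k]]])
    g_father <- ifelse(!is.na(fa_idx), gl[fa_idx], fetch(imp$FATHER, impF_row, l))
    g_mother <- ifelse(!is.na(mo_idx), gl[mo_idx], fetch(imp$MOTHER, impM_row, l))
    fd <- list(y = yv, family_id = scaffold$family_id, g = gl[pr_idx],
               g_sib = g_sib, g_father = g_father, g_mother = g_mother,
               g_parsum = fetch(imp$PAR_SUM, impP_row, l))
    des <- assemble_design(fd, model)
    est <- try(estimate_snp_effects(des$y, des$X, des$family_id, vc), silent = TRUE)
    if (inherits(est, "try-error")) next
    pe <- try(population_effect(est), silent = TRUE)
    row <- c(list(chrom = v$chrom[l], snp_id = v$snp_id[l], pos_bp = v$pos_bp[l],
                  allele0 = v$allele0[l], allele1 = v$allele1[l], freq = v$freq[l],
                  n_eff = est$n_individuals),
             est_row(est))
    if (!inherits(pe, "try-error")) {
      row$beta_pop <- pe$beta; row$se_beta_pop <- pe$se
      row$cov_delta_beta <- pe$cov_delta_beta
    }
    res[[l]] <- as_tibble(row)
  }
  bind_rows(res)
}

est_row <- function(est) {
  labs <- names(est$estimates)
  out <- list()
  for (a in labs) {
    out[[paste0("est_", a)]] <- unname(est$estimates[a])
    out[[paste0("se_", a)]] <- sqrt(est$vcov[a, a])
  }
  if (length(labs) > 1) {
    for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
      out[[paste0("cov_", labs[j], "_", labs[i])]] <- est$vcov[labs[j], labs[i]]
    }
  }
  out
}

# long imputation tibble -> per-kind [family x snp] matrices
pivot_imputed <- function(imputed, snp_ids) {
  out <- list(FATHER = NULL, MOTHER = NULL, PAR_SUM = NULL)
  if (is.null(imputed) || nrow(imputed) == 0) return(out)
  for (k in names(out)) {
    sub <- imputed[imputed$kind == k, ]
    if (nrow(sub) == 0) next
    fams <- unique(sub$family_id)
    m <- matrix(NA_real_, length(fams), length(snp_ids),
                dimnames = list(fams, snp_ids))
    m[cbind(match(sub$family_id, fams), match(sub$snp_id, snp_ids))] <- sub$value
    out[[k]] <- m
  }
  out
}

imp_lookup <- function(m, family_id, l) {
  if (is.null(m)) return(rep(NA_real_, length(family_id)))
  idx <- match(family_id, rownames(m))
  ifelse(is.na(idx), NA_real_, m[cbind(idx, l)])
}
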