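# Mendelian imputation of missing parental genotypes: exact conditional
# expectations given observed family genotypes, sibling IBD states and
# (optionally) phase, plus a best-linear-unbiased baseline for comparison.

#' Impute the sum of parental genotypes from a sibling pair
#'
#' Conditional expectation of `g_par = g_p + g_m` given the two siblings'
#' genotypes and their IBD state. In IBD0 all four parental alleles are
#' observed (`g1 + g2`); in IBD2 two are (`g1 + 2f`); in IBD1 three are
#' (`g1 + g2_notshared + f`), with the unphased both-heterozygous fallback
#' `1 + 2f` when the non-shared allele cannot be resolved. Unobserved alleles
#' are imputed by the allele-1 frequency `f`.
#'
#' Genotype pairs inconsistent with the claimed IBD state (e.g. opposite
#' homozygotes in IBD2) are imputed under an IBD0 fallback and flagged in the
#' `"inconsistent"` attribute.
#'
#' @param g1,g2 Sibling genotypes in `{0, 1, 2}` (vectors allowed).
#' @param ibd IBD state per SNP in `{0, 1, 2}`.
#' @param f Allele-1 frequency per SNP.
#' @param g2_notshared Optional allele in `{0, 1}`: the allele of sibling 2
#'   not shared IBD with sibling 1 (resolved from phase); `NA` = unresolved.
#' @return Numeric vector of imputed parental-sum values in `[0, 4]`, with
#'   attributes `n_obs_alleles` (`4 - ibd`) and `inconsistent`.
#' @export
impute_parsum_sibs <- function(g1, g2, ibd, f, g2_notshared = NA) {
  n <- max(length(g1), length(g2), length(ibd), length(f))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n); ibd <- rep_len(ibd, n)
  f <- rep_len(f, n); ns <- rep_len(g2_notshared, n)
  bad <- (ibd == 2 & g1 != g2) | (ibd == 1 & abs(g1 - g2) == 2)
  ibd_eff <- ifelse(bad, 0L, ibd)
  # IBD1: non-shared allele of sibling 2, resolvable from genotypes whenever
  # either sibling is homozygous
  shared <- ifelse(g1 != 1, g1 / 2, ifelse(g2 != 1, g2 / 2, NA))
  ns1 <- ifelse(!is.na(shared), g2 - shared, ns)
  out <- ifelse(ibd_eff == 0, g1 + g2,
         ifelse(ibd_eff == 2, g1 + 2 * f,
         ifelse(!is.na(ns1), g1 + ns1 + f, 1 + 2 * f)))
  structure(out, n_obs_alleles = 4L - as.integer(ibd_eff), inconsistent = bad)
}

#' Resolve non-shared alleles of doubly heterozygous IBD1 SNPs from phase
#'
#' For a pair of individuals sharing one allele IBD, the allele of the second
#' individual not shared with the first is ambiguous when both are
#' heterozygous. With phased haplotypes, the nearest SNP in the same IBD1
#' segment at which one individual is homozygous and the other heterozygous
#' identifies which haplotype carries the shared segment; that haplotype then
#' resolves the target SNP. Equidistant informative SNPs that disagree leave
#' the SNP unresolved.
#'
#' @param hapA Two-row matrix (haplotypes x SNPs) of individual A (e.g.
#'   sibling 1, or the observed parent for parent-offspring pairs).
#' @param hapB Two-row matrix for individual B (sibling 2, or the offspring).
#' @param states Per-SNP IBD state; only IBD1 SNPs are processed (pass all 1s
#'   for a parent-offspring pair, which is IBD1 everywhere by definition).
#' @param pos_cM Map positions of the SNPs.
#' @param info_types `"both"` (siblings: either individual homozygous is
#'   informative) or `"A_hom"` (parent-offspring: only sites where A, the
#'   observed parent, is homozygous are used, because the transmitted gamete
#'   is a recombinant of the parent's two haplotypes and cannot be read off a
#'   single parental haplotype across crossovers).
#' @return Integer vector: for each doubly heterozygous IBD1 SNP the resolved
#'   non-shared allele of individual B, `NA` elsewhere or when unresolvable.
#' @export
resolve_shared_alleles <- function(hapA, hapB, states, pos_cM,
                                   info_types = c("both", "A_hom")) {
  info_types <- match.arg(info_types)
  L <- ncol(hapA)
  stopifnot(ncol(hapB) == L, length(states) == L, length(pos_cM) == L)
  gA <- hapA[1, ] + hapA[2, ]; gB <- hapB[1, ] + hapB[2, ]
  out <- rep(NA_integer_, L)
  r <- rle(states == 1)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    targets <- seg[gA[seg] == 1 & gB[seg] == 1]
    if (length(targets) == 0) next
    # informative SNP types: A homozygous (resolves B's shared haplotype) or
    # B homozygous (resolves A's shared haplotype)
    infoA <- seg[gA[seg] != 1 & gB[seg] == 1]
    infoB <- if (info_types == "both") seg[gB[seg] != 1 & gA[seg] == 1] else integer(0)
    # B's shared haplotype index at infoA sites: haplotype matching A's allele
    hapB_shared <- if (length(infoA)) ifelse(hapB[1, infoA] == gA[infoA] / 2, 1L, 2L) else integer(0)
    # A's shared haplotype index at infoB sites
    hapA_shared <- if (length(infoB)) ifelse(hapA[1, infoB] == gB[infoB] / 2, 1L, 2L) else integer(0)
    info <- c(infoA, infoB)
    if (length(info) == 0) next
    type <- rep(c("A", "B"), c(length(infoA), length(infoB)))
    shared_hap <- c(hapB_shared, hapA_shared)
    o <- order(info)
    info <- info[o]; type <- type[o]; shared_hap <- shared_hap[o]
    for (t in targets) {
      d <- abs(pos_cM[info] - pos_cM[t])
      nearest <- which(d == min(d))
      vals <- vapply(nearest, function(i) {
        if (type[i] == "A") {
          # B's non-shared haplotype allele at the target
          hapB[3L - shared_hap[i], t]
        } else {
          # shared allele value read off A's shared haplotype
          1L - hapA[shared_hap[i], t]
        }
      }, integer(1))
      if (length(unique(vals)) == 1) out[t] <- vals[1]
    }
  }
  out
}

#' Impute a missing parent's genotype from a parent-offspring pair
#'
#' The offspring's allele transmitted by the missing parent, when determined
#' (from genotypes alone, or from phase via `transmitted`), contributes
#' itself; the untransmitted allele is imputed by `f`. When both offspring and
#' observed parent are heterozygous and phase is unresolved, the imputation
#' averages the two possibilities, giving `2f`. Mendelian-inconsistent pairs
#' are imputed as `NA` and flagged.
#'
#' @param g_o Offspring genotype(s).
#' @param g_obs_parent Observed parent genotype(s).
#' @param f Allele-1 frequency.
#' @param transmitted Optional allele in `{0, 1}` transmitted by the missing
#'   parent (resolved from phase); `NA` = unresolved.
#' @return Numeric vector of imputed genotypes in `[0, 2]` with attribute
#'   `inconsistent`.
#' @export
impute_parent_from_parent_offspring <- function(g_o, g_obs_parent, f, transmitted = NA) {
  n <- max(length(g_o), length(g_obs_parent), length(f))
  g_o <- rep_len(g_o, n); gq <- rep_len(g_obs_parent, n)
  f <- rep_len(f, n); tr <- rep_len(transmitted, n)
  bad <- (g_o == 0 & gq == 2) | (g_o == 2 & gq == 0)
  a <- ifelse(g_o == 0, 0,
       ifelse(g_o == 2, 1,
       ifelse(gq == 0, 1, ifelse(gq == 2, 0, tr))))
  out <- ifelse(bad, NA_real_, ifelse(!is.na(a), a + f, 2 * f))
  structure(out, inconsistent = bad)
}

# Exact posterior over parental allele slots and inheritance vectors for one
# nuclear family at one SNP. Parental alleles (p1, p2, m1, m2) have Bernoulli(f)
# priors (conditioned on any observed parental genotype); each sibling draws
# one paternal and one maternal slot uniformly; configurations are constrained
# by the sibling genotypes and any supplied pairwise IBD states.
impute_family_exact <- function(g_sibs, ibd_mat = NULL, f,
                                g_father = NA, g_mother = NA) {
  n <- length(g_sibs)
  stopifnot(n >= 1, n <= 5)
  alleles <- as.matrix(expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1))
  aw <- apply(alleles, 1, function(a) prod(ifelse(a == 1, f, 1 - f)))
  if (!is.na(g_father)) {
    keep <- alleles[, "p1"] + alleles[, "p2"] == g_father
    alleles <- alleles[keep, , drop = FALSE]; aw <- aw[keep]
  }
  if (!is.na(g_mother)) {
    keep <- alleles[, "m1"] + alleles[, "m2"] == g_mother
    alleles <- alleles[keep, , drop = FALSE]; aw <- aw[keep]
  }
  inh <- as.matrix(expand.grid(rep(list(1:2), 2 * n)))  # columns: pat_1..pat_n, mat_1..mat_n
  pat <- inh[, seq_len(n), drop = FALSE]
  mat <- inh[, n + seq_len(n), drop = FALSE]
  ibd_ok <- rep(TRUE, nrow(inh))
  if (!is.null(ibd_mat) && n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- ibd_mat[i, j]
      if (!is.na(s)) {
        ibd_ok <- ibd_ok & ((pat[, i] == pat[, j]) + (mat[, i] == mat[, j])) == s
      }
    }
  }
  pat <- pat[ibd_ok, , drop = FALSE]; mat <- mat[ibd_ok, , drop = FALSE]
  if (nrow(pat) == 0 || nrow(alleles) == 0) {
    return(list(ok = FALSE))
  }
  tot_w <- 0; e_gp <- 0; e_gm <- 0
  for (ia in seq_len(nrow(alleles))) {
    a <- alleles[ia, ]
    pal <- c(a["p1"], a["p2"]); mal <- c(a["m1"], a["m2"])
    g_implied <- matrix(pal[pat], nrow(pat)) + matrix(mal[mat], nrow(mat))
    match_g <- rowSums(g_implied == rep(g_sibs, each = nrow(pat))) == n
    w <- sum(match_g) * aw[ia]
    if (w == 0) next
    tot_w <- tot_w + w
    e_gp <- e_gp + w * sum(pal)
    e_gm <- e_gm + w * sum(mal)
  }
  if (tot_w == 0) return(list(ok = FALSE))
  # distinct parental slots drawn, determined by the IBD-consistent
  # inheritance configurations alone
  nobs_all <- apply(cbind(pat, 2 + mat), 1, function(x) length(unique(x)))
  list(ok = TRUE, gp = e_gp / tot_w, gm = e_gm / tot_w,
       gpar = (e_gp + e_gm) / tot_w, n_obs_alleles = mean(nobs_all))
}

#' Impute the parental-genotype sum from n genotyped siblings
#'
#' Generalizes the sibling-pair imputation: the joint pairwise IBD
#' configuration identifies which distinct parental alleles have been
#' observed; the imputed value is the posterior expectation of
#' `g_p + g_m`, which equals the sum of observed distinct parental alleles
#' plus `f` per unobserved allele (with expectation over transmissions at
#' unresolvable double-heterozygote configurations). On average
#' `4(1 - 2^-n)` parental alleles are observed from `n` siblings. Mutually
#' inconsistent IBD states fall back to a genotype-only posterior and are
#' flagged.
#'
#' @param g_sibs Integer vector of the siblings' genotypes at one SNP.
#' @param ibd_mat n x n matrix of pairwise IBD states (only the upper
#'   triangle is used; `NA` entries are unconstrained).
#' @param f Allele-1 frequency.
#' @return List with `value` (imputed parental sum), `n_obs_alleles` and
#'   `consistent`.
#' @export
impute_parsum_nsibs <- function(g_sibs, ibd_mat, f) {
  res <- impute_family_exact(g_sibs, ibd_mat, f)
  consistent <- res$ok
  if (!consistent) res <- impute_family_exact(g_sibs, NULL, f)
  if (!res$ok) return(list(value = NA_real_, n_obs_alleles = NA_real_, consistent = FALSE))
  list(value = res$gpar, n_obs_alleles = res$n_obs_alleles, consistent = consistent)
}

#' Impute a missing parent from genotyped siblings plus the other parent
#'
#' Uses sibling IBD states together with subtraction of the observed parent's
#' transmissions to determine which of the missing parent's alleles were
#' observed; unobserved alleles are imputed by `f`, and unresolvable
#' transmission ambiguities are averaged over their exact posterior.
#'
#' @inheritParams impute_parsum_nsibs
#' @param g_obs_parent Genotype of the observed parent.
#' @param which_observed `"father"` or `"mother"`: which parent is observed.
#' @return List with `value` (imputed genotype of the missing parent, in
#'   `[0, 2]`) and `consistent`.
#' @export
impute_parent_from_sibs_and_parent <- function(g_sibs, ibd_mat, g_obs_parent, f,
                                               which_observed = c("father", "mother")) {
  which_observed <- match.arg(which_observed)
  res <- if (which_observed == "father") {
    impute_family_exact(g_sibs, ibd_mat, f, g_father = g_obs_parent)
  } else {
    impute_family_exact(g_sibs, ibd_mat, f, g_mother = g_obs_parent)
  }
  consistent <- res$ok
  if (!consistent) {
    res <- if (which_observed == "father") {
      impute_family_exact(g_sibs, NULL, f, g_father = g_obs_parent)
    } else {
      impute_family_exact(g_sibs, NULL, f, g_mother = g_obs_parent)
    }
  }
  if (!res$ok) return(list(value = NA_real_, consistent = FALSE))
  list(value = if (which_observed == "father") res$gm else res$gp,
       consistent = consistent)
}

#' Best linear unbiased imputation baseline
#'
#' The best linear predictor of the missing parental quantity from the
#' observed genotypes under Hardy-Weinberg and Mendelian covariances,
#' computed exactly from the enumerated joint family genotype distribution.
#' For sibling pairs this predicts `g_par` from `(g1, g2)` with R-squared 2/3;
#' for parent-offspring pairs it predicts the missing parent from the
#' offspring and observed parent with coefficients (2/3, -1/3) and R-squared
#' 1/3.
#'
#' @param class `"SIB_PAIRS_NO_PARENTS"` or `"ONE_PARENT_ONE_OFFSPRING"`.
#' @param f Allele-1 frequency.
#' @return List with `coefficients` (named, including `(Intercept)`) and `r2`.
#' @export
linear_impute_baseline <- function(class = c("SIB_PAIRS_NO_PARENTS", "ONE_PARENT_ONE_OFFSPRING"),
                                   f = 0.5) {
  class <- match.arg(class)
  d <- family_joint_dist(f, n_sibs = 2)
  w <- d$prob
  if (class == "SIB_PAIRS_NO_PARENTS") {
    X <- cbind(1, g1 = d$g1, g2 = d$g2)
    y <- d$gp + d$gm
  } else {
    X <- cbind(1, g_offspring = d$g1, g_obs_parent = d$gm)
    y <- d$gp
  }
  beta <- solve(crossprod(X, X * w), crossprod(X, w * y))
  pred <- drop(X %*% beta)
  mu <- sum(w * y)
  r2 <- sum(w * (pred - mu)^2) / sum(w * (y - mu)^2)
  names_out <- c("(Intercept)", colnames(X)[-1])
  list(class = class, coefficients = setNames(drop(beta), names_out), r2 = r2)
}

#' Regression diagnostics of imputed against true parental genotypes
#'
#' Unbiased Mendelian imputation implies the regression coefficient of the
#' true parental genotype on the imputed one is 1 (the covariance between
#' imputed and true equals the variance of the imputed values).
#'
#' @param imputed Numeric vector of imputed values.
#' @param truth Numeric vector of true parental genotypes (same families).
#' @return Tibble with `slope`, `r2` and `n`.
#' @export
imputation_diagnostics <- function(imputed, truth) {
  ok <- complete.cases(imputed, truth)
  imputed <- imputed[ok]; truth <- truth[ok]
  if (var(imputed) == 0) abort("imputed values have zero variance")
  tibble(slope = cov(truth, imputed) / var(imputed),
         r2 = cor(truth, imputed)^2,
         n = length(imputed))
}

#' Impute missing parental genotypes for a set of families
#'
#' Driver over all imputable design classes. Sibling-pair families use the
#' IBD-state formulas (with phase-based resolution of doubly heterozygous
#' IBD1 SNPs when `phased = TRUE`); parent-offspring families use the
#' transmitted-allele formulas (phase resolves doubly heterozygous cases);
#' families with three or more genotyped siblings, or siblings plus one
#' parent, use the exact family posterior.
#'
#' @param geno A [phased_geno()] object.
#' @param families Family tibble from [build_families()].
#' @param ibd Result of [infer_sib_ibd()] (or a compatible list with `paths`),
#'   required for families with two or more genotyped siblings.
#' @param phased Use phased haplotypes to resolve double-heterozygote
#'   ambiguities.
#' @return Tibble with columns `family_id`, `snp_id`, `kind` (`PAR_SUM`,
#'   `FATHER`, `MOTHER`), `value`, `n_obs_alleles`, `phased_used`.
#' @export
mendelian_impute <- function(geno, families, ibd = NULL, phased = TRUE) {
  v <- geno$variants
  g <- genotypes(geno)
  f <- v$freq
  paths <- if (!is.null(ibd)) ibd$paths %||% ibd else NULL
  path_key <- if (!is.null(paths)) {
    vapply(paths, function(p) paste(p$sib1, p$sib2, p$chrom, sep = "\r"), character(1))
  } else character(0)
  chrom_order <- lapply(unique(v$chrom), function(ch) which(v$chrom == ch))
  names(chrom_order) <- unique(v$chrom)

  out <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families[i, ]
    cls <- fam$design_class
    sibs <- fam$offspring_ids[[1]][fam$offspring_genotyped[[1]]]
    sibs <- intersect(sibs, geno$ids)
    res <- NULL
    if (cls == "SIB_PAIRS_NO_PARENTS" && length(sibs) == 2) {
      st <- pair_states(paths, path_key, sibs, chrom_order, length(f))
      ns <- rep(NA_integer_, length(f))
      if (phased) {
        for (ch in names(chrom_order)) {
          idx <- chrom_order[[ch]]
          ns[idx] <- resolve_shared_alleles(
            rbind(geno$h1[sibs[1], idx], geno$h2[sibs[1], idx]),
            rbind(geno$h1[sibs[2], idx], geno$h2[sibs[2], idx]),
            st[idx], v$pos_cM[idx])
        }
      }
      val <- impute_parsum_sibs(g[sibs[1], ], g[sibs[2], ], st, f, ns)
      res <- tibble(snp_id = v$snp_id, kind = "PAR_SUM", value = as.numeric(val),
                    n_obs_alleles = attr(val, "n_obs_alleles"),
                    phased_used = phased & !is.na(ns))
    } else if (cls %in% c("ONE_PARENT_ONE_OFFSPRING") ||
               (cls == "ONE_PARENT_MULTI_SIB" && length(sibs) == 1)) {
      obs_par <- if (fam$father_genotyped) fam$father_id else fam$mother_id
      kind <- if (fam$father_genotyped) "MOTHER" else "FATHER"
      tr <- rep(NA_integer_, length(f))
      if (phased) {
        for (ch in names(chrom_order)) {
          idx <- chrom_order[[ch]]
          tr[idx] <- resolve_shared_alleles(
            rbind(geno$h1[obs_par, idx], geno$h2[obs_par, idx]),
            rbind(geno$h1[sibs[1], idx], geno$h2[sibs[1], idx]),
            rep(1L, length(idx)), v$pos_cM[idx], info_types = "A_hom")
        }
      }
      val <- impute_parent_from_parent_offspring(g[sibs[1], ], g[obs_par, ], f, tr)
      res <- tibble(snp_id = v$snp_id, kind = kind, value = as.numeric(val),
                    n_obs_alleles = 3L,
                    phased_used = phased & !is.na(tr))
    } else if (cls == "SIB_PAIRS_NO_PARENTS" && length(sibs) > 2) {
      st <- lapply(utils::combn(seq_along(sibs), 2, simplify = FALSE), function(pr) {
        pair_states(paths, path_key, sibs[pr], chrom_order, length(f))
      })
      prs <- utils::combn(seq_along(sibs), 2)
      vals <- numeric(length(f)); nobs <- numeric(length(f))
      for (l in seq_along(f)) {
        m <- matrix(NA_integer_, length(sibs), length(sibs))
        for (k in seq_len(ncol(prs))) m[prs[1, k], prs[2, k]] <- st[[k]][l]
        r <- impute_parsum_nsibs(g[sibs, l], m, f[l])
        vals[l] <- r$value; nobs[l] <- r$n_obs_alleles
      }
      res <- tibble(snp_id = v$snp_id, kind = "PAR_SUM", value = vals,
                    n_obs_alleles = nobs, phased_used = FALSE)
    } else if (cls == "ONE_PARENT_MULTI_SIB") {
      obs_par_id <- if (fam$father_genotyped) fam$father_id else fam$mother_id
      which_obs <- if (fam$father_genotyped) "father" else "mother"
      kind <- if (fam$father_genotyped) "MOTHER" else "FATHER"
      prs <- utils::combn(seq_along(sibs), 2)
      st <- lapply(seq_len(ncol(prs)), function(k) {
        pair_states(paths, path_key, sibs[prs[, k]], chrom_order, length(f))
      })
      vals <- numeric(length(f))
      for (l in seq_along(f)) {
        m <- matrix(NA_integer_, length(sibs), length(sibs))
        for (k in seq_len(ncol(prs))) m[prs[1, k], prs[2, k]] <- st[[k]][l]
        r <- impute_parent_from_sibs_and_parent(g[sibs, l], m, g[obs_par_id, l],
                                                f[l], which_obs)
        vals[l] <- r$value
      }
      res <- tibble(snp_id = v$snp_id, kind = kind, value = vals,
                    n_obs_alleles = NA_real_, phased_used = FALSE)
    }
    if (!is.null(res)) {
      res$family_id <- fam$family_id
      out[[length(out) + 1]] <- res
    }
  }
  if (length(out) == 0) {
    return(tibble(family_id = character(0), snp_id = character(0),
                  kind = character(0), value = numeric(0),
                  n_obs_alleles = numeric(0), phased_used = logical(0)))
  }
  bind_rows(out) |> select("family_id", "snp_id", "kind", "value",
                           "n_obs_alleles", "phased_used")
}

pair_states <- function(paths, path_key, sibs, chrom_order, L) {
  st <- rep(NA_integer_, L)
  if (is.null(paths)) abort("IBD paths required for sibling imputation")
  for (ch in names(chrom_order)) {
    k1 <- paste(sibs[1], sibs[2], ch, sep = "\r")
    k2 <- paste(sibs[2], sibs[1], ch, sep = "\r")
    hit <- match(k1, path_key)
    flip <- FALSE
    if (is.na(hit)) { hit <- match(k2, path_key); flip <- TRUE }
    if (is.na(hit)) abort(sprintf("no IBD path for pair %s-%s chr %s", sibs[1], sibs[2], ch))
    st[chrom_order[[ch]]] <- paths[[hit]]$states
  }
  st
}
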