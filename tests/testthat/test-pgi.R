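test_that("PGI scoring follows the weight file and allele orientation", {
  v <- toy_variants(3)
  v$allele0 <- c("A", "A", "A"); v$allele1 <- c("G", "G", "G")
  dos <- matrix(c(0, 1, 2,
                  2, 2, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("i1", "i2"), v$snp_id))
  w0 <- tibble::tibble(snp_id = v$snp_id, effect_allele = "G", weight = 0)
  expect_equal(unname(as.numeric(score_pgi(dos, v, w0))), c(0, 0))
  w1 <- tibble::tibble(snp_id = "s2", effect_allele = "G", weight = 1)
  expect_equal(unname(as.numeric(score_pgi(dos, v, w1))), c(1, 2))
  # effect allele = allele0: dosage flipped to ploidy - g
  wf <- tibble::tibble(snp_id = "s2", effect_allele = "A", weight = 1)
  expect_equal(unname(as.numeric(score_pgi(dos, v, wf))), c(1, 0))
  # imputed parental sums score on the 0..4 scale
  expect_equal(unname(as.numeric(score_pgi(dos * 2, v, wf, ploidy = 4))), c(2, 0))
  # strand-ambiguous SNPs dropped; unmatched majority errors
  va <- v; va$allele0 <- "A"; va$allele1 <- c("T", "G", "G")
  expect_message(score_pgi(dos, va, tibble::tibble(snp_id = v$snp_id,
                                                   effect_allele = c("T", "G", "G"),
                                                   weight = 1)),
                 "ambiguous")
  expect_error(score_pgi(dos, v, tibble::tibble(snp_id = c("zz1", "zz2", "s1"),
                                                effect_allele = "G", weight = 1)),
               "matched")
})

test_that("PGI model recovers direct and parental effects jointly with varcomps", {
  set.seed(31)
  n <- 8000
  pgi_p <- rnorm(n); pgi_m <- rnorm(n)
  pgi_o <- (pgi_p + pgi_m) / 2 + rnorm(n, 0, sqrt(1 / 2))
  y <- 0.3 * pgi_o + 0.15 * (pgi_p + pgi_m) + rnorm(n, 0, 1)
  fit <- fit_pgi_model(y, pgi_o, family_id = seq_len(n),
                       pgi_father = pgi_p, pgi_mother = pgi_m, standardize = FALSE)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$estimates["delta"] - 0.3), 3 * se["delta"])
  expect_lt(abs(fit$estimates["alpha_p"] - 0.15), 3 * se["alpha_p"])
  expect_lt(abs(fit$estimates["alpha_m"] - 0.15), 3 * se["alpha_m"])
  vc <- attr(fit, "varcomps")
  expect_s3_class(vc, "fam_varcomps")
  # null PGI: estimates within 3 SEs of zero
  y0 <- rnorm(n)
  fit0 <- fit_pgi_model(y0, pgi_o, family_id = seq_len(n),
                        pgi_father = pgi_p, pgi_mother = pgi_m)
  expect_true(all(abs(fit0$estimates) < 3 * sqrt(diag(fit0$vcov))))
})

test_that("AM adjustment divides NTCs by the inflation factor", {
  est <- structure(list(
    estimates = c(delta = 0.3, alpha = 0.22),
    vcov = matrix(c(4e-4, 1e-5, 1e-5, 9e-4), 2,
                  dimnames = list(c("delta", "alpha"), c("delta", "alpha"))),
    n_individuals = 10, n_families = 10), class = "effect_estimate")
  # r_am = 0: identity
  same <- adjust_ntc_for_am(est, 0)
  expect_equal(same$estimates, est$estimates)
  # r_am = 0.2: divide by 1.2/1.1
  adj <- adjust_ntc_for_am(est, 0.2)
  f <- 1.2 / 1.1
  expect_equal(unname(adj$estimates["alpha"]), 0.22 / f)
  expect_equal(unname(adj$estimates["delta"]), 0.3)
  expect_equal(adj$vcov["alpha", "alpha"], 9e-4 / f^2)
  expect_error(adjust_ntc_for_am(est, 1.2), "r_am")
  expect_warning(out <- adjust_ntc_for_am(est, 0.2, "ONE_PARENT_ONE_OFFSPRING"),
                 "sibling-pair")
  expect_equal(out$estimates, est$estimates)
  expect_error(estimate_r_am(c(1, 2), c(1, 2)), "parent pairs")
})

test_that("imputed parental PGIs under AM inflate NTCs by (1+r)/(1+r/2)", {
  sim <- run_simulation(sim_config(n_families = 2000, n_snps = 500, n_chr = 2,
                                   map_length_cM = 60, h2_direct = 0.3,
                                   parental_ige_share = 0.15, ige_cor = 1,
                                   am_target = 0.6, n_generations = 6), seed = 32)
  g <- genotypes(sim$geno); v <- sim$geno$variants
  w <- tibble::tibble(snp_id = v$snp_id, effect_allele = v$allele1,
                      weight = sim$truth$delta)
  pgi <- score_pgi(g, v, w); names(pgi) <- rownames(g)
  ped <- sim$pedigree
  off <- ped[!is.na(ped$father_id), ]
  fit_obs <- fit_pgi_model(off$phenotype, pgi[off$individual_id], family_id = off$fid,
                           pgi_father = pgi[off$father_id],
                           pgi_mother = pgi[off$mother_id])
  fams <- build_families(ped, off$individual_id)
  imp <- mendelian_impute(sim$geno, fams, true_ibd_paths(sim), phased = TRUE)
  fid <- unique(imp$family_id)
  D <- matrix(imp$value, nrow = length(fid), byrow = TRUE,
              dimnames = list(fid, v$snp_id))
  pgi_par <- score_pgi(D, v, w, ploidy = 4)
  fam_key <- paste(off$father_id, off$mother_id, sep = "_")
  fit_imp <- fit_pgi_model(off$phenotype, pgi[off$individual_id], family_id = off$fid,
                           pgi_parsum = pgi_par[match(fam_key, fid)])
  r_am <- estimate_r_am(pgi[unique(off$father_id)], pgi[unique(off$mother_id)])
  expect_gt(r_am, 0.1)
  factor <- (1 + r_am) / (1 + r_am / 2)
  alpha_obs <- mean(fit_obs$estimates[c("alpha_p", "alpha_m")])
  ratio <- unname(fit_imp$estimates["alpha"]) / alpha_obs
  expect_equal(ratio, factor, tolerance = 0.09)
  adj <- adjust_ntc_for_am(fit_imp, r_am)
  expect_equal(unname(adj$estimates["alpha"]) / alpha_obs, 1, tolerance = 0.09)
  # the direct effect is not inflated by imputation under AM
  expect_equal(unname(fit_imp$estimates["delta"] / fit_obs$estimates["delta"]),
               1, tolerance = 0.06)
})
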