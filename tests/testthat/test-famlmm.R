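test_that("null-model variance components match lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(21)
  n <- 1500
  fam <- rep(seq_len(n), each = 2)
  y <- rnorm(n, 0, sqrt(0.3))[fam] + rnorm(2 * n, 0, sqrt(0.7))
  vc <- fit_null_varcomps(y, fam)
  lf <- lme4::lmer(y ~ 1 + (1 | fam), REML = FALSE)
  expect_equal(vc$sigma2_F, as.numeric(lme4::VarCorr(lf)$fam), tolerance = 1e-4)
  expect_equal(vc$sigma2_e, stats::sigma(lf)^2, tolerance = 1e-4)
  expect_equal(vc$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
})

test_that("variance components handle degenerate family structures", {
  set.seed(22)
  # independent phenotypes -> sigma2_F ~ 0
  y <- rnorm(4000)
  vc0 <- fit_null_varcomps(y, rep(1:2000, each = 2))
  expect_lt(vc0$r, 0.05)
  # phenotype duplicated within pairs -> r at the optimizer bound
  yd <- rep(rnorm(500), each = 2)
  vc1 <- fit_null_varcomps(yd, rep(1:500, each = 2))
  expect_gt(vc1$r, 0.95)
  expect_error(fit_null_varcomps(c(1, NA, 3), c(1, 1, 2)), "non-finite")
  expect_warning(fit_null_varcomps(rnorm(5), 1:5), "sigma2_F set to 0")
})

test_that("GLS with identity covariance equals ordinary least squares", {
  set.seed(23)
  n <- 400
  X <- cbind(delta = rbinom(n, 2, 0.3), alpha_p = rbinom(n, 2, 0.3))
  y <- 0.2 * X[, 1] + rnorm(n)
  fit <- estimate_snp_effects(y, X, seq_len(n), list(sigma2_F = 0, sigma2_e = 1))
  ols <- lm(y ~ X)
  expect_equal(unname(fit$estimates), unname(coef(ols)[-1]), tolerance = 1e-10)
  expect_error(estimate_snp_effects(y, cbind(a = X[, 1], b = X[, 1]),
                                    seq_len(n), list(sigma2_F = 0, sigma2_e = 1)),
               "rank-deficient")
  expect_error(estimate_snp_effects(y, cbind(a = rep(1, n)), seq_len(n),
                                    list(sigma2_F = 0, sigma2_e = 1)), "monomorphic")
})

test_that("trio regression recovers simulated effects within 3 SEs", {
  set.seed(24)
  d <- simulate_snp_families(20000, 0.3, delta = 0.1, alpha_p = 0.05, alpha_m = 0)
  fit <- estimate_snp_effects(d$y1, cbind(delta = d$g1, alpha_p = d$gp, alpha_m = d$gm),
                              d$family_id, list(sigma2_F = 0, sigma2_e = 1))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$estimates["delta"] - 0.1), 3 * se["delta"])
  expect_lt(abs(fit$estimates["alpha_p"] - 0.05), 3 * se["alpha_p"])
  expect_lt(abs(fit$estimates["alpha_m"]), 3 * se["alpha_m"])
})

test_that("sibling-pair model separates delta from eta_s", {
  set.seed(25)
  d <- simulate_snp_families(20000, 0.3, delta = 0.1, alpha_p = 0.04,
                             alpha_m = 0.02, eta_s = 0.05, r = 0.2)
  vc <- list(sigma2_F = 0.2, sigma2_e = 0.8)
  imp <- impute_parsum_sibs(d$g1, d$g2, d$ibd, 0.3, d$ns2)
  fit <- estimate_snp_effects(
    c(d$y1, d$y2),
    cbind(delta = c(d$g1, d$g2), eta_s = c(d$g2, d$g1),
          alpha_par = rep(as.numeric(imp), 2)),
    c(d$family_id, d$family_id), vc)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$estimates["delta"] - 0.1), 3 * se["delta"])
  expect_lt(abs(fit$estimates["eta_s"] - 0.05), 3 * se["eta_s"])
  # the generative parental coefficients are the sibling-adjusted NTCs
  # (alpha_p - eta_s/2 in the single-proband parametrization), so the
  # parental-sum column's expected coefficient is their average, 0.03
  expect_lt(abs(fit$estimates["alpha_par"] - 0.03), 3 * se["alpha_par"])
})

test_that("population effect combines estimates per its definition", {
  mk <- function(labels, est, vc = diag(length(labels))) {
    dimnames(vc) <- list(labels, labels)
    structure(list(estimates = setNames(est, labels), vcov = vc,
                   n_individuals = 10, n_families = 10), class = "effect_estimate")
  }
  pe <- population_effect(mk(c("delta", "alpha_p", "alpha_m"), c(0.10, 0.05, 0.03)))
  expect_equal(pe$beta, 0.14)
  expect_equal(pe$se, sqrt(1 + 0.25 + 0.25))
  pe2 <- population_effect(mk(c("delta", "alpha"), c(0.10, 0.04)))
  expect_equal(pe2$beta, 0.14)
  pe3 <- population_effect(mk(c("delta", "eta_s", "alpha_par"), c(0.10, 0.02, 0.03)))
  expect_equal(pe3$beta, 0.10 + 0.03 + 0.01)
  expect_error(population_effect(mk("delta", 0.1)), "NTC")
})

test_that("sibling-difference regression estimates delta - eta_s", {
  set.seed(26)
  d <- simulate_snp_families(20000, 0.3, delta = 0.1, eta_s = 0.05)
  sd_est <- sibdiff_estimate(d$y1, d$y2, d$g1, d$g2)
  expect_lt(abs(sd_est$estimate - 0.05), 3 * sd_est$se)
  expect_error(sibdiff_estimate(d$y1, d$y2, d$g1, d$g1), "undefined")
})

test_that("robust split estimator reduces to a single GLS with one group", {
  set.seed(27)
  d <- simulate_snp_families(4000, 0.3, delta = 0.1)
  imp <- as.numeric(impute_parsum_sibs(d$g1, d$g2, d$ibd, 0.3, d$ns2))
  vc <- list(sigma2_F = 0, sigma2_e = 1)
  keep <- d$ibd == 1
  single <- robust_split_estimate(d$y1[keep], d$g1[keep], imp[keep],
                                  d$family_id[keep], rep(3, sum(keep)), vc)
  ref <- estimate_snp_effects(d$y1[keep],
                              cbind(delta = d$g1[keep], alpha_par = imp[keep]),
                              d$family_id[keep], vc)
  expect_equal(single$delta, unname(ref$estimates["delta"]), tolerance = 1e-10)
  expect_equal(single$n_groups, 1L)
  # undersized groups are merged with a warning
  expect_warning(
    robust_split_estimate(d$y1, d$g1, imp, d$family_id,
                          ifelse(seq_len(4000) <= 10, 4, 3), vc, min_group = 30),
    "merging")
})

test_that("design assembly maps family classes to their regression columns", {
  base <- tibble::tibble(y = rnorm(8), family_id = rep(1:4, 2),
                         g = rbinom(8, 2, 0.5))
  # quad: proband + sib + both parents
  quad <- dplyr::mutate(base, g_sib = rbinom(8, 2, 0.5),
                        g_father = rbinom(8, 2, 0.5), g_mother = rbinom(8, 2, 0.5))
  expect_equal(assemble_design(quad, "with_sib_ige")$labels,
               c("delta", "eta_s", "alpha_p", "alpha_m"))
  # mother-child pair: observed mother, imputed father
  mc <- dplyr::mutate(base, g_father = runif(8, 0, 2), g_mother = rbinom(8, 2, 0.5))
  expect_equal(assemble_design(mc, "no_sib_ige")$labels,
               c("delta", "alpha_p", "alpha_m"))
  # sibling pairs: imputed parental sum only
  sib <- dplyr::mutate(base, g_parsum = runif(8, 0, 4))
  expect_equal(assemble_design(sib, "no_sib_ige")$labels, c("delta", "alpha"))
  expect_equal(assemble_design(dplyr::mutate(sib, g_sib = rbinom(8, 2, 0.5)),
                               "with_sib_ige")$labels,
               c("delta", "eta_s", "alpha_par"))
  # centered columns
  des <- assemble_design(sib, "no_sib_ige")
  expect_equal(mean(des$X[, "delta"]), 0, tolerance = 1e-12)
})

test_that("family_gwas produces consistent summary rows on a small simulation", {
  sim <- run_simulation(sim_config(n_families = 200, n_snps = 40,
                                   map_length_cM = 30, h2_direct = 0.4), seed = 28)
  ped <- sim$pedigree
  offspring <- ped$individual_id[!is.na(ped$father_id)]
  fams <- build_families(ped, offspring)
  imp <- mendelian_impute(sim$geno, fams, true_ibd_paths(sim), phased = TRUE)
  ss <- family_gwas(sim$geno, fams, imp, sim$phenotype, model = "no_sib_ige")
  expect_equal(nrow(ss), 40L)
  expect_equal(ss$beta_pop, ss$est_delta + ss$est_alpha, tolerance = 1e-10)
  expect_true(all(ss$se_delta > 0))
  # round-trip through the summary-statistic writer preserves beta_pop
  path <- tempfile()
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$beta_pop, signif(ss$beta_pop, 6), tolerance = 1e-5)
})
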