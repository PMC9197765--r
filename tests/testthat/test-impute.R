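test_that("sibling-pair parental-sum formulas match their conditional expectations", {
  expect_equal(as.numeric(impute_parsum_sibs(1, 2, 0, 0.5)), 3)
  expect_equal(as.numeric(impute_parsum_sibs(1, 1, 2, 0.5)), 2)
  expect_equal(as.numeric(impute_parsum_sibs(1, 1, 1, 0.25)), 1.5)          # unresolved double het
  expect_equal(as.numeric(impute_parsum_sibs(1, 1, 1, 0.2, g2_notshared = 1)), 2.2)
  # IBD-inconsistent genotypes fall back to IBD0 and are flagged
  v <- impute_parsum_sibs(0, 2, 2, 0.5)
  expect_true(attr(v, "inconsistent"))
  expect_equal(as.numeric(v), 2)
  expect_equal(attr(impute_parsum_sibs(c(1, 1), c(2, 1), c(0, 1), 0.5), "n_obs_alleles"),
               c(4L, 3L))
})

test_that("parent-offspring imputation handles forced, ambiguous and impossible cases", {
  expect_equal(as.numeric(impute_parent_from_parent_offspring(1, 1, 0.2)), 0.4)
  expect_equal(as.numeric(impute_parent_from_parent_offspring(0, 1, 0.2)), 0.2)
  expect_equal(as.numeric(impute_parent_from_parent_offspring(1, 0, 0.2)), 1.2)
  expect_equal(as.numeric(impute_parent_from_parent_offspring(1, 1, 0.2, transmitted = 1)), 1.2)
  bad <- impute_parent_from_parent_offspring(2, 0, 0.2)
  expect_true(is.na(as.numeric(bad)) && attr(bad, "inconsistent"))
})

test_that("exact R2 and unbiasedness: sib pairs 3/4 (phased) vs 2/3 baseline, PO 1/2 vs 1/3", {
  for (f in c(0.1, 0.3, 0.5)) {
    sib_ph <- r2_exact_sib(f, phased = TRUE)
    sib_un <- r2_exact_sib(f, phased = FALSE)
    po_ph <- r2_exact_po(f, phased = TRUE)
    po_un <- r2_exact_po(f, phased = FALSE)
    expect_equal(unname(sib_ph["r2"]), 3 / 4, tolerance = 1e-10)
    expect_equal(unname(sib_ph["slope"]), 1, tolerance = 1e-10)
    expect_equal(unname(po_ph["r2"]), 1 / 2, tolerance = 1e-10)
    expect_equal(unname(po_ph["slope"]), 1, tolerance = 1e-10)
    expect_equal(unname(sib_un["slope"]), 1, tolerance = 1e-10)
    expect_equal(unname(po_un["slope"]), 1, tolerance = 1e-10)
    # phased >= unphased >= best linear baseline
    expect_gte(sib_ph["r2"], sib_un["r2"])
    expect_gte(sib_un["r2"], linear_impute_baseline("SIB_PAIRS_NO_PARENTS", f)$r2 - 1e-12)
    expect_gte(po_un["r2"], linear_impute_baseline("ONE_PARENT_ONE_OFFSPRING", f)$r2 - 1e-12)
  }
  expect_equal(linear_impute_baseline("SIB_PAIRS_NO_PARENTS", 0.3)$r2, 2 / 3, tolerance = 1e-10)
  b <- linear_impute_baseline("ONE_PARENT_ONE_OFFSPRING", 0.3)
  expect_equal(b$r2, 1 / 3, tolerance = 1e-10)
  expect_equal(unname(b$coefficients[c("g_offspring", "g_obs_parent")]),
               c(2 / 3, -1 / 3), tolerance = 1e-10)
})

test_that("unphased sib-pair R2 approaches the phased value at extreme frequencies", {
  gap <- sapply(c(0.4, 0.1, 0.01),
                function(f) r2_exact_sib(f, TRUE)["r2"] - r2_exact_sib(f, FALSE)["r2"])
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.002)
})

test_that("per-IBD-state R2 contributions are 1, 3/4 and 1/2", {
  f <- 0.3
  d <- sibpair_enumeration(f)
  gh <- impute_parsum_sibs(d$g1, d$g2, d$ibd, f, d$ns2)
  for (k in 0:2) {
    i <- d$ibd == k
    w <- d$w[i] / sum(d$w[i])
    r2_k <- wvar(gh[i], w) / wvar(d$gpar[i], w)
    expect_equal(r2_k, c(1, 3 / 4, 1 / 2)[k + 1], tolerance = 1e-10)
  }
})

test_that("phase resolves the shared allele through informative neighbours", {
  # two sibs, IBD1 throughout; neighbour SNP 1: sib A hom 0 / sib B het with
  # haplotype 1 carrying the shared 0 allele; target SNP 2: both het, B's
  # shared haplotype 1 carries allele 1 -> non-shared allele is 0
  hapA <- rbind(c(0L, 1L), c(0L, 0L))
  hapB <- rbind(c(0L, 1L), c(1L, 0L))
  ns <- resolve_shared_alleles(hapA, hapB, states = c(1L, 1L), pos_cM = c(0, 0.1))
  expect_equal(ns[2], 0L)
  # no informative neighbour in the segment -> unresolved
  hapA2 <- rbind(c(1L, 1L), c(0L, 0L))
  hapB2 <- rbind(c(1L, 1L), c(0L, 0L))
  expect_true(all(is.na(resolve_shared_alleles(hapA2, hapB2, c(1L, 1L), c(0, 0.1)))))
  # sites outside IBD1 or not doubly heterozygous stay NA
  expect_true(is.na(ns[1]))
})

test_that("the n-sibling engine agrees with the pair formulas at n = 2", {
  f <- 0.3
  d <- sibpair_enumeration(f)
  combos <- unique(d[, c("g1", "g2", "ibd")])
  for (i in seq_len(nrow(combos))) {
    m <- matrix(NA_integer_, 2, 2); m[1, 2] <- combos$ibd[i]
    eng <- impute_parsum_nsibs(c(combos$g1[i], combos$g2[i]), m, f)
    pair <- as.numeric(impute_parsum_sibs(combos$g1[i], combos$g2[i], combos$ibd[i], f))
    expect_equal(eng$value, pair, tolerance = 1e-10)
    expect_equal(eng$n_obs_alleles, 4 - combos$ibd[i])
  }
})

test_that("observed parental alleles average 4(1 - 2^-n) over simulated meioses", {
  set.seed(11)
  for (n in c(3, 4)) {
    nobs <- replicate(400, {
      tp <- sample(1:2, n, TRUE); tm <- sample(1:2, n, TRUE)
      length(unique(tp)) + length(unique(tm))
    })
    expect_equal(mean(nobs), 4 * (1 - 2^-n),
                 tolerance = 4 * sd(nobs) / sqrt(length(nobs)))
  }
  # n = 2 closed form: IBD distribution (1/4, 1/2, 1/4) -> mean 3 exactly
  expect_equal(sum(c(4, 3, 2) * c(0.25, 0.5, 0.25)), 3)
})

test_that("imputing a parent from siblings plus the other parent is exact and unbiased", {
  f <- 0.3
  d <- sibpair_enumeration(f)
  vals <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    m <- matrix(NA_integer_, 2, 2); m[1, 2] <- d$ibd[i]
    vals[i] <- impute_parent_from_sibs_and_parent(
      c(d$g1[i], d$g2[i]), m, d$m1[i] + d$m2[i], f, "mother")$value
  }
  gp <- d$p1 + d$p2
  # unbiased: E[ghat] = E[gp] and cov(ghat, gp) = var(ghat)
  expect_equal(sum(d$w * vals), sum(d$w * gp), tolerance = 1e-10)
  expect_equal(wcov(vals, gp, d$w), wvar(vals, d$w), tolerance = 1e-10)
  expect_true(all(vals >= 0 & vals <= 2))
  # sibs in IBD0 with all transmissions resolved: integer imputation
  # (mother homozygous 0, sib genotypes 1 and 0 -> father alleles {1, 0})
  m0 <- matrix(NA_integer_, 2, 2); m0[1, 2] <- 0L
  expect_equal(impute_parent_from_sibs_and_parent(c(1, 0), m0, 0, f, "mother")$value, 1)
})

test_that("unbiasedness holds over the exact joint distribution for every class", {
  for (f in c(0.1, 0.3, 0.5)) {
    d <- sibpair_enumeration(f)
    for (phased in c(TRUE, FALSE)) {
      gh <- impute_parsum_sibs(d$g1, d$g2, d$ibd, f, if (phased) d$ns2 else NA)
      expect_equal(sum(d$w * gh), sum(d$w * d$gpar), tolerance = 1e-10)
      expect_equal(wcov(gh, d$gpar, d$w), wvar(gh, d$w), tolerance = 1e-10)
    }
    po <- po_enumeration(f)
    for (phased in c(TRUE, FALSE)) {
      gh <- impute_parent_from_parent_offspring(po$go, po$gm, f,
                                                transmitted = if (phased) po$at else NA)
      expect_equal(sum(po$w * gh), sum(po$w * po$gp), tolerance = 1e-10)
      expect_equal(wcov(gh, po$gp, po$w), wvar(gh, po$w), tolerance = 1e-10)
    }
  }
})

test_that("imputation diagnostics report slope and R2", {
  x <- c(0, 1, 2, 1, 0, 2)
  expect_equal(imputation_diagnostics(x, x)$slope, 1)
  expect_equal(imputation_diagnostics(x, x)$r2, 1)
  expect_error(imputation_diagnostics(rep(1, 5), c(0, 1, 2, 1, 0)), "zero variance")
})

test_that("the family imputation driver is unbiased on simulated families", {
  sim <- run_simulation(sim_config(n_families = 250, n_snps = 400,
                                   map_length_cM = 60, h2_direct = 0.4), seed = 12)
  ped <- sim$pedigree
  offspring <- ped$individual_id[!is.na(ped$father_id)]
  fams <- build_families(ped, offspring)
  ibd <- true_ibd_paths(sim)
  g <- genotypes(sim$geno)
  for (phased in c(TRUE, FALSE)) {
    imp <- mendelian_impute(sim$geno, fams, ibd, phased = phased)
    m <- match(imp$family_id, fams$family_id)
    truth <- g[cbind(match(fams$father_id[m], rownames(g)),
                     match(imp$snp_id, colnames(g)))] +
      g[cbind(match(fams$mother_id[m], rownames(g)), match(imp$snp_id, colnames(g)))]
    dd <- imputation_diagnostics(imp$value, truth)
    expect_equal(dd$slope, 1, tolerance = 0.02)
    if (phased) expect_equal(mean(imp$n_obs_alleles), 3, tolerance = 0.1)
  }
  # one-parent families impute the missing parent with slope ~ 1
  fams_po <- build_families(ped, c(offspring[grepl("_o1$", offspring)],
                                   unique(ped$individual_id[grepl("_m$", ped$individual_id)])))
  expect_true(all(fams_po$design_class == "ONE_PARENT_ONE_OFFSPRING"))
  imp_po <- mendelian_impute(sim$geno, fams_po, NULL, phased = TRUE)
  m <- match(imp_po$family_id, fams_po$family_id)
  truth_p <- g[cbind(match(fams_po$father_id[m], rownames(g)),
                     match(imp_po$snp_id, colnames(g)))]
  dpo <- imputation_diagnostics(imp_po$value, truth_p)
  expect_equal(dpo$slope, 1, tolerance = 0.03)
  expect_gt(dpo$r2, 0.4)
})
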