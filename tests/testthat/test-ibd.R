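# enumeration oracle for the emission distribution: parental alleles and
# transmissions conditional on the IBD state
emission_oracle <- function(f, k) {
  d <- sibpair_enumeration(f)
  d <- d[d$ibd == k, ]
  out <- matrix(0, 3, 3)
  for (i in seq_len(nrow(d))) {
    out[d$g1[i] + 1, d$g2[i] + 1] <- out[d$g1[i] + 1, d$g2[i] + 1] + d$w[i]
  }
  out / sum(out)
}

test_that("emission probabilities match the enumeration oracle", {
  for (f in c(0.2, 0.5)) {
    for (k in 0:2) {
      O <- emission_oracle(f, k)
      M <- matrix(0, 3, 3)
      for (a in 0:2) for (b in 0:2) {
        M[a + 1, b + 1] <- exp(ibd_emission_logprob(a, b, f, gamma = 0))[k + 1]
      }
      expect_equal(M, O, tolerance = 1e-12)
    }
  }
})

test_that("emission error model and missing-genotype handling behave", {
  # gamma = 0: opposite homozygotes impossible in IBD2
  expect_equal(exp(ibd_emission_logprob(0, 2, 0.5, 0))[3], 0)
  expect_equal(exp(ibd_emission_logprob(0, 0, 0.5, 0))[3], 0.25)
  # gamma > 0: full support
  expect_true(all(exp(ibd_emission_logprob(0, 2, 0.5, 1e-4)) > 0))
  # missing genotype marginalized: emission constant across states
  e <- exp(ibd_emission_logprob(NA, 1, 0.3, 0))
  expect_equal(e[1], e[2])
  expect_equal(e[2], e[3])
})

test_that("vectorized emissions agree with per-SNP scalar calls", {
  set.seed(3)
  g1 <- sample(0:2, 50, TRUE); g2 <- sample(0:2, 50, TRUE)
  f <- runif(50, 0.05, 0.95)
  vec <- ibd_emission_logprob(g1, g2, f, 1e-4)
  for (i in c(1, 17, 50)) {
    expect_equal(vec[i, ], ibd_emission_logprob(g1[i], g2[i], f[i], 1e-4)[1, ])
  }
})

test_that("transition matrix has the right limits and symmetry", {
  expect_equal(ibd_transition_matrix(0), diag(3), ignore_attr = TRUE)
  far <- ibd_transition_matrix(1e6)
  for (i in 1:3) expect_equal(unname(far[i, ]), c(0.25, 0.5, 0.25), tolerance = 1e-9)
  for (d in c(0.1, 1, 10)) {
    Tm <- ibd_transition_matrix(d)
    expect_equal(unname(rowSums(Tm)), c(1, 1, 1))
    expect_equal(Tm[1, 3], Tm[3, 1])
  }
})

test_that("segment smoothing removes short runs with agreeing flanks only", {
  v <- toy_variants(5, cm_span = 4)
  mkpath <- function(states) {
    structure(list(sib1 = "a", sib2 = "b", chrom = "1",
                   states = states, posterior = NULL,
                   variants = v[, c("snp_id", "pos_bp", "pos_cM")]),
              class = "ibd_path")
  }
  p <- mkpath(c(1L, 1L, 2L, 1L, 1L))
  p$segments <- famimpute:::states_to_segments(p)
  expect_equal(smooth_segments(p, 0.5)$states, rep(1L, 5))
  # flanks disagree -> unchanged
  p2 <- mkpath(c(0L, 0L, 2L, 1L, 1L))
  p2$segments <- famimpute:::states_to_segments(p2)
  expect_equal(smooth_segments(p2, 0.5)$states, c(0L, 0L, 2L, 1L, 1L))
  # m = 0 -> identity
  expect_equal(smooth_segments(p, 0)$states, p$states)
})

test_that("decoding recovers block-constant IBD paths", {
  set.seed(4)
  L <- 900
  f <- runif(L, 0.2, 0.8)
  p1 <- rbinom(L, 1, f); p2 <- rbinom(L, 1, f)
  m1 <- rbinom(L, 1, f); m2 <- rbinom(L, 1, f)
  truth <- rep(c(2L, 0L, 1L), each = 300)
  g1 <- p1 + m1
  g2 <- ifelse(truth == 2, p1 + m1, ifelse(truth == 0, p2 + m2, p1 + m2))
  v <- toy_variants(L, cm_span = 90)
  v$freq <- f
  path <- infer_ibd(g1, g2, v)
  expect_gt(mean(path$states == truth), 0.95)
  # posteriors sum to one
  expect_equal(unname(rowSums(path$posterior)), rep(1, L), tolerance = 1e-9)
  # Viterbi beats random perturbations of its own path
  emis <- ibd_emission_logprob(g1, g2, f, 1e-4)
  pathll <- function(s) {
    ll <- log(c(0.25, 0.5, 0.25))[s[1] + 1] + emis[1, s[1] + 1]
    for (t in 2:L) {
      Tm <- log(ibd_transition_matrix(v$pos_cM[t] - v$pos_cM[t - 1]))
      ll <- ll + Tm[s[t - 1] + 1, s[t] + 1] + emis[t, s[t] + 1]
    }
    ll
  }
  ll_vit <- pathll(path$states)
  for (rep in 1:5) {
    pert <- path$states
    i <- sample.int(L, 10)
    pert[i] <- (pert[i] + sample(1:2, 10, TRUE)) %% 3L
    expect_lte(pathll(pert), ll_vit + 1e-9)
  }
})

test_that("identical siblings decode as IBD2 and summaries weight by length", {
  L <- 120
  v <- toy_variants(L, cm_span = 30, f = 0.5)
  set.seed(5)
  h <- rbinom(L, 1, 0.5); h2 <- rbinom(L, 1, 0.5)
  path <- infer_ibd(h + h2, h + h2, v)
  expect_true(all(path$states == 2L))
  s <- ibd_summary(list(path))
  expect_equal(s$fraction, c(0, 0, 1))
})

test_that("constant LD scores leave the decoded path unchanged", {
  set.seed(6)
  L <- 300
  f <- runif(L, 0.2, 0.8)
  g1 <- rbinom(L, 2, f); g2 <- rbinom(L, 2, f)
  v <- toy_variants(L, cm_span = 40); v$freq <- f
  v$ld_score <- 1
  p1 <- infer_ibd(g1, g2, v)
  v$ld_score <- 2.5
  p2 <- infer_ibd(g1, g2, v)
  expect_equal(p1$states, p2$states)
})

test_that("accuracy does not improve when genotyping error increases", {
  sim <- run_simulation(sim_config(n_families = 30, n_snps = 1200,
                                   map_length_cM = 40, h2_direct = 0.4), seed = 9)
  acc <- sapply(c(0, 0.02), function(rate) {
    set.seed(10)
    geno <- if (rate > 0) add_genotype_errors(sim$geno, rate) else sim$geno
    res <- suppressWarnings(infer_sib_ibd(geno, sim$families))
    st <- do.call(rbind, lapply(res$paths, function(p) p$states))
    fams <- vapply(res$paths, function(p) sub("_o1$", "", p$sib1), character(1))
    mean(st == sim$ibd_true[fams, ])
  })
  expect_gte(acc[1], acc[2])
})
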