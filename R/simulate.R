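# Forward-in-time nuclear-family simulator: phased genotypes, pedigrees, true
# IBD from recorded crossovers, and phenotypes under configurable direct
# effects, parental/sibling indirect effects, vertical transmission,
# assortative mating, stratification and ascertainment.

#' Simulation configuration
#'
#' Defaults describe a neutral random-mating population of independent
#' nuclear families: SNPs in linkage equilibrium at founding with frequencies
#' Uniform(0.05, 0.5) on a uniform genetic map, a single generation, half the
#' phenotypic variance from direct effects and the rest from independent
#' Gaussian noise.
#'
#' @param n_families Number of final-generation families (couples, each with
#'   two offspring).
#' @param n_snps Total number of SNPs.
#' @param n_chr Number of chromosomes (SNPs split evenly).
#' @param map_length_cM Map length per chromosome.
#' @param freq_range Founder allele-frequency range (uniform draw).
#' @param n_generations Number of generations simulated forward.
#' @param h2_direct Phenotypic variance share of direct effects (founder
#'   generation scaling).
#' @param parental_ige_share Variance share of parental indirect effects.
#' @param ige_cor Correlation between per-SNP direct and parental indirect
#'   effects.
#' @param eta_s_share Variance share of the sibling indirect effect.
#' @param vt Vertical-transmission coefficient on each parent's phenotype.
#' @param am_target Target spousal phenotype correlation (0 = random mating).
#' @param n_demes Number of demes (subpopulations, endogamous).
#' @param fst Balding-Nichols divergence of founder deme frequencies.
#' @param deme_offset_sd Standard deviation of fixed deme phenotype offsets.
#' @param ascertainment `NULL`, or `list(k, c0)`: families retained with
#'   probability `plogis(k * (pct - c0))` where `pct` is the percentile of
#'   the offspring mean phenotype.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 500, n_snps = 600, n_chr = 1,
                       map_length_cM = 100, freq_range = c(0.05, 0.5),
                       n_generations = 1, h2_direct = 0.5,
                       parental_ige_share = 0, ige_cor = 0.5,
                       eta_s_share = 0, vt = 0, am_target = 0,
                       n_demes = 1, fst = 0, deme_offset_sd = 0,
                       ascertainment = NULL) {
  cfg <- as.list(environment())
  shares <- h2_direct + parental_ige_share + eta_s_share
  stopifnot(shares <= 1, h2_direct >= 0, parental_ige_share >= 0,
            eta_s_share >= 0, n_demes >= 1, fst >= 0, am_target < 1,
            n_families %% n_demes == 0)
  structure(cfg, class = "sim_config")
}

#' Simulate one meiosis
#'
#' Poisson crossovers on the cM map (Haldane model, no interference); the
#' gamete records which parental haplotype each locus came from.
#'
#' @param h1,h2 Parent's haplotype vectors over one chromosome.
#' @param pos_cM Map positions of the SNPs.
#' @return List with `gamete` (allele vector), `origin` (0/1 parental
#'   haplotype per SNP) and `crossovers` (cM positions).
#' @export
simulate_meiosis <- function(h1, h2, pos_cM) {
  span <- max(pos_cM) - min(pos_cM)
  nx <- rpois(1, span / 100)
  xo <- sort(runif(nx, min(pos_cM), max(pos_cM)))
  start <- rbinom(1, 1, 0.5)
  origin <- (start + findInterval(pos_cM, xo)) %% 2L
  list(gamete = ifelse(origin == 0L, h1, h2), origin = origin, crossovers = xo)
}

#' Pair mates with a target spousal phenotype correlation
#'
#' Noisy phenotype rank matching: the pool is split into two halves, each
#' half is ranked on phenotype plus Gaussian noise, and equal ranks are
#' paired. The noise scale is calibrated by bisection (on fixed noise draws)
#' so the realized cross-spouse phenotype correlation is within 0.02 of the
#' target.
#'
#' @param y Phenotypes of the mating pool (even length).
#' @param target_corr Target spousal correlation, in `[0, 1)`.
#' @return Two-column integer matrix of paired indices into `y`.
#' @export
mate_assortatively <- function(y, target_corr) {
  n <- length(y)
  stopifnot(n %% 2 == 0)
  if (target_corr >= 1) abort("target spousal correlation must be < 1")
  half <- sample.int(n, n / 2)
  A <- half; B <- setdiff(seq_len(n), half)
  if (target_corr <= 0) {
    return(cbind(A, sample(B)))
  }
  zA <- rnorm(length(A)); zB <- rnorm(length(B))
  sdy <- sd(y)
  realized <- function(s) {
    oA <- A[order(y[A] + s * sdy * zA)]
    oB <- B[order(y[B] + s * sdy * zB)]
    cor(y[oA], y[oB])
  }
  lo <- 0; hi <- 50
  if (realized(lo) < target_corr) {
    warn("target spousal correlation not achievable; using exact rank matching")
    hi <- 0
  }
  for (it in seq_len(40)) {
    mid <- (lo + hi) / 2
    if (realized(mid) > target_corr) lo <- mid else hi <- mid
    if (abs(realized((lo + hi) / 2) - target_corr) < 0.01) break
  }
  s <- (lo + hi) / 2
  oA <- A[order(y[A] + s * sdy * zA)]
  oB <- B[order(y[B] + s * sdy * zB)]
  cbind(oA, oB)
}

#' Generate phenotypes under the family effect model
#'
#' `Y = G delta + (G_p + G_m) alpha + eta (sibling direct-genotype score) +
#' vt (Y_p + Y_m) + deme offset + noise`. Parental and sibling terms are
#' omitted when the corresponding arguments are `NULL` (founder generation).
#'
#' @param G Centered genotype matrix (individuals x SNPs).
#' @param delta Per-SNP direct effects.
#' @param alpha Per-SNP parental indirect effects (may be `NULL`).
#' @param eta Per-SNP sibling indirect effects (may be `NULL`).
#' @param Gp,Gm Centered parental genotype matrices aligned to rows of `G`.
#' @param Gsib Centered sibling genotype matrix aligned to rows of `G`.
#' @param y_parents Two-column matrix of parental phenotypes (for vertical
#'   transmission), aligned to rows of `G`.
#' @param vt Vertical-transmission coefficient.
#' @param deme_offset Per-individual fixed offset.
#' @param noise_sd Residual standard deviation.
#' @return Numeric phenotype vector.
#' @export
generate_phenotypes <- function(G, delta, alpha = NULL, eta = NULL,
                                Gp = NULL, Gm = NULL, Gsib = NULL,
                                y_parents = NULL, vt = 0,
                                deme_offset = 0, noise_sd = 1) {
  y <- drop(G %*% delta)
  if (!is.null(alpha) && !is.null(Gp)) y <- y + drop((Gp + Gm) %*% alpha)
  if (!is.null(eta) && !is.null(Gsib)) y <- y + drop(Gsib %*% eta)
  if (vt != 0 && !is.null(y_parents)) y <- y + vt * rowSums(y_parents)
  y + deme_offset + rnorm(nrow(G), 0, noise_sd)
}

#' Run the forward family simulation
#'
#' Iterates mate -> meiosis -> phenotype for the configured number of
#' generations and emits the final generation as nuclear families with two
#' offspring: phased genotypes for parents and offspring, a pedigree, offspring
#' phenotypes, per-SNP true effects, true sibling IBD states from the recorded
#' crossovers, and realized population summaries (spousal correlations,
#' F_st).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return List of class `sim_output` with elements `geno` (a
#'   [phased_geno()] of parents and offspring), `pedigree`, `phenotype`
#'   (offspring tibble), `families`, `truth` (per-SNP effect tibble),
#'   `ibd_true` (family x SNP state matrix), `realized` (tibble of realized
#'   summaries) and `config`.
#' @export
run_simulation <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  L <- cfg$n_snps
  N <- 2L * cfg$n_families              # individuals per generation
  chrom <- rep(seq_len(cfg$n_chr), each = ceiling(L / cfg$n_chr))[seq_len(L)]
  pos_cM <- stats::ave(seq_len(L), chrom, FUN = function(i) {
    seq(0, cfg$map_length_cM, length.out = length(i))
  })
  base_f <- runif(L, cfg$freq_range[1], cfg$freq_range[2])
  deme_f <- matrix(base_f, cfg$n_demes, L, byrow = TRUE)
  if (cfg$n_demes > 1 && cfg$fst > 0) {
    a <- base_f * (1 - cfg$fst) / cfg$fst
    b <- (1 - base_f) * (1 - cfg$fst) / cfg$fst
    for (d in seq_len(cfg$n_demes)) {
      deme_f[d, ] <- pmin(pmax(rbeta(L, a, b), 0.01), 0.99)
    }
  }
  deme <- rep(seq_len(cfg$n_demes), length.out = N)
  deme <- sort(deme)
  offsets <- rnorm(cfg$n_demes, 0, cfg$deme_offset_sd)

  h1 <- matrix(rbinom(N * L, 1, deme_f[deme, ]), N, L)
  h2 <- matrix(rbinom(N * L, 1, deme_f[deme, ]), N, L)

  # effect sizes scaled to the configured founder variance shares
  Gc <- scale(h1 + h2, scale = FALSE)
  delta <- rnorm(L)
  delta <- delta * sqrt(cfg$h2_direct) / sd(drop(Gc %*% delta))
  alpha <- NULL
  if (cfg$parental_ige_share > 0) {
    raw <- cfg$ige_cor * scale(delta)[, 1] + sqrt(1 - cfg$ige_cor^2) * rnorm(L)
    # scaled so that the two parents' combined contribution has the target share
    alpha <- raw * sqrt(cfg$parental_ige_share) / sd(drop((2 * Gc) %*% raw))
    alpha <- alpha * sqrt(2)  # parents are independent at founding, not duplicated
  }
  eta <- NULL
  if (cfg$eta_s_share > 0) {
    eta <- delta * sqrt(cfg$eta_s_share) / sd(drop(Gc %*% delta))
  }
  noise_sd <- sqrt(max(1 - cfg$h2_direct - cfg$parental_ige_share - cfg$eta_s_share, 0.02))

  y <- generate_phenotypes(Gc, delta, deme_offset = offsets[deme], noise_sd = noise_sd)

  parent_state <- NULL
  spouse_cor <- NA_real_
  for (gen in seq_len(cfg$n_generations)) {
    pairs <- do.call(rbind, lapply(split(seq_len(N), deme), function(idx) {
      pr <- mate_assortatively(y[idx], cfg$am_target)
      cbind(idx[pr[, 1]], idx[pr[, 2]])
    }))
    spouse_cor <- cor(y[pairs[, 1]], y[pairs[, 2]])
    n_cpl <- nrow(pairs)
    ch1 <- matrix(0L, N, L); ch2 <- matrix(0L, N, L)
    orig_p <- matrix(0L, N, L); orig_m <- matrix(0L, N, L)
    child_deme <- integer(N); child_fam <- integer(N)
    for (cpl in seq_len(n_cpl)) {
      fa <- pairs[cpl, 1]; mo <- pairs[cpl, 2]
      for (k in 1:2) {
        child <- 2L * (cpl - 1L) + k
        for (ch in unique(chrom)) {
          idx <- which(chrom == ch)
          gp <- simulate_meiosis(h1[fa, idx], h2[fa, idx], pos_cM[idx])
          gm <- simulate_meiosis(h1[mo, idx], h2[mo, idx], pos_cM[idx])
          ch1[child, idx] <- gp$gamete    # paternal haplotype first
          ch2[child, idx] <- gm$gamete
          orig_p[child, idx] <- gp$origin
          orig_m[child, idx] <- gm$origin
        }
        child_deme[child] <- deme[fa]
        child_fam[child] <- cpl
      }
    }
    Gc_child <- scale(ch1 + ch2, scale = FALSE)
    Gc_par <- scale(h1 + h2, scale = FALSE)
    sib_of <- ifelse(seq_len(N) %% 2 == 1, seq_len(N) + 1, seq_len(N) - 1)
    y_child <- generate_phenotypes(
      Gc_child, delta, alpha = alpha, eta = eta,
      Gp = Gc_par[pairs[child_fam, 1], , drop = FALSE],
      Gm = Gc_par[pairs[child_fam, 2], , drop = FALSE],
      Gsib = Gc_child[sib_of, , drop = FALSE],
      y_parents = cbind(y[pairs[child_fam, 1]], y[pairs[child_fam, 2]]),
      vt = cfg$vt, deme_offset = offsets[child_deme], noise_sd = noise_sd)
    parent_state <- list(h1 = h1, h2 = h2, y = y, pairs = pairs, deme = deme)
    h1 <- ch1; h2 <- ch2; y <- y_child; deme <- child_deme
    fam_of_child <- child_fam
    orig_p_keep <- orig_p; orig_m_keep <- orig_m
  }
  if (cfg$n_generations == 0 || is.null(parent_state)) {
    abort("n_generations must be >= 1")
  }

  # assemble final-generation families
  n_fam <- nrow(parent_state$pairs)
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  pid <- sprintf("%s_p", fam_ids); mid <- sprintf("%s_m", fam_ids)
  o1 <- sprintf("%s_o1", fam_ids); o2 <- sprintf("%s_o2", fam_ids)
  keep_fam <- rep(TRUE, n_fam)
  y_o1 <- y[seq(1, N, by = 2)]; y_o2 <- y[seq(2, N, by = 2)]
  if (!is.null(cfg$ascertainment)) {
    sc <- (y_o1 + y_o2) / 2
    pct <- rank(sc) / length(sc)
    keep_fam <- runif(n_fam) < stats::plogis(cfg$ascertainment$k * (pct - cfg$ascertainment$c0))
  }
  fsel <- which(keep_fam)
  i_o1 <- 2 * fsel - 1; i_o2 <- 2 * fsel
  i_fa <- parent_state$pairs[fsel, 1]; i_mo <- parent_state$pairs[fsel, 2]

  ids <- c(pid[fsel], mid[fsel], o1[fsel], o2[fsel])
  H1 <- rbind(parent_state$h1[i_fa, , drop = FALSE], parent_state$h1[i_mo, , drop = FALSE],
              h1[i_o1, , drop = FALSE], h1[i_o2, , drop = FALSE])
  H2 <- rbind(parent_state$h2[i_fa, , drop = FALSE], parent_state$h2[i_mo, , drop = FALSE],
              h2[i_o1, , drop = FALSE], h2[i_o2, , drop = FALSE])
  freq <- colMeans(rbind(parent_state$h1[c(i_fa, i_mo), , drop = FALSE],
                         parent_state$h2[c(i_fa, i_mo), , drop = FALSE]))
  variants <- tibble(snp_id = sprintf("snp%05d", seq_len(L)),
                     chrom = as.character(chrom),
                     pos_bp = as.integer(round(pos_cM * 1e6) + 1),
                     allele0 = "A", allele1 = "B",
                     pos_cM = pos_cM, freq = pmin(pmax(freq, 1e-4), 1 - 1e-4),
                     ld_score = NA_real_)
  geno <- phased_geno(ids, variants, H1, H2, phased = TRUE)

  ibd_true <- (orig_p_keep[i_o1, , drop = FALSE] == orig_p_keep[i_o2, , drop = FALSE]) +
    (orig_m_keep[i_o1, , drop = FALSE] == orig_m_keep[i_o2, , drop = FALSE])
  rownames(ibd_true) <- fam_ids[fsel]

  pedigree <- bind_rows(
    tibble(fid = fam_ids[fsel], individual_id = pid[fsel], father_id = NA_character_,
           mother_id = NA_character_, sex = 1L, phenotype = NA_real_),
    tibble(fid = fam_ids[fsel], individual_id = mid[fsel], father_id = NA_character_,
           mother_id = NA_character_, sex = 2L, phenotype = NA_real_),
    tibble(fid = fam_ids[fsel], individual_id = o1[fsel], father_id = pid[fsel],
           mother_id = mid[fsel], sex = 1L, phenotype = y_o1[fsel]),
    tibble(fid = fam_ids[fsel], individual_id = o2[fsel], father_id = pid[fsel],
           mother_id = mid[fsel], sex = 2L, phenotype = y_o2[fsel]))
  phenotype <- tibble(individual_id = c(o1[fsel], o2[fsel]),
                      y = c(y_o1[fsel], y_o2[fsel]))
  # direct-effect genetic score defines the realized PGI-level spousal correlation
  pgi_fa <- drop(parent_state$h1[i_fa, , drop = FALSE] %*% delta +
                 parent_state$h2[i_fa, , drop = FALSE] %*% delta)
  pgi_mo <- drop(parent_state$h1[i_mo, , drop = FALSE] %*% delta +
                 parent_state$h2[i_mo, , drop = FALSE] %*% delta)
  fst_realized <- if (cfg$n_demes > 1) {
    fd <- rowsum(parent_state$h1 + parent_state$h2, parent_state$deme) /
      (2 * as.numeric(table(parent_state$deme)))
    fbar <- colMeans(fd)
    mean(apply(fd, 2, function(x) mean((x - mean(x))^2)) / (fbar * (1 - fbar)), na.rm = TRUE)
  } else 0
  structure(list(
    geno = geno, pedigree = pedigree, phenotype = phenotype,
    families = build_families(pedigree, ids),
    truth = tibble(snp_id = variants$snp_id, freq = variants$freq,
                   delta = delta,
                   alpha = if (is.null(alpha)) rep(0, L) else alpha,
                   eta_s = if (is.null(eta)) rep(0, L) else eta),
    ibd_true = ibd_true,
    realized = tibble(spouse_phenotype_cor = spouse_cor,
                      r_am = cor(pgi_fa, pgi_mo),
                      fst = fst_realized,
                      n_families = length(fsel)),
    config = cfg), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d families, %d SNPs; spousal cor %.3f, r_am %.3f, Fst %.4f\n",
              x$realized$n_families, nrow(x$geno$variants),
              x$realized$spouse_phenotype_cor, x$realized$r_am, x$realized$fst))
  invisible(x)
}

#' Convert the simulator's recorded IBD truth into IBD paths
#'
#' Builds `ibd_path` objects (one per sibling pair and chromosome) from the
#' crossover-derived true states of a [run_simulation()] output, for feeding
#' [mendelian_impute()] with exact IBD when the HMM step is being bypassed.
#'
#' @param sim A `sim_output`.
#' @return List with `paths` and `segments`, as from [infer_sib_ibd()].
#' @export
true_ibd_paths <- function(sim) {
  v <- sim$geno$variants
  fams <- rownames(sim$ibd_true)
  paths <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    for (fm in fams) {
      p <- structure(list(sib1 = paste0(fm, "_o1"), sib2 = paste0(fm, "_o2"),
                          chrom = ch, states = unname(sim$ibd_true[fm, idx]),
                          posterior = NULL,
                          variants = v[idx, c("snp_id", "pos_bp", "pos_cM")]),
                     class = "ibd_path")
      p$segments <- states_to_segments(p)
      paths[[length(paths) + 1]] <- p
    }
  }
  list(paths = paths, segments = bind_rows(lapply(paths, tidy)))
}

#' Inject genotyping errors
#'
#' With probability `rate` per individual x SNP, replaces the haplotype pair
#' with a fresh Hardy-Weinberg draw at the SNP's frequency (the same error
#' model the IBD HMM assumes).
#'
#' @param geno A [phased_geno()].
#' @param rate Error probability.
#' @return The perturbed `phased_geno`.
#' @export
add_genotype_errors <- function(geno, rate) {
  n <- length(geno$ids); L <- nrow(geno$variants)
  hit <- matrix(runif(n * L) < rate, n, L)
  if (any(hit)) {
    fmat <- matrix(geno$variants$freq, n, L, byrow = TRUE)
    geno$h1[hit] <- rbinom(sum(hit), 1, fmat[hit])
    geno$h2[hit] <- rbinom(sum(hit), 1, fmat[hit])
  }
  geno
}

#' Simulate single-SNP sibling-pair families
#'
#' Fast generator for one biallelic SNP across independent nuclear families
#' with two offspring: parental alleles, recorded transmissions (hence exact
#' IBD states and the phased-resolvable non-shared allele), and phenotypes
#' under the single-locus model with family-correlated residuals.
#'
#' @param n_families Number of families.
#' @param f Allele-1 frequency (scalar, or per-deme vector of length
#'   `n_demes`).
#' @param delta,alpha_p,alpha_m,eta_s True single-locus effects.
#' @param r Sibling residual correlation (family-effect share of the unit
#'   residual variance).
#' @param n_demes Number of equally sized demes.
#' @param deme_offset Per-deme fixed phenotype offsets (recycled).
#' @return Tibble with parental genotypes, sibling genotypes, transmitted
#'   alleles, IBD state, the non-shared allele of sibling 2 (for IBD1),
#'   phenotypes `y1`, `y2` and `deme`.
#' @export
simulate_snp_families <- function(n_families, f, delta = 0, alpha_p = 0,
                                  alpha_m = 0, eta_s = 0, r = 0,
                                  n_demes = 1, deme_offset = 0) {
  deme <- rep(seq_len(n_demes), length.out = n_families)
  fd <- rep_len(f, n_demes)[deme]
  off <- rep_len(deme_offset, n_demes)[deme]
  p1 <- rbinom(n_families, 1, fd); p2 <- rbinom(n_families, 1, fd)
  m1 <- rbinom(n_families, 1, fd); m2 <- rbinom(n_families, 1, fd)
  tp1 <- rbinom(n_families, 1, 0.5); tm1 <- rbinom(n_families, 1, 0.5)
  tp2 <- rbinom(n_families, 1, 0.5); tm2 <- rbinom(n_families, 1, 0.5)
  a_p1 <- ifelse(tp1 == 0, p1, p2); a_m1 <- ifelse(tm1 == 0, m1, m2)
  a_p2 <- ifelse(tp2 == 0, p1, p2); a_m2 <- ifelse(tm2 == 0, m1, m2)
  g1 <- a_p1 + a_m1; g2 <- a_p2 + a_m2
  gp <- p1 + p2; gm <- m1 + m2
  ibd <- (tp1 == tp2) + (tm1 == tm2)
  # non-shared allele of sibling 2 in IBD1 (known from the recorded
  # transmissions; what phase resolves in real data)
  ns2 <- ifelse(ibd == 1L, ifelse(tp1 == tp2, a_m2, a_p2), NA_integer_)
  fe <- rnorm(n_families, 0, sqrt(r))
  y1 <- delta * g1 + eta_s * g2 + alpha_p * gp + alpha_m * gm + off + fe +
    rnorm(n_families, 0, sqrt(1 - r))
  y2 <- delta * g2 + eta_s * g1 + alpha_p * gp + alpha_m * gm + off + fe +
    rnorm(n_families, 0, sqrt(1 - r))
  tibble(family_id = seq_len(n_families), deme = deme, f = fd,
         gp = gp, gm = gm, gpar = gp + gm,
         g1 = g1, g2 = g2, a_p1 = a_p1, a_m1 = a_m1, a_p2 = a_p2, a_m2 = a_m2,
         ibd = as.integer(ibd), ns2 = ns2, y1 = y1, y2 = y2)
}
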