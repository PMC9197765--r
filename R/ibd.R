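# Sibling IBD inference: a 3-state hidden Markov model over {IBD0, IBD1, IBD2}
# with a genotyping-error emission model, inverse-LD-score likelihood
# weighting, Haldane-map transitions and post-hoc segment smoothing.

#' IBD HMM parameters
#'
#' @param gamma Genotyping-error probability in `[0, 0.5)`: with probability
#'   `gamma` an individual's genotype is replaced by a Hardy-Weinberg draw.
#' @param min_seg_cM Minimum segment length `m` (cM) for post-hoc smoothing.
#' @return A list of class `ibd_params`.
#' @export
ibd_params <- function(gamma = 1e-4, min_seg_cM = 0.01) {
  stopifnot(gamma >= 0, gamma < 0.5, min_seg_cM >= 0)
  structure(list(gamma = gamma, min_seg_cM = min_seg_cM), class = "ibd_params")
}

hwe_pmf <- function(g, f) {
  ifelse(is.na(g), 1,
         ifelse(g == 0, (1 - f)^2, ifelse(g == 1, 2 * f * (1 - f), f^2)))
}

# Error-free P(g1, g2 | IBD = k, f) from the shared/non-shared allele
# construction: in IBD k the pair shares k alleles drawn once from the
# parents, plus (2 - k) independent draws each; all draws are Bernoulli(f)
# under random mating.
emission_prob_errorfree <- function(g1, g2, f, state) {
  bern <- function(x, f) ifelse(x < 0 | x > 1, 0, ifelse(x == 1, f, 1 - f))
  if (state == 0) return(hwe_pmf(g1, f) * hwe_pmf(g2, f))
  if (state == 2) return(ifelse(is.na(g1) | is.na(g2),
                                hwe_pmf(dplyr::coalesce(g1, g2), f),
                                ifelse(g1 == g2, hwe_pmf(g1, f), 0)))
  # IBD1: condition on the shared allele
  p <- 0
  for (a in 0:1) {
    pa <- if (a == 1) f else 1 - f
    t1 <- ifelse(is.na(g1), 1, bern(g1 - a, f))
    t2 <- ifelse(is.na(g2), 1, bern(g2 - a, f))
    p <- p + pa * t1 * t2
  }
  p
}

#' Emission log-probabilities of a sibling pair's genotypes
#'
#' For each IBD state `k`, computes `P(g1, g2 | IBD = k, f, gamma)` where with
#' probability `gamma` each individual's genotype is independently replaced by
#' a Hardy-Weinberg draw at frequency `f`. A missing genotype is marginalized
#' out.
#'
#' @param g1,g2 Genotypes in `{0, 1, 2}` or `NA`; vectors allowed.
#' @param f Allele-1 frequency (scalar or vector matching `g1`).
#' @param gamma Genotyping-error probability.
#' @return A matrix (length x 3) of log-probabilities, columns = IBD 0, 1, 2.
#' @export
ibd_emission_logprob <- function(g1, g2, f, gamma = 1e-4) {
  stopifnot(all(f > 0 & f < 1))
  n <- max(length(g1), length(g2), length(f))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n); f <- rep_len(f, n)
  keep <- (1 - gamma)^2
  background <- hwe_pmf(g1, f) * hwe_pmf(g2, f)
  out <- vapply(0:2, function(k) {
    p0 <- emission_prob_errorfree(g1, g2, f, k)
    log(keep * p0 + (1 - keep) * background)
  }, numeric(n))
  if (!is.matrix(out)) out <- matrix(out, nrow = n)
  colnames(out) <- paste0("IBD", 0:2)
  out
}

#' IBD transition matrix over a genetic distance
#'
#' The IBD state is the sum of two independent binary sharing indicators
#' (paternal and maternal). Over `d_cM` each indicator flips with probability
#' `2*theta*(1-theta)` where `theta = (1 - exp(-2d/100))/2` (Haldane map
#' function; two independent meioses per parent).
#'
#' @param d_cM Genetic distance in centimorgans (scalar, >= 0).
#' @return A 3x3 row-stochastic matrix, states 0/1/2.
#' @export
ibd_transition_matrix <- function(d_cM) {
  stopifnot(d_cM >= 0)
  theta <- (1 - exp(-2 * d_cM / 100)) / 2
  rho <- 2 * theta * (1 - theta)
  s <- 1 - rho
  matrix(c(s^2,        2 * rho * s,   rho^2,
           rho * s,    s^2 + rho^2,   rho * s,
           rho^2,      2 * rho * s,   s^2),
         nrow = 3, byrow = TRUE, dimnames = list(paste0("IBD", 0:2), paste0("IBD", 0:2)))
}

ibd_stationary <- c(0.25, 0.5, 0.25)

#' Infer the IBD path of one sibling pair along a chromosome
#'
#' Runs the HMM over SNPs sorted by map position. Per-SNP emission
#' log-likelihoods are multiplied by the inverse LD score, normalized to mean
#' one over the chromosome (pseudo-likelihood down-weighting of SNPs in
#' strong LD), before decoding; the same weighted scores are used for the
#' Viterbi path and the forward-backward posteriors.
#' The decoded path is then smoothed with [smooth_segments()].
#'
#' @param g1,g2 Genotype vectors of the two siblings over the chromosome.
#' @param variants Variant tibble with `snp_id`, `pos_bp`, `pos_cM` and
#'   optionally `ld_score` (defaults to 1 with a warning when absent).
#' @param params An [ibd_params()] object.
#' @param sib_pair Character vector of the two sibling IDs.
#' @param chrom Chromosome label.
#' @return An object of class `ibd_path`: per-SNP Viterbi states, posterior
#'   probabilities, and a segment tibble with half-open `[start_bp, end_bp)`
#'   intervals.
#' @export
infer_ibd <- function(g1, g2, variants, params = ibd_params(),
                      sib_pair = c("sib1", "sib2"), chrom = NULL) {
  v <- variants
  L <- nrow(v)
  stopifnot(length(g1) == L, length(g2) == L)
  if (is.null(chrom)) chrom <- as.character(v$chrom[1] %||% "1")
  if (is.unsorted(v$pos_cM)) abort("variants must be sorted by pos_cM")
  if (L < 10) warn(sprintf("chromosome %s has only %d SNPs; IBD path unreliable", chrom, L))
  ld <- v$ld_score
  if (is.null(ld) || all(is.na(ld))) {
    warn("no LD scores supplied; defaulting to 1.0 (no down-weighting)")
    ld <- rep(1, L)
  }
  ld[is.na(ld) | ld < 1] <- 1
  # inverse-LD-score weights, normalized to mean 1 so that uniform LD leaves
  # the emission/transition balance (and hence the decoded path) unchanged
  w <- (1 / ld) / mean(1 / ld)
  emis <- ibd_emission_logprob(g1, g2, v$freq, params$gamma) * w

  d <- diff(v$pos_cM)
  trans <- lapply(d, function(x) log(ibd_transition_matrix(max(x, 0))))

  # forward-backward (log space)
  la <- matrix(-Inf, L, 3); lb <- matrix(0, L, 3)
  la[1, ] <- log(ibd_stationary) + emis[1, ]
  for (t in seq_len(L - 1)) {
    m <- la[t, ] + trans[[t]]          # 3x3: rows = from
    la[t + 1, ] <- apply(m, 2, logsumexp) + emis[t + 1, ]
  }
  for (t in rev(seq_len(L - 1))) {
    m <- trans[[t]] + rep(emis[t + 1, ] + lb[t + 1, ], each = 3)
    lb[t, ] <- apply(m, 1, logsumexp)
  }
  lpost <- la + lb
  post <- exp(lpost - apply(lpost, 1, logsumexp))

  # Viterbi; ties broken toward the state with larger stationary probability
  # (IBD1), then the lower state index
  pref <- c(2L, 1L, 3L)  # evaluation order: state 1, 0, 2 (1-based columns)
  dp <- matrix(-Inf, L, 3); ptr <- matrix(1L, L, 3)
  dp[1, ] <- log(ibd_stationary) + emis[1, ]
  for (t in seq_len(L - 1)) {
    for (j in 1:3) {
      cand <- dp[t, ] + trans[[t]][, j]
      best <- pref[which.max(cand[pref])]
      ptr[t + 1, j] <- best
      dp[t + 1, j] <- cand[best] + emis[t + 1, j]
    }
  }
  states <- integer(L)
  states[L] <- pref[which.max(dp[L, pref])]
  if (L > 1) for (t in rev(seq_len(L - 1))) states[t] <- ptr[t + 1, states[t + 1]]
  states <- states - 1L

  path <- structure(list(sib1 = sib_pair[1], sib2 = sib_pair[2], chrom = chrom,
                         states = states, posterior = post,
                         variants = v[, intersect(c("snp_id", "pos_bp", "pos_cM"), names(v))],
                         viterbi_loglik = max(dp[L, ])),
                    class = "ibd_path")
  path$segments <- states_to_segments(path)
  smooth_segments(path, params$min_seg_cM)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

states_to_segments <- function(path) {
  v <- path$variants; s <- path$states
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  tibble(sib1 = path$sib1, sib2 = path$sib2, chrom = path$chrom,
         start_bp = v$pos_bp[starts],
         end_bp = c(v$pos_bp[starts[-1]], v$pos_bp[nrow(v)] + 1L),
         start_cM = v$pos_cM[starts], end_cM = v$pos_cM[ends],
         state = r$values, n_snps = r$lengths)
}

#' Smooth an IBD path by removing short segments
#'
#' Any maximal run of constant state spanning less than `m` cM whose two
#' flanking segments agree with each other is replaced by the flanking state,
#' iteratively until a fixed point. Chromosome-end segments are kept.
#'
#' @param path An `ibd_path` object.
#' @param m Minimum segment length in cM.
#' @return The smoothed `ibd_path`.
#' @export
smooth_segments <- function(path, m = 0.01) {
  if (m <= 0) return(path)
  s <- path$states
  cm <- path$variants$pos_cM
  repeat {
    r <- rle(s)
    if (length(r$values) < 3) break
    ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
    span <- cm[ends] - cm[starts]
    changed <- FALSE
    for (k in 2:(length(r$values) - 1)) {
      if (span[k] < m && r$values[k - 1] == r$values[k + 1] &&
          r$values[k] != r$values[k - 1]) {
        s[starts[k]:ends[k]] <- r$values[k - 1]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  path$states <- s
  path$segments <- states_to_segments(path)
  path
}

#' @export
print.ibd_path <- function(x, ...) {
  cat(sprintf("<ibd_path> %s-%s chr%s: %d SNPs, %d segments (IBD0/1/2 = %s)\n",
              x$sib1, x$sib2, x$chrom, length(x$states), nrow(x$segments),
              paste(tabulate(x$states + 1L, 3), collapse = "/")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ibd_path <- function(x, ...) x$segments

#' @rdname infer_ibd
#' @param object,x An `ibd_path` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ibd_path <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_cM, xmax = .data$end_cM,
                                    ymin = 0, ymax = 1, fill = factor(.data$state))) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "steelblue", `2` = "navy"),
                               name = "IBD state") +
    ggplot2::labs(x = "position (cM)", y = NULL,
                  title = sprintf("IBD path %s-%s chr%s", object$sib1, object$sib2, object$chrom)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Genome-wide IBD state fractions
#'
#' Length-weighted (cM) fractions of IBD0/1/2 across a list of IBD paths.
#' Each SNP owns half the map interval to each neighbour.
#'
#' @param paths List of `ibd_path` objects (paths with no SNPs are skipped).
#' @return Tibble with columns `state` and `fraction`.
#' @export
ibd_summary <- function(paths) {
  if (inherits(paths, "ibd_path")) paths <- list(paths)
  stopifnot(length(paths) >= 1)
  tot <- c(0, 0, 0)
  for (p in paths) {
    L <- length(p$states)
    if (L == 0) next
    cm <- p$variants$pos_cM
    w <- if (L == 1) 1 else (c(diff(cm), 0) + c(0, diff(cm))) / 2
    tot <- tot + vapply(0:2, function(k) sum(w[p$states == k]), numeric(1))
  }
  tibble(state = 0:2, fraction = tot / sum(tot))
}

#' Infer IBD paths for all genotyped sibling pairs
#'
#' Driver over a genotype set and family table: runs [infer_ibd()] per sibling
#' pair and chromosome.
#'
#' @param geno A [phased_geno()] with `pos_cM` filled in.
#' @param families Family tibble from [build_families()], or a two-column
#'   tibble/matrix of sibling ID pairs.
#' @param params An [ibd_params()] object.
#' @return List with `paths` (list of `ibd_path`) and `segments` (combined
#'   tibble).
#' @export
infer_sib_ibd <- function(geno, families, params = ibd_params()) {
  pairs <- sib_pairs_from(families, geno$ids)
  g <- genotypes(geno)
  v <- geno$variants
  if (is.null(v$ld_score) || all(is.na(v$ld_score))) {
    warn("no LD scores supplied; defaulting to 1.0 (no down-weighting)")
    v$ld_score <- 1
  }
  paths <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos_cM[idx])]
    for (r in seq_len(nrow(pairs))) {
      p <- infer_ibd(g[pairs$sib1[r], idx], g[pairs$sib2[r], idx],
                     v[idx, ], params,
                     sib_pair = c(pairs$sib1[r], pairs$sib2[r]), chrom = ch)
      paths[[length(paths) + 1]] <- p
    }
  }
  list(paths = paths, segments = bind_rows(lapply(paths, tidy)))
}

sib_pairs_from <- function(families, ids) {
  if (!is.null(families$offspring_ids)) {
    rows <- list()
    for (i in seq_len(nrow(families))) {
      sibs <- intersect(families$offspring_ids[[i]][families$offspring_genotyped[[i]]], ids)
      if (length(sibs) >= 2) {
        cmb <- utils::combn(sibs, 2)
        rows[[length(rows) + 1]] <- tibble(sib1 = cmb[1, ], sib2 = cmb[2, ])
      }
    }
    bind_rows(rows)
  } else {
    tibble(sib1 = as.character(families[[1]]), sib2 = as.character(families[[2]]))
  }
}

#' Sum-of-r-squared LD scores from a genotype set
#'
#' Computes, for each SNP, the sum of squared Pearson correlations with all
#' SNPs within a map window (including itself, so scores are >= 1).
#'
#' @param geno A [phased_geno()] with `pos_cM` filled in.
#' @param window_cM Window half-width in cM.
#' @return Tibble with `snp_id` and `ld_score`.
#' @export
ld_scores_r2 <- function(geno, window_cM = 1) {
  g <- genotypes(geno)
  v <- geno$variants
  out <- numeric(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    cm <- v$pos_cM[idx]
    gs <- scale(g[, idx, drop = FALSE])
    n <- nrow(gs)
    lo <- findInterval(cm - window_cM, cm, left.open = TRUE) + 1
    hi <- findInterval(cm + window_cM, cm)
    for (j in seq_along(idx)) {
      r <- crossprod(gs[, lo[j]:hi[j], drop = FALSE], gs[, j]) / (n - 1)
      out[idx[j]] <- sum(r^2, na.rm = TRUE)
    }
  }
  tibble(snp_id = v$snp_id, ld_score = pmax(out, 1))
}
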