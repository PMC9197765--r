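# Moment-based estimation of genome-wide correlations between effect classes
# (e.g. direct vs population effects), correcting the second moments for the
# known per-SNP sampling variance-covariance, with block-jackknife standard
# errors.

#' Genome-wide correlation between two effect columns
#'
#' Method-of-moments estimator: the empirical covariance and variances of the
#' per-SNP estimates are corrected by subtracting the mean sampling
#' (co)variances, and the correlation of the underlying true effects is their
#' ratio:
#' `r = (cov(a,b) - mean(scov)) / sqrt((var(a) - mean(se_a^2)) (var(b) - mean(se_b^2)))`.
#' Standard errors come from a delete-one block jackknife over contiguous
#' genomic blocks (chromosome-respecting when a `chrom` column is present).
#'
#' @param data Tibble with one aligned row per SNP.
#' @param a,b Names of the two effect-estimate columns.
#' @param se_a,se_b Names of their standard-error columns.
#' @param cov_ab Name of the sampling-covariance column, or `NULL` for 0
#'   (e.g. estimates from disjoint samples).
#' @param n_blocks Number of jackknife blocks.
#' @param weights Optional name of a per-SNP weight column for the moment
#'   averages (default unweighted).
#' @param se_quantile Optional: drop SNPs whose larger standard error exceeds
#'   this quantile before estimation (default keeps all SNPs).
#' @param cross_sample Flag recorded in the result (set by
#'   [cross_sample_correlation()]).
#' @return One-row tibble of class `fam_cor`: `r_hat`, `se`, `n_snps`,
#'   `n_blocks`, `label_a`, `label_b`, `cross_sample`, `out_of_range`.
#' @export
moment_correlation <- function(data, a, b, se_a, se_b, cov_ab = NULL,
                               n_blocks = 100, weights = NULL,
                               se_quantile = NULL, cross_sample = FALSE) {
  d <- as_tibble(data)
  need <- c(a, b, se_a, se_b, cov_ab, weights)
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  d <- d[complete.cases(d[, need]), ]
  if (nrow(d) == 0) abort("no aligned SNPs with complete estimates")
  if (!is.null(se_quantile)) {
    worst <- pmax(d[[se_a]], d[[se_b]])
    d <- d[worst <= stats::quantile(worst, se_quantile), ]
  }
  n <- nrow(d)
  n_blocks <- min(n_blocks, n)
  blk <- if ("chrom" %in% names(d)) {
    # contiguous equal-SNP blocks that respect chromosome boundaries
    ch <- as.integer(factor(d$chrom, levels = unique(d$chrom)))
    within <- stats::ave(seq_len(n), ch, FUN = seq_along)
    per_ch <- table(ch)
    nb_ch <- pmax(1, round(n_blocks * as.numeric(per_ch) / n))
    offset <- c(0, cumsum(nb_ch))[ch]
    offset + ceiling(within / (as.numeric(per_ch)[ch] / nb_ch[ch]))
  } else {
    cut(seq_len(n), n_blocks, labels = FALSE)
  }
  w <- if (is.null(weights)) rep(1, n) else d[[weights]]
  est <- function(keep) {
    x <- d[[a]][keep]; y <- d[[b]][keep]; wk <- w[keep]; wk <- wk / sum(wk)
    mx <- sum(wk * x); my <- sum(wk * y)
    cab <- sum(wk * (x - mx) * (y - my)) -
      (if (is.null(cov_ab)) 0 else sum(wk * d[[cov_ab]][keep]))
    va <- sum(wk * (x - mx)^2) - sum(wk * d[[se_a]][keep]^2)
    vb <- sum(wk * (y - my)^2) - sum(wk * d[[se_b]][keep]^2)
    c(cab = cab, va = va, vb = vb)
  }
  full <- est(rep(TRUE, n))
  if (full["va"] <= 0 || full["vb"] <= 0) {
    abort(sprintf(paste("sampling-noise-corrected variance is not positive",
                        "(var_a = %.3g, var_b = %.3g): estimates are too noisy",
                        "relative to the true effect variance"),
                  full["va"], full["vb"]))
  }
  r_hat <- unname(full["cab"] / sqrt(full["va"] * full["vb"]))
  blocks <- unique(blk)
  loo <- vapply(blocks, function(k) {
    m <- est(blk != k)
    if (m["va"] <= 0 || m["vb"] <= 0) return(NA_real_)
    unname(m["cab"] / sqrt(m["va"] * m["vb"]))
  }, numeric(1))
  loo <- loo[is.finite(loo)]
  B <- length(loo)
  se <- if (B >= 2) sqrt((B - 1) / B * sum((loo - mean(loo))^2)) else NA_real_
  out <- tibble(r_hat = r_hat, se = se, n_snps = n, n_blocks = B,
                label_a = a, label_b = b, cross_sample = cross_sample,
                out_of_range = abs(r_hat) > 1)
  if (out$out_of_range) warn("corrected correlation outside [-1, 1] (noisy input); reported as-is")
  class(out) <- c("fam_cor", class(out))
  out
}

#' Correlation between effects estimated in disjoint samples
#'
#' [moment_correlation()] with the sampling covariance between the two
#' estimate sets fixed at zero, appropriate when they come from
#' non-overlapping samples.
#'
#' @inheritParams moment_correlation
#' @return A `fam_cor` tibble.
#' @export
cross_sample_correlation <- function(data, a, b, se_a, se_b,
                                     n_blocks = 100, weights = NULL,
                                     se_quantile = NULL) {
  moment_correlation(data, a, b, se_a, se_b, cov_ab = NULL,
                     n_blocks = n_blocks, weights = weights,
                     se_quantile = se_quantile, cross_sample = TRUE)
}

#' Align two summary-statistic sets by SNP
#'
#' Inner join on `snp_id`, suffixing overlapping columns, for feeding
#' cross-sample correlations.
#'
#' @param sumstats_a,sumstats_b Summary-statistic tibbles with `snp_id`.
#' @return Joined tibble (columns suffixed `_a`/`_b`).
#' @export
align_sumstats <- function(sumstats_a, sumstats_b) {
  out <- inner_join(sumstats_a, sumstats_b, by = "snp_id", suffix = c("_a", "_b"))
  if (nrow(out) == 0) abort("no overlapping SNPs after alignment")
  out
}
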