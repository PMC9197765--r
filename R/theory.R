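# Closed-form efficiency and bias reference formulas, plus deterministic
# expected-information computations by enumeration over the finite family
# genotype distribution. Used for diagnostics and as test oracles against the
# simulator. Throughout, r is the correlation of the siblings' residuals.

#' Effective-sample-size gain for the direct effect, phased sibling imputation
#'
#' Gain relative to the sibling-difference estimator: `1 + (1-r)/(3(1+r))`,
#' with a maximum of 4/3 at r = 0.
#'
#' @param r Sibling residual correlation in `[0, 1)` (1 allowed as a limit).
#' @return Numeric gain factor.
#' @export
effn_direct_sib_phased <- function(r) {
  stopifnot(all(r >= 0), all(r <= 1))
  1 + (1 - r) / (3 * (1 + r))
}

#' Effective-sample-size gain for the average NTC, phased sibling imputation
#'
#' Gain relative to the no-imputation regression on sibling genotypes alone:
#' `1 + (1 - r/2)/(2(1+r))`, maximum 1.5 at r = 0, infimum 1.125 as r -> 1.
#'
#' @inheritParams effn_direct_sib_phased
#' @return Numeric gain factor.
#' @export
effn_ntc_sib_phased <- function(r) {
  stopifnot(all(r >= 0), all(r <= 1))
  1 + (1 - r / 2) / (2 * (1 + r))
}

#' Effective-sample-size gain for the structure-robust split estimator
#'
#' `1 + (1-r)/(6(1+r))` relative to the sibling-difference estimator;
#' maximum 7/6 at r = 0.
#'
#' @inheritParams effn_direct_sib_phased
#' @return Numeric gain factor.
#' @export
effn_direct_split <- function(r) {
  stopifnot(all(r >= 0), all(r <= 1))
  1 + (1 - r) / (6 * (1 + r))
}

#' Bias in the direct effect from wrongly assuming no sibling IGE
#'
#' When the sibling indirect effect `eta_s` is nonzero but omitted from the
#' sibling-pair model, the direct-effect estimate is biased by
#' `-((1+2r)/(2+r)) * eta_s` — smaller in magnitude than the sibling-difference
#' bias `-eta_s` for r < 1.
#'
#' @inheritParams effn_direct_sib_phased
#' @param eta_s True sibling indirect effect.
#' @return Numeric bias.
#' @export
bias_delta_assuming_no_sibige <- function(r, eta_s) {
  stopifnot(all(r >= 0), all(r <= 1))
  -((1 + 2 * r) / (2 + r)) * eta_s
}

#' Structure-induced bias in the direct effect
#'
#' Mixing imputations with different numbers of observed parental alleles
#' under population structure biases the pooled direct-effect estimate by
#' approximately `F_st * alpha / 2` for small `F_st`.
#'
#' @param f_st Wright's fixation index between subpopulations (>= 0).
#' @param alpha Average NTC (including structure confounding).
#' @return Numeric bias.
#' @export
structure_bias_delta <- function(f_st, alpha) {
  stopifnot(all(f_st >= 0))
  f_st * alpha / 2
}

# Expected per-family second-moment matrix of the regression columns for a
# parent-offspring design, by exact enumeration over parental alleles and
# transmissions. Columns: offspring genotype, imputed missing parent,
# observed parent. Used to compute relative expected GLS information.
po_design_moments <- function(f, phased) {
  combos <- expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1, tp = 1:2, tm = 1:2)
  w <- apply(combos[, 1:4], 1, function(a) prod(ifelse(a == 1, f, 1 - f))) / 4
  gp <- combos$p1 + combos$p2
  gm <- combos$m1 + combos$m2
  at <- ifelse(combos$tp == 1, combos$p1, combos$p2)  # paternal transmitted allele
  am <- ifelse(combos$tm == 1, combos$m1, combos$m2)
  go <- at + am
  imp <- if (phased) {
    at + f
  } else {
    ifelse(go == 1 & gm == 1, 2 * f, at + f)  # double-het averaged over the two patterns
  }
  X <- cbind(delta = go, alpha_p = imp, alpha_m = gm)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc, Xc * w)
}

#' Relative effective sample size of parent-offspring versus trio designs
#'
#' Expected GLS information for the direct effect from a parent-offspring pair
#' (one parent observed, the other imputed) relative to complete observation
#' of both parents, at independent-residual families. With phased data the
#' ratio is 1/2 regardless of allele frequency; with unphased data it falls
#' from 1/2 as MAF approaches 0 to 1/6 at MAF 0.5. Computed by deterministic
#' enumeration over the finite family genotype distribution (no closed form
#' for the unphased curve).
#'
#' @param maf Minor allele frequency in (0, 0.5].
#' @param phased Whether double-heterozygote transmissions are resolved.
#' @return Relative effective sample size in (0, 1/2].
#' @export
effn_po_relative <- function(maf, phased = TRUE) {
  stopifnot(maf > 0, maf <= 0.5)
  M_po <- po_design_moments(maf, phased)
  combos <- expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1, tp = 1:2, tm = 1:2)
  w <- apply(combos[, 1:4], 1, function(a) prod(ifelse(a == 1, maf, 1 - maf))) / 4
  go <- ifelse(combos$tp == 1, combos$p1, combos$p2) +
    ifelse(combos$tm == 1, combos$m1, combos$m2)
  X <- cbind(delta = go, alpha_p = combos$p1 + combos$p2, alpha_m = combos$m1 + combos$m2)
  Xc <- sweep(X, 2, colSums(X * w))
  M_trio <- crossprod(Xc, Xc * w)
  solve(M_trio)["delta", "delta"] / solve(M_po)["delta", "delta"]
}

#' Plot the theoretical efficiency curves
#'
#' Gain factors for the direct effect and average NTC from phased sibling
#' imputation and for the robust split estimator, as functions of the sibling
#' residual correlation.
#'
#' @param r Grid of sibling residual correlations.
#' @return A ggplot object.
#' @export
plot_efficiency_curves <- function(r = seq(0, 0.99, by = 0.01)) {
  d <- bind_rows(
    tibble(r = r, gain = effn_direct_sib_phased(r), quantity = "direct effect (phased sibs)"),
    tibble(r = r, gain = effn_ntc_sib_phased(r), quantity = "average NTC (phased sibs)"),
    tibble(r = r, gain = effn_direct_split(r), quantity = "direct effect (robust split)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$gain, colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sibling residual correlation r",
                  y = "effective-sample-size gain") +
    ggplot2::theme_minimal()
}
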