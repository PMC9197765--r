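# Independent enumeration oracles: exhaustive enumeration of parental alleles
# and transmissions for a nuclear family at one SNP. These never call the
# imputation formulas they are used to check.

# joint enumeration for a sibling pair: parental alleles (Bernoulli(f)) and
# both siblings' transmission choices, with derived IBD state and the
# non-shared allele of sibling 2
sibpair_enumeration <- function(f) {
  d <- expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1,
                   tp1 = 1:2, tm1 = 1:2, tp2 = 1:2, tm2 = 1:2)
  d$w <- apply(d[, 1:4], 1, function(a) prod(ifelse(a == 1, f, 1 - f))) / 16
  d$a_p1 <- ifelse(d$tp1 == 1, d$p1, d$p2); d$a_m1 <- ifelse(d$tm1 == 1, d$m1, d$m2)
  d$a_p2 <- ifelse(d$tp2 == 1, d$p1, d$p2); d$a_m2 <- ifelse(d$tm2 == 1, d$m1, d$m2)
  d$g1 <- d$a_p1 + d$a_m1; d$g2 <- d$a_p2 + d$a_m2
  d$gpar <- d$p1 + d$p2 + d$m1 + d$m2
  d$ibd <- (d$tp1 == d$tp2) + (d$tm1 == d$tm2)
  d$ns2 <- ifelse(d$ibd == 1, ifelse(d$tp1 == d$tp2, d$a_m2, d$a_p2), NA)
  d
}

# parent-offspring enumeration: one offspring, mother observed, father missing
po_enumeration <- function(f) {
  d <- expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1, tp = 1:2, tm = 1:2)
  d$w <- apply(d[, 1:4], 1, function(a) prod(ifelse(a == 1, f, 1 - f))) / 4
  d$at <- ifelse(d$tp == 1, d$p1, d$p2)   # paternally transmitted allele
  d$go <- d$at + ifelse(d$tm == 1, d$m1, d$m2)
  d$gp <- d$p1 + d$p2; d$gm <- d$m1 + d$m2
  d
}

wvar <- function(x, w) sum(w * x^2) - sum(w * x)^2
wcov <- function(x, y, w) sum(w * x * y) - sum(w * x) * sum(w * y)

# exact R^2 and truth-on-imputed slope of the sibling-pair parental-sum
# imputation over the enumeration
r2_exact_sib <- function(f, phased = TRUE) {
  d <- sibpair_enumeration(f)
  gh <- impute_parsum_sibs(d$g1, d$g2, d$ibd, f, if (phased) d$ns2 else NA)
  c(r2 = wvar(gh, d$w) / wvar(d$gpar, d$w),
    slope = wcov(gh, d$gpar, d$w) / wvar(gh, d$w))
}

# exact R^2 of the parent-offspring imputation (father from offspring+mother)
r2_exact_po <- function(f, phased = TRUE) {
  d <- po_enumeration(f)
  gh <- impute_parent_from_parent_offspring(d$go, d$gm, f,
                                            transmitted = if (phased) d$at else NA)
  c(r2 = wvar(gh, d$w) / wvar(d$gp, d$w),
    slope = wcov(gh, d$gp, d$w) / wvar(gh, d$w))
}

# small variant table for hand-built genotype fixtures
toy_variants <- function(L, chrom = "1", cm_span = 50, f = 0.5) {
  tibble::tibble(snp_id = paste0("s", seq_len(L)), chrom = chrom,
                 pos_bp = as.integer(seq_len(L) * 1000),
                 allele0 = "A", allele1 = "B",
                 pos_cM = seq(0, cm_span, length.out = L),
                 freq = rep_len(f, L), ld_score = 1)
}
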