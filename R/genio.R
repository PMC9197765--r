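# Readers/writers for on-disk formats plus the in-memory phased genotype
# container. All downstream code consumes the in-memory types only.

#' Phased genotype container
#'
#' Holds per-individual, per-SNP haplotype pairs (alleles 0/1) together with
#' variant metadata. Genotypes are counts of allele "1", whose population
#' frequency is stored in `variants$freq`. Missingness is explicit (`NA`
#' haplotypes), never encoded as an allele value.
#'
#' @param ids Character vector of individual IDs.
#' @param variants Tibble with columns `snp_id`, `chrom`, `pos_bp`, `allele0`,
#'   `allele1` and optionally `pos_cM`, `freq`, `ld_score`.
#' @param h1,h2 Integer matrices (individuals x SNPs) of alleles in `{0, 1}`;
#'   `NA` marks a missing haplotype.
#' @param phased Logical matrix (individuals x SNPs) or a single logical; `TRUE`
#'   where the haplotype pair carries phase information.
#' @return An object of class `phased_geno`.
#' @export
phased_geno <- function(ids, variants, h1, h2, phased = TRUE) {
  ids <- as.character(ids)
  variants <- as_tibble(variants)
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  stopifnot(nrow(h1) == length(ids), nrow(h2) == length(ids),
            ncol(h1) == nrow(variants), ncol(h2) == nrow(variants))
  if (is.matrix(phased)) {
    stopifnot(identical(dim(phased), dim(h1)))
  } else {
    phased <- matrix(isTRUE(phased), nrow(h1), ncol(h1))
  }
  for (col in c("pos_cM", "freq", "ld_score")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  bad <- h1[!is.na(h1)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) abort("haplotype alleles must be 0/1")
  rownames(h1) <- rownames(h2) <- ids
  structure(list(ids = ids, variants = variants, h1 = h1, h2 = h2,
                 phased = phased),
            class = "phased_geno")
}

#' @export
print.phased_geno <- function(x, ...) {
  cat(sprintf("<phased_geno> %d individuals x %d SNPs (%d chromosome%s)\n",
              length(x$ids), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' Extract the genotype (allele-count) matrix
#'
#' @param geno A [phased_geno()] object.
#' @return Integer matrix (individuals x SNPs) of counts of allele "1";
#'   `NA` where either haplotype is missing.
#' @export
genotypes <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  g <- geno$h1 + geno$h2
  colnames(g) <- geno$variants$snp_id
  g
}

#' Read phased genotypes from a VCF file
#'
#' Parses the GT field of a VCF 4.x file. Phased entries ("0|1") retain their
#' haplotype order; unphased entries ("0/1") are loaded with the phased flag
#' set to `FALSE`. Multi-allelic records are skipped with a warning, as are
#' variants with all genotypes missing. Allele "1" (the ALT allele) is the
#' counted allele and `freq` is its frequency, estimated from pedigree founders
#' when a pedigree is supplied (to avoid double-counting transmitted alleles),
#' otherwise from all individuals.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param maf_min Minimum minor allele frequency; variants below it are dropped.
#' @param pedigree Optional pedigree tibble (see [read_pedigree()]) used to
#'   restrict frequency estimation to founders.
#' @return A [phased_geno()] object.
#' @export
read_phased_vcf <- function(path, maf_min = 0, pedigree = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic variant(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ids <- colnames(gt)
  ok <- is.na(gt) | grepl("^[01.]([|/])[01.]$", gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed GT entry '%s' at variant %s, sample %s",
                  gt[!ok][1], fix[bad[1], "ID"], ids[bad[2]]))
  }
  phased <- t(grepl("|", gt, fixed = TRUE) & !is.na(gt))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  a1[a1 == "." | is.na(a1)] <- NA; a2[a2 == "." | is.na(a2)] <- NA
  h1 <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  h2 <- t(matrix(as.integer(a2), nrow = nrow(gt)))
  variants <- tibble(
    snp_id = unname(ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                           paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])),
    chrom = unname(fix[, "CHROM"]),
    pos_bp = as.integer(fix[, "POS"]),
    allele0 = unname(fix[, "REF"]),
    allele1 = unname(fix[, "ALT"]))
  g <- h1 + h2
  rownames(g) <- ids
  freq_ids <- ids
  if (!is.null(pedigree)) {
    offspring <- pedigree$individual_id[
      pedigree$father_id %in% ids & pedigree$mother_id %in% ids]
    founders <- setdiff(ids, offspring)
    if (length(founders) > 0) freq_ids <- founders
  }
  freq <- colMeans(g[freq_ids, , drop = FALSE], na.rm = TRUE) / 2
  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing)) {
    warn(sprintf("dropping %d variant(s) with all genotypes missing", sum(all_missing)))
  }
  maf <- pmin(freq, 1 - freq)
  keep <- !all_missing & !is.na(maf) & maf >= maf_min
  variants <- variants[keep, , drop = FALSE]
  variants$freq <- unname(freq[keep])
  phased_geno(ids, variants, h1[, keep, drop = FALSE], h2[, keep, drop = FALSE],
              phased[, keep, drop = FALSE])
}

#' Write phased genotypes to a VCF file
#'
#' Inverse of [read_phased_vcf()]: haplotype order and phase flags round-trip.
#'
#' @param geno A [phased_geno()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  v <- geno$variants
  sep <- ifelse(t(geno$phased), "|", "/")
  c1 <- t(ifelse(is.na(geno$h1), ".", geno$h1))
  c2 <- t(ifelse(is.na(geno$h2), ".", geno$h2))
  gt <- matrix(paste0(c1, sep, c2), nrow = nrow(v))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$ids), collapse = "\t"))
  body <- cbind(v$chrom, v$pos_bp, v$snp_id, v$allele0, v$allele1,
                ".", ".", ".", "GT", gt)
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a genetic map
#'
#' Whitespace-delimited text with columns chromosome, position (bp) and map
#' position (cM); a header line is detected and skipped. Map positions must be
#' non-decreasing within a chromosome.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `chrom`, `pos_bp`, `pos_cM`.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][2])))
  m <- read.table(path, header = FALSE, skip = as.integer(has_header),
                  col.names = c("chrom", "pos_bp", "pos_cM"),
                  colClasses = c("character", "integer", "numeric"))
  m <- as_tibble(m) |> arrange(.data$chrom, .data$pos_bp)
  bad <- m |> group_by(.data$chrom) |>
    summarise(dec = any(diff(.data$pos_cM) < 0), .groups = "drop")
  if (any(bad$dec)) {
    abort(sprintf("decreasing cM positions within chromosome %s",
                  paste(bad$chrom[bad$dec], collapse = ", ")))
  }
  m
}

#' Interpolate genetic-map positions
#'
#' Linear interpolation between map points; queries beyond the ends of the map
#' are clamped to the terminal cM values.
#'
#' @param map Genetic map tibble from [read_genetic_map()].
#' @param chrom Chromosome of the query positions.
#' @param pos_bp Integer vector of base-pair positions.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  m <- map[map$chrom == as.character(chrom), ]
  if (nrow(m) == 0) abort(sprintf("chromosome %s not in map", chrom))
  if (nrow(m) == 1) return(rep(m$pos_cM, length(pos_bp)))
  approx(m$pos_bp, m$pos_cM, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' Attach map positions and LD scores to a genotype set
#'
#' @param geno A [phased_geno()] object.
#' @param map Optional genetic map tibble; fills `variants$pos_cM`.
#' @param ld_scores Optional tibble (`snp_id`, `ld_score`); fills
#'   `variants$ld_score`.
#' @return The updated `phased_geno`.
#' @export
attach_variant_info <- function(geno, map = NULL, ld_scores = NULL) {
  v <- geno$variants
  if (!is.null(map)) {
    for (ch in unique(v$chrom)) {
      i <- which(v$chrom == ch)
      v$pos_cM[i] <- interpolate_cM(map, ch, v$pos_bp[i])
    }
  }
  if (!is.null(ld_scores)) {
    v <- v |> select(-"ld_score") |>
      left_join(ld_scores[, c("snp_id", "ld_score")], by = "snp_id")
  }
  geno$variants <- v
  geno
}

#' Read a FAM-like pedigree file
#'
#' Columns: family ID, individual ID, father ID, mother ID, sex, phenotype.
#' "0" and "NA" mark missing parents.
#'
#' @param path Path to the pedigree file.
#' @return Tibble with columns `fid`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `phenotype`.
#' @export
read_pedigree <- function(path) {
  p <- read.table(path, header = FALSE, colClasses = "character",
                  col.names = c("fid", "individual_id", "father_id",
                                "mother_id", "sex", "phenotype"))
  p <- as_tibble(p)
  p$father_id[p$father_id %in% c("0", "NA", "")] <- NA
  p$mother_id[p$mother_id %in% c("0", "NA", "")] <- NA
  p$sex <- suppressWarnings(as.integer(p$sex))
  p$phenotype <- suppressWarnings(as.numeric(p$phenotype))
  p
}

#' Read per-SNP LD scores
#'
#' @param path Tab-delimited file with columns `snp_id` and `ld_score`.
#' @return Tibble with those columns.
#' @export
read_ld_scores <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t")
  names(x)[1:2] <- c("snp_id", "ld_score")
  as_tibble(x[, 1:2])
}

#' Read PGI weights
#'
#' @param path Tab-delimited file with columns `snp_id`, `effect_allele`,
#'   `weight`.
#' @return Tibble with those columns.
#' @export
read_pgi_weights <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", colClasses = c("character", "character", "numeric"))
  names(x)[1:3] <- c("snp_id", "effect_allele", "weight")
  as_tibble(x[, 1:3])
}

# All parameter labels a summary-statistic row may carry, in canonical order.
sumstat_labels <- c("delta", "eta_s", "alpha_p", "alpha_m", "alpha", "alpha_par")

derive_beta_pop <- function(row) {
  est <- function(l) row[[paste0("est_", l)]]
  se2 <- function(l) row[[paste0("se_", l)]]^2
  cv <- function(a, b) {
    col <- paste0("cov_", a, "_", b); col2 <- paste0("cov_", b, "_", a)
    v <- if (col %in% names(row)) row[[col]] else if (col2 %in% names(row)) row[[col2]] else NA_real_
    if (is.na(v)) 0 else v
  }
  if (!is.na(est("alpha_p")) && !is.na(est("alpha_m"))) {
    beta <- est("delta") + (est("alpha_p") + est("alpha_m")) / 2
    vb <- se2("delta") + (se2("alpha_p") + se2("alpha_m")) / 4 +
      cv("delta", "alpha_p") + cv("delta", "alpha_m") + cv("alpha_p", "alpha_m") / 2
  } else if (!is.na(est("alpha"))) {
    beta <- est("delta") + est("alpha")
    vb <- se2("delta") + se2("alpha") + 2 * cv("delta", "alpha")
  } else if (!is.na(est("alpha_par")) && !is.na(est("eta_s"))) {
    beta <- est("delta") + est("alpha_par") + est("eta_s") / 2
    vb <- se2("delta") + se2("alpha_par") + se2("eta_s") / 4 +
      2 * cv("delta", "alpha_par") + cv("delta", "eta_s") + cv("alpha_par", "eta_s")
  } else {
    beta <- NA_real_; vb <- NA_real_
  }
  c(beta_pop = beta, se_beta_pop = sqrt(vb))
}

#' Write summary statistics to a tab-delimited file
#'
#' One row per SNP with columns `chrom`, `snp_id`, `pos_bp`, `allele0`,
#' `allele1`, `freq`, per-parameter `est_*`/`se_*` columns, the lower triangle
#' of the sampling covariance as `cov_<a>_<b>` columns, `beta_pop`,
#' `se_beta_pop` and `n_eff`. Parameters a row does not carry are written as
#' `NA`. `beta_pop` is (re)derived from the stored estimates.
#'
#' @param sumstats Tibble of summary-statistic rows (see [family_gwas()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  s <- as_tibble(sumstats)
  meta <- c("chrom", "snp_id", "pos_bp", "allele0", "allele1", "freq")
  for (col in meta) if (!col %in% names(s)) s[[col]] <- NA
  labs <- sumstat_labels
  for (l in labs) {
    for (pre in c("est_", "se_")) {
      if (!paste0(pre, l) %in% names(s)) s[[paste0(pre, l)]] <- NA_real_
    }
  }
  covcols <- character(0)
  for (i in seq_along(labs)) for (j in seq_len(i - 1)) {
    col <- paste0("cov_", labs[j], "_", labs[i])
    alt <- paste0("cov_", labs[i], "_", labs[j])
    if (!col %in% names(s)) s[[col]] <- if (alt %in% names(s)) s[[alt]] else NA_real_
    covcols <- c(covcols, col)
  }
  bp <- do.call(rbind, c(list(matrix(numeric(0), 0, 2)),
                         lapply(seq_len(nrow(s)), function(i) derive_beta_pop(s[i, ]))))
  s$beta_pop <- bp[, 1]
  s$se_beta_pop <- bp[, 2]
  if (!"n_eff" %in% names(s)) s$n_eff <- NA_real_
  if (!"cov_delta_beta" %in% names(s)) s$cov_delta_beta <- NA_real_
  out <- s[, c(meta, as.vector(rbind(paste0("est_", labs), paste0("se_", labs))),
               covcols, "beta_pop", "se_beta_pop", "cov_delta_beta", "n_eff")]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read summary statistics written by [write_sumstats()]
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_sumstats <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c(chrom = "character", snp_id = "character")))
}

#' Write IBD segments to a BED-like file
#'
#' Half-open `[start_bp, end_bp)` intervals, one per segment, with columns
#' `sib1`, `sib2`, `chrom`, `start_bp`, `end_bp`, `state`; a header comment
#' documents the coordinate convention.
#'
#' @param segments Tibble of segments (see [infer_ibd()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#sib1\tsib2\tchrom\tstart_bp\tend_bp(half-open)\tstate", con)
  write.table(segments[, c("sib1", "sib2", "chrom", "start_bp", "end_bp", "state")],
              con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read IBD segments written by [write_ibd_segments()]
#'
#' @param path Path to the file.
#' @return A tibble of segments.
#' @export
read_ibd_segments <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                  col.names = c("sib1", "sib2", "chrom", "start_bp", "end_bp", "state"),
                  colClasses = c("character", "character", "character",
                                 "integer", "integer", "integer"))
  as_tibble(x)
}
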