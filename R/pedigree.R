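# Nuclear-family construction and the genotype-observation-pattern taxonomy.

design_classes <- c("PROBAND_ONLY", "SIB_PAIRS_NO_PARENTS", "ONE_PARENT_ONE_OFFSPRING",
                    "ONE_PARENT_MULTI_SIB", "TRIO", "QUAD_BOTH_PARENTS_SIBS",
                    "BOTH_PARENTS_ONE_OFFSPRING", "NOT_IMPUTABLE")

# Exact joint distribution of (g_p, g_m, g_1, ..., g_n) for a nuclear family
# under Hardy-Weinberg equilibrium at frequency f and Mendelian transmission.
family_joint_dist <- function(f, n_sibs = 2) {
  stopifnot(f > 0, f < 1)
  hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  trans <- function(g) c(1 - g / 2, g / 2)  # P(transmitted allele = 0 / 1)
  grids <- c(list(gp = 0:2, gm = 0:2), setNames(rep(list(0:2), n_sibs),
                                                paste0("g", seq_len(n_sibs))))
  d <- expand.grid(grids)
  child_prob <- function(gc, gp, gm) {
    # P(child genotype | parents): convolution of the two transmissions
    tp <- trans(gp); tm <- trans(gm)
    p <- c(tp[1] * tm[1], tp[1] * tm[2] + tp[2] * tm[1], tp[2] * tm[2])
    p[gc + 1]
  }
  prob <- hwe[d$gp + 1] * hwe[d$gm + 1]
  for (j in seq_len(n_sibs)) {
    prob <- prob * mapply(child_prob, d[[paste0("g", j)]], d$gp, d$gm)
  }
  d$prob <- prob
  as_tibble(d[d$prob > 0, ])
}

#' Decide whether a missing-parent imputation is nonlinear
#'
#' A genotype-observation pattern admits a nonlinear imputation when the
#' conditional expectation of the missing parental genotype(s) given the
#' observed data differs from the best linear predictor of it. The observed
#' data are the flagged genotype slots plus, when both offspring are
#' genotyped, their IBD state (which the imputation always conditions on).
#' Decided by exact enumeration of parental alleles and transmissions under
#' Hardy-Weinberg equilibrium at frequency `freq`.
#'
#' @param offspring1_genotyped,offspring2_genotyped,father_genotyped,mother_genotyped
#'   Logical flags of the canonical two-offspring observation pattern.
#' @param freq Frequency of allele "1", in (0, 1).
#' @return `TRUE` iff the imputation of the missing parental genotype(s) is a
#'   nonlinear function of the observed data. Patterns with both parents
#'   observed (nothing to impute) return `FALSE`.
#' @export
classify_nonlinear <- function(offspring1_genotyped, offspring2_genotyped,
                               father_genotyped, mother_genotyped, freq = 0.5) {
  stopifnot(freq > 0, freq < 1)
  flags <- c(offspring1_genotyped, offspring2_genotyped,
             father_genotyped, mother_genotyped)
  if (!any(flags)) abort("at least one member must be genotyped")
  if (father_genotyped && mother_genotyped) return(FALSE)
  # enumeration over parental alleles and both siblings' transmissions
  d <- expand.grid(p1 = 0:1, p2 = 0:1, m1 = 0:1, m2 = 0:1,
                   tp1 = 1:2, tm1 = 1:2, tp2 = 1:2, tm2 = 1:2)
  w <- apply(d[, 1:4], 1, function(a) prod(ifelse(a == 1, freq, 1 - freq))) / 16
  d$g1 <- ifelse(d$tp1 == 1, d$p1, d$p2) + ifelse(d$tm1 == 1, d$m1, d$m2)
  d$g2 <- ifelse(d$tp2 == 1, d$p1, d$p2) + ifelse(d$tm2 == 1, d$m1, d$m2)
  d$ibd <- (d$tp1 == d$tp2) + (d$tm1 == d$tm2)
  d$gp <- d$p1 + d$p2; d$gm <- d$m1 + d$m2
  slots <- c("g1", "g2", "gp", "gm")[flags]
  if (flags[1] && flags[2]) slots <- c(slots, "ibd")
  target <- rowSums(d[, c("gp", "gm")[!flags[3:4]], drop = FALSE])
  obs <- d[, slots, drop = FALSE]
  key <- do.call(paste, c(obs, sep = ","))
  cond <- tapply(w * target, key, sum) / tapply(w, key, sum)
  # best linear predictor from the same enumerated moments
  X <- cbind(1, as.matrix(obs))
  XtWX <- crossprod(X, X * w)
  XtWy <- crossprod(X, w * target)
  blp <- drop(X %*% solve(XtWX, XtWy))
  max(abs(cond[key] - blp)) > 1e-9
}

#' Enumerate the 15 genotype-observation patterns
#'
#' All nonempty subsets of the four canonical genotype slots of a two-offspring
#' nuclear family (offspring 1, offspring 2, father, mother), each tagged with
#' whether a nonlinear imputation of the missing parental genotype(s) is
#' possible.
#'
#' @param freq Allele-1 frequency used for the nonlinearity classification.
#' @return Tibble with 15 rows and columns `offspring1_genotyped`,
#'   `offspring2_genotyped`, `father_genotyped`, `mother_genotyped`,
#'   `nonlinear_imputable`.
#' @export
enumerate_patterns <- function(freq = 0.5) {
  g <- expand.grid(offspring1_genotyped = c(FALSE, TRUE),
                   offspring2_genotyped = c(FALSE, TRUE),
                   father_genotyped = c(FALSE, TRUE),
                   mother_genotyped = c(FALSE, TRUE))
  g <- as_tibble(g[rowSums(g) > 0, ])
  g$nonlinear_imputable <- pmap(g, function(offspring1_genotyped, offspring2_genotyped,
                                            father_genotyped, mother_genotyped) {
    classify_nonlinear(offspring1_genotyped, offspring2_genotyped,
                       father_genotyped, mother_genotyped, freq)
  }) |> unlist()
  g
}

check_pedigree_acyclic <- function(ped) {
  parent_of <- rbind(
    data.frame(child = ped$individual_id, parent = ped$father_id),
    data.frame(child = ped$individual_id, parent = ped$mother_id))
  parent_of <- parent_of[!is.na(parent_of$parent), ]
  if (any(parent_of$child == parent_of$parent)) abort("individual is its own parent")
  # walk up from every individual; pedigree depth is tiny
  up <- split(parent_of$parent, parent_of$child)
  for (id in names(up)) {
    seen <- character(0)
    frontier <- up[[id]]
    while (length(frontier)) {
      if (id %in% frontier) abort(sprintf("pedigree cycle involving %s", id))
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(up[frontier], use.names = FALSE), seen)
    }
  }
  invisible(TRUE)
}

classify_family <- function(n_gen_off, father_gen, mother_gen) {
  n_par <- father_gen + mother_gen
  if (n_gen_off == 0) return("NOT_IMPUTABLE")
  if (n_par == 2) return(if (n_gen_off == 1) "TRIO" else "QUAD_BOTH_PARENTS_SIBS")
  if (n_par == 1) return(if (n_gen_off == 1) "ONE_PARENT_ONE_OFFSPRING" else "ONE_PARENT_MULTI_SIB")
  if (n_gen_off == 1) "PROBAND_ONLY" else "SIB_PAIRS_NO_PARENTS"
}

#' Build nuclear-family units from a pedigree
#'
#' Groups offspring by their (father, mother) couple, flags genotyped and
#' phenotyped members, and assigns each family its design class (the
#' missing-data taxonomy driving imputation and regression design). Offspring
#' listed with conflicting parents are skipped with a warning; half-siblings
#' (a parent shared across couples) trigger a warning and remain in separate
#' nuclear families. When genotypes are supplied, monozygotic twins /
#' duplicates (genotype discordance below 0.1% over at least 1,000 SNPs) are
#' flagged and one member of each pair is dropped from the genotyped offspring.
#'
#' @param ped Pedigree tibble (see [read_pedigree()]).
#' @param genotyped_ids Character vector of genotyped individual IDs.
#' @param geno Optional [phased_geno()] used for duplicate detection.
#' @param phenotyped_ids Optional character vector; defaults to individuals
#'   with a non-missing `phenotype` in `ped`.
#' @return Tibble with one row per family: parent IDs, list-columns of
#'   offspring IDs and flags, counts, `design_class` and
#'   `nonlinear_imputable`.
#' @export
build_families <- function(ped, genotyped_ids, geno = NULL, phenotyped_ids = NULL) {
  check_pedigree_acyclic(ped)
  if (is.null(phenotyped_ids)) {
    phenotyped_ids <- ped$individual_id[!is.na(ped$phenotype)]
  }
  dup <- ped |> count(.data$individual_id) |> filter(.data$n > 1)
  conflicted <- character(0)
  if (nrow(dup) > 0) {
    for (id in dup$individual_id) {
      rows <- ped[ped$individual_id == id, c("father_id", "mother_id")]
      if (nrow(unique(rows)) > 1) conflicted <- c(conflicted, id)
    }
    if (length(conflicted)) {
      warn(sprintf("offspring with conflicting parents skipped: %s",
                   paste(conflicted, collapse = ", ")))
    }
  }
  off <- ped |>
    filter(!is.na(.data$father_id) | !is.na(.data$mother_id),
           !.data$individual_id %in% conflicted) |>
    distinct(.data$individual_id, .keep_all = TRUE)
  if (nrow(off) == 0) return(tibble())
  # half-sib warning: a parent appearing in more than one couple
  couples <- off |> distinct(.data$father_id, .data$mother_id)
  for (side in c("father_id", "mother_id")) {
    shared <- couples[[side]][!is.na(couples[[side]])]
    shared <- unique(shared[duplicated(shared)])
    if (length(shared)) {
      warn(sprintf("half-siblings through parent(s) %s kept in separate nuclear families",
                   paste(shared, collapse = ", ")))
    }
  }
  fams <- off |>
    mutate(family_id = paste(coalesce(.data$father_id, "0"),
                             coalesce(.data$mother_id, "0"), sep = "_")) |>
    group_by(.data$family_id, .data$father_id, .data$mother_id) |>
    summarise(offspring_ids = list(.data$individual_id), .groups = "drop")

  gset <- as.character(genotyped_ids)
  if (!is.null(geno)) {
    gset <- drop_mz_duplicates(fams, gset, geno)
  }
  fams <- fams |>
    mutate(
      offspring_genotyped = map(.data$offspring_ids, ~ .x %in% gset),
      offspring_phenotyped = map(.data$offspring_ids, ~ .x %in% phenotyped_ids),
      n_offspring = map_int(.data$offspring_ids, length),
      n_genotyped_offspring = map_int(.data$offspring_genotyped, sum),
      father_genotyped = !is.na(.data$father_id) & .data$father_id %in% gset,
      mother_genotyped = !is.na(.data$mother_id) & .data$mother_id %in% gset,
      design_class = pmap(list(.data$n_genotyped_offspring, .data$father_genotyped,
                               .data$mother_genotyped), classify_family) |> unlist()) |>
    arrange(.data$family_id)
  # nonlinearity flag via a lookup over the distinct observation patterns
  pat <- fams |>
    distinct(n = pmin(.data$n_genotyped_offspring, 2L), fg = .data$father_genotyped,
             mg = .data$mother_genotyped) |>
    mutate(nonlinear_imputable = pmap_lgl(
      list(.data$n, .data$fg, .data$mg),
      function(n, fg, mg) {
        if ((fg && mg) || (n == 0 && fg + mg <= 1)) return(FALSE)
        classify_nonlinear(n >= 1, n >= 2, fg, mg, 0.3)
      }))
  fams |>
    mutate(n = pmin(.data$n_genotyped_offspring, 2L), fg = .data$father_genotyped,
           mg = .data$mother_genotyped) |>
    left_join(pat, by = c("n", "fg", "mg")) |>
    select(-"n", -"fg", -"mg")
}

# Flag MZ twins / duplicated samples among genotyped siblings and drop one of
# each pair from the genotyped set (discordance < 0.1% over >= 1,000 SNPs).
drop_mz_duplicates <- function(fams, gset, geno) {
  g <- genotypes(geno)
  dropped <- character(0)
  for (i in seq_len(nrow(fams))) {
    sibs <- intersect(fams$offspring_ids[[i]], intersect(gset, geno$ids))
    if (length(sibs) < 2) next
    for (a in seq_along(sibs)) for (b in seq_len(a - 1)) {
      ga <- g[sibs[a], ]; gb <- g[sibs[b], ]
      ok <- !is.na(ga) & !is.na(gb)
      if (sum(ok) >= 1000 && mean(ga[ok] != gb[ok]) < 0.001) {
        dropped <- c(dropped, sibs[a])
      }
    }
  }
  if (length(dropped)) {
    inform(sprintf("dropping %d monozygotic-twin/duplicate sample(s): %s",
                   length(dropped), paste(unique(dropped), collapse = ", ")))
  }
  setdiff(gset, dropped)
}
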