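#' Simulated cohorts and individuals
#'
#' A `sim_cohort` couples an individual-level table (`info`: pedigree fields
#' plus `cytotype`, `breeding_value` and `phenotype`) with a genotype array of
#' dimension `n_loci x ploidy x n`. Every individual carries exactly `ploidy`
#' allele copies per locus at every stage of a simulation.
#'
#' @param info Tibble of individual records.
#' @param geno Integer array `n_loci x ploidy x n` of allele codes.
#' @return A `sim_cohort` object.
#' @export
sim_cohort <- function(info, geno) {
  info <- tibble::as_tibble(info)
  if (length(dim(geno)) != 3 || dim(geno)[3] != nrow(info)) {
    rlang::abort("genotype array must be n_loci x ploidy x n_individuals",
      class = "ploidysel_error_bad_argument"
    )
  }
  structure(list(info = info, geno = geno), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(
    "<sim_cohort> ", nrow(x$info), " individuals, ploidy ", dim(x$geno)[2],
    ", ", dim(x$geno)[1], " loci\n",
    sep = ""
  )
  invisible(x)
}

cohort_subset <- function(cohort, idx) {
  sim_cohort(cohort$info[idx, , drop = FALSE], cohort$geno[, , idx, drop = FALSE])
}

#' Extract one individual from a cohort
#'
#' @param cohort A [sim_cohort()].
#' @param i Row index or id.
#' @return A `sim_individual`: the info fields as a list plus `genotype`
#'   (an `n_loci x ploidy` matrix).
#' @export
cohort_individual <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$info$id)
  ind <- as.list(cohort$info[i, ])
  ind$genotype <- cohort$geno[, , i, drop = TRUE]
  structure(ind, class = "sim_individual")
}

#' Found a base population of maternal families
#'
#' Draws `n_families` unobserved dams with Hardy-Weinberg genotypes at the
#' architecture's founder allele frequencies and, for each, `n_per_family`
#' offspring formed from one dam gamete plus one gamete drawn from the
#' population allele pool (open pollination), so family members are maternal
#' half sibs by default. With `full_sib = TRUE` each family also shares a
#' single drawn sire. The dams themselves are not part of the returned
#' cohort: base individuals are recorded as pedigree founders with unknown
#' parents, carrying only their maternal family label (the analysis treats
#' maternal families as unrelated and fully outcrossed).
#'
#' @param arch A [genetic_architecture()].
#' @param n_families Number of maternal families (>= 1).
#' @param n_per_family Individuals per family.
#' @param ploidy 2 or 4.
#' @param cytotype Cytotype label; defaults to `"diploid"` for ploidy 2 and
#'   `"tetraploid"` for ploidy 4.
#' @param line Line label recorded for the base cohort (default `"base"`).
#' @param full_sib Share the sire within each family as well.
#' @param neo_founders For ploidy-4 cohorts: `"hwe"` draws founder alleles at
#'   Hardy-Weinberg tetrasomic frequencies; `"doubled"` draws diploid dams
#'   and pollen and doubles every genotype at synthesis
#'   ([synthesize_neotetraploid()]), as in colchicine conversion.
#' @param id_prefix Prefix for generated ids.
#' @return A [sim_cohort()] of `n_families * n_per_family` founders with
#'   phenotypes assigned at generation 0.
#' @export
found_base_population <- function(arch, n_families, n_per_family, ploidy,
                                  cytotype = NULL, line = "base",
                                  full_sib = FALSE,
                                  neo_founders = c("hwe", "doubled"),
                                  id_prefix = "B") {
  neo_founders <- match.arg(neo_founders)
  if (n_families < 1 || n_per_family < 1) {
    rlang::abort("family counts must be >= 1", class = "ploidysel_error_bad_argument")
  }
  if (!ploidy %in% c(2L, 4L)) {
    rlang::abort("ploidy must be 2 or 4", class = "ploidysel_error_bad_argument")
  }
  if (is.null(cytotype)) cytotype <- if (ploidy == 2) "diploid" else "tetraploid"
  L <- arch$n_loci
  draw_ploidy <- if (ploidy == 4L && neo_founders == "doubled") 2L else as.integer(ploidy)
  n <- n_families * n_per_family
  alpha <- if (draw_ploidy == 2L) 0 else arch$double_reduction

  dams <- draw_hwe_genotypes(arch, n_families, draw_ploidy)
  geno <- array(0L, c(L, draw_ploidy, n))
  half <- draw_ploidy %/% 2L
  for (f in seq_len(n_families)) {
    idx <- (f - 1L) * n_per_family + seq_len(n_per_family)
    dam_gam <- gametes_batch(dams[, , f, drop = TRUE], n_per_family, alpha)
    if (full_sib) {
      sire <- draw_hwe_genotypes(arch, 1L, draw_ploidy)[, , 1, drop = TRUE]
      pollen <- gametes_batch(sire, n_per_family, alpha)
    } else {
      # open pollination: pollen gametes straight from the allele pool
      pollen <- array(draw_alleles(arch, L * half * n_per_family), c(L, half, n_per_family))
    }
    geno[, seq_len(half), idx] <- dam_gam
    geno[, half + seq_len(half), idx] <- pollen
  }
  if (ploidy == 4L && neo_founders == "doubled") {
    geno <- geno[, c(1L, 2L, 1L, 2L), , drop = FALSE]
  }
  fam <- rep(paste0(id_prefix, "F", seq_len(n_families)), each = n_per_family)
  info <- tibble::tibble(
    id = paste0(id_prefix, seq_len(n)),
    dam = UNKNOWN_PARENT, sire = UNKNOWN_PARENT,
    maternal_family = fam, line = line, generation = 0L,
    ploidy = as.integer(ploidy), cytotype = cytotype, fertile = NA
  )
  cohort <- sim_cohort(info, geno)
  assign_phenotype_cohort(cohort, arch, generation = 0L)
}

draw_hwe_genotypes <- function(arch, n, ploidy) {
  L <- arch$n_loci
  array(draw_alleles(arch, L * ploidy * n), c(L, ploidy, n))
}

# iid allele draws at the founder frequencies, locus-major layout
draw_alleles <- function(arch, total) {
  L <- arch$n_loci
  p <- rep.int(arch$founder_allele_freq, total %/% L)
  ifelse(stats::runif(total) < p, 1L, 2L)
}

#' Double a diploid genotype into a neotetraploid one
#'
#' Models colchicine-induced genome doubling as exact duplication: every
#' allele's copy number is doubled (AB becomes AABB), deterministically, so
#' population allele frequencies are unchanged and no new alleles appear.
#'
#' @param g An `n_loci x 2` genotype matrix (or a `sim_individual` with one).
#' @return An `n_loci x 4` genotype matrix.
#' @export
synthesize_neotetraploid <- function(g) {
  if (inherits(g, "sim_individual")) g <- g$genotype
  g <- as.matrix(g)
  if (ncol(g) != 2) {
    rlang::abort("input genotype must be diploid (2 allele columns)",
      class = "ploidysel_error_ploidy_mismatch"
    )
  }
  g[, c(1L, 2L, 1L, 2L), drop = FALSE]
}

#' Draw a gamete from a genotype
#'
#' Disomic meiosis (ploidy 2) draws one of the two alleles per locus;
#' tetrasomic meiosis (ploidy 4) draws two distinct alleles per locus
#' uniformly (random chromosome segregation) and, with probability `alpha`,
#' replaces the pair with two copies of a single uniformly chosen parental
#' allele (double reduction).
#'
#' @param g Genotype matrix `n_loci x ploidy` (or a `sim_individual`).
#' @param alpha Double-reduction probability in `[0, 1/6]`; must be 0 for
#'   diploids.
#' @param n Number of gametes.
#' @return For `n = 1` an `n_loci x ploidy/2` matrix; otherwise an
#'   `n_loci x ploidy/2 x n` array.
#' @export
make_gamete <- function(g, alpha = 0, n = 1) {
  if (inherits(g, "sim_individual")) g <- g$genotype
  g <- as.matrix(g)
  if (alpha < 0 || alpha > 1 / 6) {
    rlang::abort("alpha must lie in [0, 1/6]", class = "ploidysel_error_bad_alpha")
  }
  if (ncol(g) == 2 && alpha > 0) {
    rlang::abort("double reduction is undefined for diploid meiosis",
      class = "ploidysel_error_bad_alpha"
    )
  }
  out <- gametes_batch(g, n, alpha)
  if (n == 1) out[, , 1, drop = TRUE] else out
}

# vectorised gamete engine: returns n_loci x ploidy/2 x n
gametes_batch <- function(g, n, alpha) {
  L <- nrow(g)
  P <- ncol(g)
  if (!P %in% c(2L, 4L)) {
    rlang::abort("ploidy must be 2 or 4", class = "ploidysel_error_ploidy_mismatch")
  }
  rows <- rep.int(seq_len(L), n)
  if (P == 2L) {
    pick <- sample.int(2L, L * n, replace = TRUE)
    return(array(g[rows + (pick - 1L) * L], c(L, 1L, n)))
  }
  first <- sample.int(4L, L * n, replace = TRUE)
  step <- sample.int(3L, L * n, replace = TRUE)
  second <- ((first - 1L + step) %% 4L) + 1L
  if (alpha > 0) {
    dr <- stats::runif(L * n) < alpha
    second[dr] <- first[dr]
  }
  out <- array(0L, c(L, 2L, n))
  out[, 1L, ] <- g[rows + (first - 1L) * L]
  out[, 2L, ] <- g[rows + (second - 1L) * L]
  out
}

#' Cross two individuals
#'
#' Unites one gamete from each parent. Parents must share a ploidy and be
#' distinct individuals (the experiment's crossing scheme excludes selfing).
#'
#' @param dam,sire `sim_individual`s (or lists with `id` and `genotype`).
#' @param alpha Double-reduction probability for tetrasomic meiosis.
#' @return Offspring genotype matrix `n_loci x ploidy`.
#' @export
cross <- function(dam, sire, alpha = 0) {
  if (!is.null(dam$id) && !is.null(sire$id) && identical(dam$id, sire$id)) {
    rlang::abort("cannot self an individual", class = "ploidysel_error_selfing")
  }
  gd <- as.matrix(dam$genotype)
  gs <- as.matrix(sire$genotype)
  if (ncol(gd) != ncol(gs)) {
    rlang::abort("parents differ in ploidy", class = "ploidysel_error_ploidy_mismatch")
  }
  cbind(
    gametes_batch(gd, 1L, alpha)[, , 1, drop = TRUE],
    gametes_batch(gs, 1L, alpha)[, , 1, drop = TRUE]
  )
}

# genetic values under the architecture's dosage scale
breeding_values <- function(geno, arch) {
  d <- dim(geno)
  L <- d[1]
  P <- d[2]
  n <- d[3]
  eff <- arch$allele_effects
  vals <- eff[rep.int(seq_len(L), P * n) + (as.integer(geno) - 1L) * L]
  s <- if (arch$dosage_scale == "ploidy_standardized") 2 / P else 1
  s * colSums(matrix(vals, L * P, n))
}

#' Assign a phenotype to an individual
#'
#' Phenotype (days to first flower) is the cytotype baseline plus the
#' generation's environmental block, the dosage-scaled genetic value, and a
#' Normal(0, `env_sd`) residual. Sterility is an independent Bernoulli draw
#' at the cytotype's base rate for generation 0 and the later-generation
#' rate afterwards.
#'
#' @param ind A `sim_individual` (needs `genotype`, `ploidy`, `cytotype`).
#' @param arch A [genetic_architecture()].
#' @param generation Generation number (0-based).
#' @return The individual with `breeding_value`, `phenotype` and `fertile`
#'   filled in.
#' @export
assign_phenotype <- function(ind, arch, generation) {
  g <- array(as.matrix(ind$genotype), c(nrow(ind$genotype), ncol(ind$genotype), 1L))
  bv <- breeding_values(g, arch)
  cyt <- ind$cytotype %||% if (ncol(ind$genotype) == 2) "diploid" else "tetraploid"
  ind$breeding_value <- bv
  ind$phenotype <- unname(arch$ploidy_baseline[cyt]) + gen_env_at(arch, generation) +
    bv + stats::rnorm(1, 0, arch$env_sd)
  ind$fertile <- stats::runif(1) >= sterility_at(arch, cyt, generation)
  ind
}

assign_phenotype_cohort <- function(cohort, arch, generation) {
  n <- nrow(cohort$info)
  bv <- breeding_values(cohort$geno, arch)
  cyt <- cohort$info$cytotype
  base <- unname(arch$ploidy_baseline[cyt])
  ster <- vapply(cyt, function(cc) sterility_at(arch, cc, generation), numeric(1))
  cohort$info$breeding_value <- bv
  cohort$info$phenotype <- base + gen_env_at(arch, generation) + bv +
    stats::rnorm(n, 0, arch$env_sd)
  cohort$info$fertile <- stats::runif(n) >= ster
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
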