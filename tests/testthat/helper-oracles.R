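# Independent oracles and fixture builders used across the test files.

# quick pedigree constructor from parallel vectors
ped_build <- function(id, dam, sire, generation,
                      family = id, line = "L", ploidy = 2, fertile = TRUE) {
  pedigree(data.frame(
    id = id, dam = dam, sire = sire, maternal_family = family,
    line = line, generation = generation, ploidy = ploidy, fertile = fertile
  ))
}

# Gene-dropping oracle for diploid pedigrees: founders get unique allele
# pairs, each individual inherits one uniformly chosen allele from each
# parent, and F is the fraction of drops in which the target's two alleles
# are identical by descent. Independent of the path-counting implementation.
gene_drop_F <- function(ped, target, n_drops = 1e5) {
  df <- as.data.frame(ped)
  # restrict the drop to the target's ancestor closure
  anc <- target
  repeat {
    parents <- setdiff(unique(c(
      df$dam[df$id %in% anc], df$sire[df$id %in% anc]
    )), "0")
    new <- setdiff(parents, anc)
    if (length(new) == 0) break
    anc <- c(anc, new)
  }
  df <- df[df$id %in% anc, ]
  df <- df[order(df$generation), ]
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  next_allele <- 0L
  for (i in seq_len(n)) {
    dam <- df$dam[i]
    sire <- df$sire[i]
    if (dam == "0") {
      a1[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      j <- idx[[dam]]
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[j, ], a2[j, ])
    }
    if (sire == "0") {
      a2[i, ] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      j <- idx[[sire]]
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[j, ], a2[j, ])
    }
  }
  t <- idx[[target]]
  mean(a1[t, ] == a2[t, ])
}

# Exhaustive enumeration of tetrasomic gamete probabilities for one locus:
# all 6 unordered draws of 2 distinct alleles from the 4 copies, plus the
# double-reduction branch (probability alpha, two copies of one uniformly
# chosen allele). Returns probabilities named by sorted allele pair.
enumerate_gamete_probs <- function(alleles, alpha = 0) {
  stopifnot(length(alleles) == 4)
  pair_label <- function(x, y) paste(sort(c(x, y)), collapse = "/")
  probs <- c()
  add <- function(label, p) {
    probs[label] <<- (if (label %in% names(probs)) probs[[label]] else 0) + p
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      add(pair_label(alleles[i], alleles[j]), (1 - alpha) / 6)
    }
  }
  if (alpha > 0) {
    for (i in 1:4) add(pair_label(alleles[i], alleles[i]), alpha / 4)
  }
  probs[probs > 0]
}

# label observed gametes (2 x n matrix of a locus' gamete alleles)
gamete_labels <- function(g2) {
  apply(g2, 2, function(x) paste(sort(x), collapse = "/"))
}

# hand-sized cohort with explicit phenotypes/families and dummy genotypes
manual_cohort <- function(phenotype, family = as.character(seq_along(phenotype)),
                          fertile = TRUE, ploidy = 2, line = "L", generation = 0) {
  n <- length(phenotype)
  info <- tibble::tibble(
    id = paste0("m", seq_len(n)),
    dam = "0", sire = "0",
    maternal_family = as.character(family),
    line = line, generation = as.integer(generation),
    ploidy = as.integer(ploidy), cytotype = "diploid",
    fertile = rep_len(fertile, n),
    breeding_value = 0, phenotype = phenotype
  )
  sim_cohort(info, array(1L, c(1, ploidy, n)))
}

# compact diploid design used where a full experiment-sized run would be slow
mini_diploid_design <- function() {
  design_config(
    base_families = 30, M = 12, k = 3, generations = 3,
    n_offspring = 4, final_n_offspring = 2, final_families = 10,
    cytotype = "diploid", line_prefix = "D"
  )
}
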