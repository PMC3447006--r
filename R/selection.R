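#' Truncation selection on flowering time
#'
#' Returns the `M` earliest-flowering fertile individuals subject to at most
#' one per maternal family: walking down the flowering-rank order, an
#' individual whose family is already represented is skipped and the
#' next-ranked plant takes its place. Ties in flowering time are broken by
#' the run's seeded random stream.
#'
#' @param cohort A [sim_cohort()].
#' @param M Number to select.
#' @param one_per_family Apply the family restriction (default `TRUE`).
#' @return The selected subset as a [sim_cohort()], with the selected row
#'   indices in attribute `"indices"`.
#' @export
truncation_select <- function(cohort, M, one_per_family = TRUE) {
  info <- cohort$info
  eligible <- which(info$fertile)
  if (length(eligible) < M) {
    rlang::abort(
      paste0("only ", length(eligible), " fertile individuals for M = ", M),
      class = "ploidysel_error_insufficient"
    )
  }
  ord <- eligible[order(info$phenotype[eligible], stats::runif(length(eligible)))]
  picked <- select_walk(ord, info$maternal_family, M, one_per_family)
  if (length(picked) < M) {
    rlang::abort(
      paste0("fewer than M = ", M, " maternal families among fertile individuals"),
      class = "ploidysel_error_insufficient"
    )
  }
  out <- cohort_subset(cohort, picked)
  attr(out, "indices") <- picked
  out
}

# walk an ordered index vector taking at most one individual per family
select_walk <- function(ord, family, M, one_per_family) {
  if (!one_per_family) {
    return(ord[seq_len(min(M, length(ord)))])
  }
  picked <- integer(0)
  seen <- character(0)
  for (i in ord) {
    f <- family[i]
    if (!f %in% seen) {
      picked <- c(picked, i)
      seen <- c(seen, f)
      if (length(picked) == M) break
    }
  }
  picked
}

# control-line "selection": a random fertile draw under the same family rule
random_select <- function(cohort, M, one_per_family = TRUE) {
  info <- cohort$info
  eligible <- which(info$fertile)
  if (length(eligible) < M) {
    rlang::abort(
      paste0("only ", length(eligible), " fertile individuals for M = ", M),
      class = "ploidysel_error_insufficient"
    )
  }
  ord <- sample(eligible)
  picked <- select_walk(ord, info$maternal_family, M, one_per_family)
  if (length(picked) < M) {
    rlang::abort(
      paste0("fewer than M = ", M, " maternal families among fertile individuals"),
      class = "ploidysel_error_insufficient"
    )
  }
  out <- cohort_subset(cohort, picked)
  attr(out, "indices") <- picked
  out
}

#' Reciprocal crossing design among selected parents
#'
#' Pairs each of the `M` selected parents with exactly `k` distinct
#' non-relative partners within the line, yielding `M * k / 2` parent pairs;
#' each pair later produces one seed family with a randomly chosen
#' dam/sire orientation (the reciprocal orientation is the discarded member
#' of the seed-family pair). The design is built as a circulant pairing on a
#' randomly shuffled parent order (offsets `1..k/2`, plus the antipodal
#' matching when `k` is odd) and reshuffled until no paired parents are
#' relatives.
#'
#' @param selected A [sim_cohort()] of selected parents (or a character
#'   vector of ids present in `ped`).
#' @param k Partners per parent (>= 1; `M * k` must be even).
#' @param ped A [pedigree()] used for the relatedness checks.
#' @param relative_depth Generations searched when testing relatedness
#'   between prospective mates. The default 1 excludes parent-offspring and
#'   (half-)sib matings, the practical reading of crossing "non-relatives"
#'   in a closed line where all members eventually share distant ancestors.
#' @param max_tries Construction budget per component before giving up.
#' @return A tibble with columns `a`, `b` (parent ids), one row per pair.
#' @export
crossing_design <- function(selected, k, ped = NULL, relative_depth = 1,
                            max_tries = 400) {
  ids <- if (inherits(selected, "sim_cohort")) selected$info$id else as.character(selected)
  M <- length(ids)
  if (k < 1 || k >= M) {
    rlang::abort("need 1 <= k < M", class = "ploidysel_error_bad_argument")
  }
  if ((M * k) %% 2 != 0 || (k %% 2 == 1 && M %% 2 != 0)) {
    rlang::abort("M * k must be even (and M even when k is odd)",
      class = "ploidysel_error_bad_argument"
    )
  }
  forbidden <- matrix(FALSE, M, M)
  if (!is.null(ped)) {
    assert_ped_id(ped, ids)
    ctx <- ped_context(ped)
    anc <- lapply(ids, function(one) ancestor_set(ctx, ctx$idx[[one]], relative_depth))
    for (i in seq_len(M - 1)) {
      for (j in seq(i + 1, M)) {
        if (length(intersect(anc[[i]], anc[[j]])) > 0) {
          forbidden[i, j] <- forbidden[j, i] <- TRUE
        }
      }
    }
  }
  # the design decomposes into k %/% 2 Hamiltonian cycles (two partners each)
  # plus, for odd k, one perfect matching (one partner); components are drawn
  # independently and must avoid forbidden pairs and one another's edges
  used <- matrix(FALSE, M, M)
  ai <- integer(0)
  bi <- integer(0)
  add_edges <- function(x, y) {
    ai <<- c(ai, x)
    bi <<- c(bi, y)
    used[cbind(x, y)] <<- TRUE
    used[cbind(y, x)] <<- TRUE
  }
  fail <- function() {
    rlang::abort(
      paste0(
        "no ", k, "-regular non-relative crossing design found in ",
        max_tries, " tries"
      ),
      class = "ploidysel_error_no_design"
    )
  }
  for (comp in seq_len(k %/% 2)) {
    cyc <- design_cycle(M, forbidden | used, max_tries)
    if (is.null(cyc)) fail()
    add_edges(cyc, cyc[c(seq(2, M), 1L)])
  }
  if (k %% 2 == 1) {
    mt <- design_matching(M, forbidden | used, max_tries)
    if (is.null(mt)) fail()
    add_edges(mt[, 1], mt[, 2])
  }
  tibble::tibble(a = ids[ai], b = ids[bi])
}

# random Hamiltonian cycle avoiding blocked edges, with 2-opt conflict repair
design_cycle <- function(M, blocked, max_tries) {
  for (try in seq_len(max_tries)) {
    perm <- sample(M)
    for (rep in seq_len(40 * M)) {
      nxt <- perm[c(seq(2, M), 1L)]
      bad <- which(blocked[cbind(perm, nxt)])
      if (length(bad) == 0) {
        return(perm)
      }
      i <- bad[sample.int(length(bad), 1)]
      j <- sample.int(M, 1)
      if (j == i) next
      # 2-opt: reverse the segment after i up to j; new edges (i,j), (i+1,j+1)
      lo <- min(i, j)
      hi <- max(i, j)
      cand <- perm
      cand[(lo + 1):hi] <- rev(cand[(lo + 1):hi])
      nxt2 <- cand[c(seq(2, M), 1L)]
      if (!any(blocked[cbind(cand, nxt2)][c(lo, hi)])) perm <- cand
    }
  }
  NULL
}

# random perfect matching avoiding blocked edges, with pair-swap repair
design_matching <- function(M, blocked, max_tries) {
  half <- M %/% 2
  for (try in seq_len(max_tries)) {
    perm <- sample(M)
    a <- perm[seq_len(half)]
    b <- perm[half + seq_len(half)]
    for (rep in seq_len(40 * M)) {
      bad <- which(blocked[cbind(a, b)])
      if (length(bad) == 0) {
        return(cbind(a, b))
      }
      i <- bad[sample.int(length(bad), 1)]
      j <- sample.int(half, 1)
      if (j == i) next
      # swap partners of pairs i and j
      tmp <- b[i]
      b[i] <- b[j]
      b[j] <- tmp
    }
  }
  NULL
}

#' Advance one generation from a crossing design
#'
#' For each retained pair one orientation (dam, sire) is chosen uniformly at
#' random to contribute a seed family of `n_offspring`; offspring genotypes
#' unite one gamete from each parent, phenotypes are assigned for the new
#' generation, and individuals die independently with probability
#' `mortality`.
#'
#' @param pairs Tibble from [crossing_design()] (columns `a`, `b`).
#' @param parents The [sim_cohort()] holding the paired parents.
#' @param arch A [genetic_architecture()].
#' @param generation Generation number of the offspring.
#' @param line Line label for the offspring.
#' @param n_offspring Seedlings reared per family.
#' @param mortality Independent death probability per seedling.
#' @param n_families If smaller than `nrow(pairs)`, that many pairs are
#'   sampled (without replacement) to contribute families; used for the
#'   final common-garden generation and the neotetraploid first round.
#' @return A [sim_cohort()] of surviving offspring.
#' @export
advance_generation <- function(pairs, parents, arch, generation, line,
                               n_offspring = 4, mortality = 0.1,
                               n_families = NULL) {
  if (nrow(pairs) == 0) {
    rlang::abort("no pairs to advance", class = "ploidysel_error_insufficient")
  }
  keep <- seq_len(nrow(pairs))
  if (!is.null(n_families) && n_families < nrow(pairs)) {
    keep <- sort(sample(keep, n_families))
  }
  idx <- match(c(pairs$a, pairs$b), parents$info$id)
  ai <- idx[seq_len(nrow(pairs))][keep]
  bi <- idx[nrow(pairs) + seq_len(nrow(pairs))][keep]
  swap <- stats::runif(length(keep)) < 0.5
  dam_i <- ifelse(swap, bi, ai)
  sire_i <- ifelse(swap, ai, bi)

  L <- arch$n_loci
  P <- dim(parents$geno)[2]
  alpha <- if (P == 2L) 0 else arch$double_reduction
  nf <- length(keep)
  n <- nf * n_offspring
  geno <- array(0L, c(L, P, n))
  half <- P %/% 2L
  for (f in seq_len(nf)) {
    cols <- (f - 1L) * n_offspring + seq_len(n_offspring)
    geno[, seq_len(half), cols] <-
      gametes_batch(parents$geno[, , dam_i[f], drop = TRUE], n_offspring, alpha)
    geno[, half + seq_len(half), cols] <-
      gametes_batch(parents$geno[, , sire_i[f], drop = TRUE], n_offspring, alpha)
  }
  fam_label <- paste0(line, "_g", generation, "_f", seq_len(nf))
  info <- tibble::tibble(
    id = paste0(line, "_g", generation, "_", seq_len(n)),
    dam = rep(parents$info$id[dam_i], each = n_offspring),
    sire = rep(parents$info$id[sire_i], each = n_offspring),
    maternal_family = rep(fam_label, each = n_offspring),
    line = line, generation = as.integer(generation),
    ploidy = as.integer(P),
    cytotype = parents$info$cytotype[1],
    fertile = NA
  )
  cohort <- assign_phenotype_cohort(sim_cohort(info, geno), arch, generation)
  survive <- which(stats::runif(n) >= mortality)
  cohort_subset(cohort, survive)
}
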