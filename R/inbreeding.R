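#' Wright's path-method inbreeding coefficient
#'
#' Computes F for one individual by enumerating, for every common ancestor A
#' of its parents, all pairs of ancestral paths (one from each parent up to A)
#' that share no individual other than A. Each such pair of paths contributes
#' \eqn{(1/2)^{n_1 + n_2 + 1} (1 + F_A)}, where \eqn{n_1} and \eqn{n_2} are
#' the path lengths in links from each parent to A and \eqn{F_A} is the
#' ancestor's own (recursively computed) inbreeding coefficient. Paths, not
#' ancestors, are deduplicated: several loops through one ancestor each
#' contribute a term.
#'
#' Transmission is treated as disomic for all ploidies, i.e. the classical
#' diploid path coefficients are applied to tetraploids as well; no
#' tetrasomic identity generalisation is attempted.
#'
#' @param ped A [pedigree()].
#' @param id Individual id (character scalar or vector; vectorised).
#' @return F in `[0, 1]`; exactly 0 for founders and non-inbred individuals.
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("a", "b", "s1", "s2", "x"),
#'   dam = c("0", "0", "a", "a", "s1"),
#'   sire = c("0", "0", "b", "b", "s2"),
#'   maternal_family = "A", line = "D1",
#'   generation = c(0, 0, 1, 1, 2), ploidy = 2, fertile = TRUE
#' ))
#' inbreeding_coefficient(ped, "x") # offspring of full sibs: 0.25
inbreeding_coefficient <- function(ped, id) {
  assert_ped_id(ped, id)
  ctx <- ped_context(ped)
  vapply(id, function(one) f_coef(ctx, ctx$idx[[one]]), numeric(1), USE.NAMES = length(id) > 1)
}

# Precomputed parent indices plus memo caches shared across queries.
ped_context <- function(ped) {
  idx <- ped_index(ped)
  dam <- ifelse(ped$dam == UNKNOWN_PARENT, 0L, idx[ped$dam])
  sire <- ifelse(ped$sire == UNKNOWN_PARENT, 0L, idx[ped$sire])
  list(
    idx = as.list(idx), dam = unname(dam), sire = unname(sire),
    f_cache = new.env(parent = emptyenv()),
    p_cache = new.env(parent = emptyenv())
  )
}

# All upward paths from node i: a list of integer vectors, each starting at i
# and ending at some ancestor (i itself included as the zero-length path).
upward_paths <- function(ctx, i) {
  key <- as.character(i)
  hit <- ctx$p_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  paths <- list(i)
  for (p in c(ctx$dam[i], ctx$sire[i])) {
    if (p > 0L) {
      paths <- c(paths, lapply(upward_paths(ctx, p), function(pp) c(i, pp)))
    }
  }
  ctx$p_cache[[key]] <- paths
  paths
}

f_coef <- function(ctx, i) {
  key <- as.character(i)
  hit <- ctx$f_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  d <- ctx$dam[i]
  s <- ctx$sire[i]
  f <- 0
  if (d > 0L && s > 0L) {
    dp <- upward_paths(ctx, d)
    sp <- upward_paths(ctx, s)
    d_end <- vapply(dp, function(p) p[length(p)], integer(1))
    s_end <- vapply(sp, function(p) p[length(p)], integer(1))
    for (a in intersect(d_end, s_end)) {
      fa <- f_coef(ctx, a)
      for (p1 in dp[d_end == a]) {
        for (p2 in sp[s_end == a]) {
          # paths may meet only at the common ancestor itself
          if (length(intersect(p1[-length(p1)], p2[-length(p2)])) == 0L) {
            n1 <- length(p1) - 1L
            n2 <- length(p2) - 1L
            f <- f + 0.5^(n1 + n2 + 1) * (1 + fa)
          }
        }
      }
    }
  }
  ctx$f_cache[[key]] <- f
  f
}

#' Do two individuals share an ancestor?
#'
#' `TRUE` iff `a` and `b` share any ancestor within `max_depth` generations,
#' or one is an ancestor of the other within that depth. The default depth
#' spans the entire known pedigree.
#'
#' @param ped A [pedigree()].
#' @param a,b Individual ids.
#' @param max_depth Number of generations searched upward (>= 1).
#' @return Logical scalar.
#' @export
are_relatives <- function(ped, a, b, max_depth = Inf) {
  assert_ped_id(ped, c(a, b))
  if (max_depth < 1) {
    rlang::abort("max_depth must be >= 1", class = "ploidysel_error_bad_argument")
  }
  ctx <- ped_context(ped)
  length(intersect(
    ancestor_set(ctx, ctx$idx[[a]], max_depth),
    ancestor_set(ctx, ctx$idx[[b]], max_depth)
  )) > 0
}

# self plus ancestors up to `depth` links away, as row indices
ancestor_set <- function(ctx, i, depth) {
  out <- i
  frontier <- i
  d <- 0
  while (length(frontier) > 0 && d < depth) {
    frontier <- unique(c(ctx$dam[frontier], ctx$sire[frontier]))
    frontier <- frontier[frontier > 0L]
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    d <- d + 1
  }
  out
}

#' Mean inbreeding coefficient of a line at a generation
#'
#' Arithmetic mean of [inbreeding_coefficient()] over the individuals of one
#' line in one generation. Sterile individuals are excluded by default,
#' mirroring the exclusion of sterile plants from all experiment summaries.
#'
#' @param ped A [pedigree()].
#' @param line Line label (e.g. `"D1"`).
#' @param generation Generation number.
#' @param fertile_only Restrict to fertile individuals (default `TRUE`).
#' @return Mean F (scalar).
#' @export
mean_line_inbreeding <- function(ped, line, generation, fertile_only = TRUE) {
  keep <- ped$line == line & ped$generation == generation
  if (fertile_only) keep <- keep & ped$fertile
  ids <- ped$id[keep]
  if (length(ids) == 0) {
    rlang::abort(
      paste0("no individuals in line ", line, " generation ", generation),
      class = "ploidysel_error_empty_selection"
    )
  }
  ctx <- ped_context(ped)
  mean(vapply(ids, function(one) f_coef(ctx, ctx$idx[[one]]), numeric(1)))
}
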