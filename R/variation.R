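#' Coefficient of variation of flowering time
#'
#' `100 * sd / mean`, with the sample (n - 1) standard deviation. Intended
#' to be computed on fertile individuals only.
#'
#' @param values Flowering times in days (n >= 2, positive mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    rlang::abort("need at least 2 values", class = "ploidysel_error_bad_argument")
  }
  m <- mean(values)
  if (m <= 0) {
    rlang::abort("mean must be positive for a CV", class = "ploidysel_error_bad_argument")
  }
  100 * stats::sd(values) / m
}

#' Noncentral-t confidence interval for a coefficient of variation
#'
#' Inverts the noncentral t distribution: with
#' \eqn{t_{obs} = \sqrt{n} / (cv/100)}, the noncentrality parameters
#' \eqn{\lambda_L > \lambda_U} are found such that \eqn{t_{obs}} is the
#' \eqn{(1-level)/2} and \eqn{(1+level)/2} quantile of the noncentral t with
#' `n - 1` degrees of freedom; the interval is
#' \eqn{(100\sqrt{n}/\lambda_L,\; 100\sqrt{n}/\lambda_U)}. The interval is
#' asymmetric, wider above the point estimate than below, and exact for
#' normally distributed data. Root finding uses expanding-bracket bisection
#' to a tolerance of 1e-8.
#'
#' @param cv CV in percent (> 0).
#' @param n Sample size (>= 2).
#' @param level Confidence level in (0, 1).
#' @return List with `lower_cl`, `upper_cl` (percent).
#' @export
#' @examples
#' cv_confidence_interval(7.9, 146)
cv_confidence_interval <- function(cv, n, level = 0.95) {
  if (cv <= 0 || n < 2 || level <= 0 || level >= 1) {
    rlang::abort("need cv > 0, n >= 2, 0 < level < 1",
      class = "ploidysel_error_bad_argument"
    )
  }
  t_obs <- sqrt(n) / (cv / 100)
  df <- n - 1
  lam_hi <- invert_ncp(t_obs, df, (1 - level) / 2) # large ncp -> lower CV bound
  lam_lo <- invert_ncp(t_obs, df, (1 + level) / 2) # small ncp -> upper CV bound
  list(
    lower_cl = 100 * sqrt(n) / lam_hi,
    upper_cl = 100 * sqrt(n) / lam_lo
  )
}

# solve pt(t_obs, df, ncp = lambda) = q for lambda; pt is strictly
# decreasing in the noncentrality parameter
invert_ncp <- function(t_obs, df, q, tol = 1e-8) {
  # pt() emits a precision note at extreme noncentrality; its accuracy is
  # far beyond the bisection tolerance used here
  f <- function(lam) suppressWarnings(stats::pt(t_obs, df, ncp = lam)) - q
  lo <- 0
  hi <- max(2 * t_obs, 1)
  f_lo <- f(lo)
  f_hi <- f(hi)
  tries <- 0
  while (f_hi > 0 && tries < 60) {
    lo <- hi
    f_lo <- f_hi
    hi <- hi * 2
    f_hi <- f(hi)
    tries <- tries + 1
  }
  if (f_lo < 0 || f_hi > 0) {
    rlang::abort("noncentrality root finding failed to bracket",
      class = "ploidysel_error_no_convergence"
    )
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-line, per-generation CV table
#'
#' CVs of flowering time among fertile individuals, with noncentral-t
#' confidence intervals, for every line and generation of a phenotype
#' table.
#'
#' @param phenotypes Phenotype tibble (as in an `experiment_record`).
#' @param level Confidence level.
#' @return Tibble with `line`, `generation`, `n`, `cv`, `lcl`, `ucl`.
#' @export
cv_table <- function(phenotypes, level = 0.95) {
  phen <- tibble::as_tibble(phenotypes)
  phen <- phen[phen$fertile, ]
  groups <- unique(phen[c("line", "generation")])
  groups <- groups[order(groups$line, groups$generation), ]
  out <- lapply(seq_len(nrow(groups)), function(i) {
    rows <- phen[phen$line == groups$line[i] & phen$generation == groups$generation[i], ]
    n <- nrow(rows)
    if (n < 2) {
      return(NULL)
    }
    cv <- coefficient_of_variation(rows$phenotype_days)
    ci <- cv_confidence_interval(cv, n, level)
    tibble::tibble(
      line = groups$line[i], generation = groups$generation[i],
      n = n, cv = cv, lcl = ci$lower_cl, ucl = ci$upper_cl
    )
  })
  dplyr::bind_rows(out)
}

#' 2C DNA content from flow-cytometry peak positions
#'
#' `(sample_peak / standard_peak) * standard_2c`: the sample's fluorescence
#' peak relative to an internal standard of known genome size, scaled to
#' picograms. The default standard is *Epilobium hirsutum* at 0.87 pg.
#' Scale-invariant in detector units.
#'
#' @param sample_peak Sample fluorescence peak position (> 0).
#' @param standard_peak Standard's peak position (> 0).
#' @param standard_2c 2C DNA content of the standard in pg.
#' @return Estimated 2C DNA content in pg.
#' @export
dna_content_2c <- function(sample_peak, standard_peak, standard_2c = 0.87) {
  if (any(sample_peak <= 0) || any(standard_peak <= 0)) {
    rlang::abort("peak positions must be positive",
      class = "ploidysel_error_bad_argument"
    )
  }
  (sample_peak / standard_peak) * standard_2c
}
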