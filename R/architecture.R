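#' Genetic architecture of the simulated flowering-time trait
#'
#' Describes an additive polygenic trait (days to first flower) shared by all
#' simulated designs: biallelic loci with per-allele effects, founder allele
#' frequencies, an environmental residual, cytotype-specific baselines and
#' sterility rates, per-generation environmental blocks, and the tetrasomic
#' double-reduction rate.
#'
#' @param n_loci Number of biallelic loci (default 100, an
#'   infinitesimal-style architecture of many equal effects).
#' @param effect_size Per-allele-copy effect difference `d` in days between
#'   the two alleles at every locus. Ignored when `allele_effects` is given.
#' @param allele_effects `n_loci x 2` matrix of per-copy effects in days
#'   (column 1 = "early" allele). Defaults to centred equal effects
#'   `(-(1-p) d, p d)` so the founder genetic mean is zero.
#' @param founder_allele_freq Founder frequency of allele 1, recycled across
#'   loci.
#' @param env_sd Environmental residual standard deviation in days.
#' @param ploidy_baseline Named vector of baseline flowering times (days) per
#'   cytotype; defaults are the observed base-population means of the
#'   fireweed experiment (diploid 44.5, neotetraploid 47.4, tetraploid 50.5).
#' @param dosage_scale `"ploidy_standardized"` (default) scales the summed
#'   allele effects by `2/ploidy`, so doubling a genome leaves a genotype's
#'   value unchanged and cytotype differences are carried by
#'   `ploidy_baseline`; `"raw"` sums effects without scaling.
#' @param double_reduction Probability `alpha` in `[0, 1/6]` that a
#'   tetrasomic gamete carries two copies of a single parental allele.
#' @param sterility_rate Named per-cytotype base-population sterility
#'   fractions (defaults 0.35/0.28/0.05 as observed in field-derived and
#'   colchicine-converted material).
#' @param sterility_rate_later Sterility fraction applied from generation 1
#'   onward (default 0.06; greenhouse-reared generations are far less sterile
#'   than the field-derived base).
#' @param generation_env_effects Environmental block (days) added to every
#'   phenotype of a generation, indexed from generation 0. The default swings
#'   mimic the large between-generation rearing effects seen in the source
#'   experiment; generations beyond the vector get a zero block.
#'
#' @return A `genetic_architecture` object (list).
#' @seealso [calibrate_architecture()] to derive `effect_size` and `env_sd`
#'   from a target heritability and coefficient of variation.
#' @export
genetic_architecture <- function(n_loci = 100,
                                 effect_size = 0.3,
                                 allele_effects = NULL,
                                 founder_allele_freq = 0.5,
                                 env_sd = 3,
                                 ploidy_baseline = c(
                                   diploid = 44.5,
                                   neotetraploid = 47.4,
                                   tetraploid = 50.5
                                 ),
                                 dosage_scale = c("ploidy_standardized", "raw"),
                                 double_reduction = 0,
                                 sterility_rate = c(
                                   diploid = 0.35,
                                   neotetraploid = 0.28,
                                   tetraploid = 0.05
                                 ),
                                 sterility_rate_later = 0.06,
                                 generation_env_effects = c(0, -3.7, 3.5, 1.1, -6.0)) {
  dosage_scale <- match.arg(dosage_scale)
  p <- rep_len(founder_allele_freq, n_loci)
  if (any(p < 0 | p > 1)) {
    rlang::abort("founder allele frequencies must lie in [0, 1]",
      class = "ploidysel_error_bad_argument"
    )
  }
  if (is.null(allele_effects)) {
    allele_effects <- cbind(-(1 - p) * effect_size, p * effect_size)
  }
  allele_effects <- as.matrix(allele_effects)
  if (nrow(allele_effects) != n_loci || ncol(allele_effects) != 2) {
    rlang::abort("allele_effects must be an n_loci x 2 matrix",
      class = "ploidysel_error_bad_argument"
    )
  }
  if (env_sd < 0) {
    rlang::abort("env_sd must be >= 0", class = "ploidysel_error_bad_argument")
  }
  if (double_reduction < 0 || double_reduction > 1 / 6) {
    rlang::abort("double_reduction must lie in [0, 1/6]",
      class = "ploidysel_error_bad_alpha"
    )
  }
  if (any(sterility_rate < 0 | sterility_rate >= 1) ||
    sterility_rate_later < 0 || sterility_rate_later >= 1) {
    rlang::abort("sterility rates must lie in [0, 1)",
      class = "ploidysel_error_bad_argument"
    )
  }
  structure(
    list(
      n_loci = as.integer(n_loci),
      allele_effects = allele_effects,
      founder_allele_freq = p,
      env_sd = env_sd,
      ploidy_baseline = ploidy_baseline,
      dosage_scale = dosage_scale,
      double_reduction = double_reduction,
      sterility_rate = sterility_rate,
      sterility_rate_later = sterility_rate_later,
      generation_env_effects = generation_env_effects
    ),
    class = "genetic_architecture"
  )
}

#' Calibrate an architecture to a target heritability and base CV
#'
#' Solves for the per-copy effect size and environmental standard deviation
#' such that the founder population has phenotypic variance
#' \eqn{\sigma^2_P = (cv \cdot \mu / 100)^2} and narrow-sense heritability
#' `h2`. Under the ploidy-standardised dosage scale the founder additive
#' variance is \eqn{(4/ploidy)\, L\, p(1-p)\, d^2} for genotypes drawn at
#' Hardy-Weinberg frequencies, and \eqn{2 L p(1-p) d^2} for neotetraploids
#' founded by doubling diploid draws (the duplicated copies are perfectly
#' correlated at synthesis).
#'
#' @param h2 Target narrow-sense heritability of the founder cohort.
#' @param cytotype `"diploid"`, `"neotetraploid"` or `"tetraploid"`;
#'   determines ploidy and the default mean/CV.
#' @param mean_days Base-population mean flowering time; defaults to the
#'   architecture baseline for `cytotype`.
#' @param cv_percent Base-population coefficient of variation (percent);
#'   defaults to the observed base CVs (7.9 diploid, 6.4 neotetraploid,
#'   12.3 tetraploid).
#' @param founders `"hwe"` for Hardy-Weinberg founder draws (any ploidy) or
#'   `"doubled"` for neotetraploid founders synthesised by doubling diploid
#'   draws.
#' @param n_loci,founder_allele_freq,... Passed to [genetic_architecture()].
#'
#' @return A `genetic_architecture` with `effect_size` and `env_sd` solved
#'   for the target, and the cytotype baseline set to `mean_days`.
#' @export
#' @examples
#' arch <- calibrate_architecture(h2 = 0.40, cytotype = "diploid")
#' arch$env_sd
calibrate_architecture <- function(h2,
                                   cytotype = c("diploid", "neotetraploid", "tetraploid"),
                                   mean_days = NULL,
                                   cv_percent = NULL,
                                   founders = c("hwe", "doubled"),
                                   n_loci = 100,
                                   founder_allele_freq = 0.5,
                                   ...) {
  cytotype <- match.arg(cytotype)
  founders <- match.arg(founders)
  if (h2 < 0 || h2 > 1) {
    rlang::abort("h2 must lie in [0, 1]", class = "ploidysel_error_bad_argument")
  }
  default_cv <- c(diploid = 7.9, neotetraploid = 6.4, tetraploid = 12.3)
  default_mean <- c(diploid = 44.5, neotetraploid = 47.4, tetraploid = 50.5)
  if (is.null(mean_days)) mean_days <- unname(default_mean[cytotype])
  if (is.null(cv_percent)) cv_percent <- unname(default_cv[cytotype])
  ploidy <- if (cytotype == "diploid") 2 else 4
  sigma2_p <- (cv_percent / 100 * mean_days)^2
  sigma2_a <- h2 * sigma2_p
  p <- rep_len(founder_allele_freq, n_loci)
  var_factor <- if (founders == "doubled") 2 else 4 / ploidy
  denom <- var_factor * sum(p * (1 - p))
  d <- if (sigma2_a == 0) 0 else sqrt(sigma2_a / denom)
  arch <- genetic_architecture(
    n_loci = n_loci,
    effect_size = d,
    founder_allele_freq = founder_allele_freq,
    env_sd = sqrt(sigma2_p - sigma2_a),
    ...
  )
  arch$ploidy_baseline[cytotype] <- mean_days
  arch$target_h2 <- h2
  arch
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("<genetic_architecture>\n")
  cat("  loci:", x$n_loci, " dosage scale:", x$dosage_scale, "\n")
  cat("  env_sd:", format(x$env_sd, digits = 4), "days; double reduction:",
    x$double_reduction, "\n")
  cat("  baselines:", paste(names(x$ploidy_baseline),
    format(x$ploidy_baseline, digits = 4),
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}

# environmental block for a generation (0-based); zero beyond the vector
gen_env_at <- function(arch, generation) {
  g <- generation + 1L
  ifelse(g >= 1L & g <= length(arch$generation_env_effects),
    arch$generation_env_effects[pmin(pmax(g, 1L), length(arch$generation_env_effects))],
    0
  )
}

sterility_at <- function(arch, cytotype, generation) {
  if (generation == 0L) {
    unname(arch$sterility_rate[cytotype])
  } else {
    arch$sterility_rate_later
  }
}
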