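#' Per-generation selection differential
#'
#' `S_i = mean_fertile - mean_selected`, computed on fertile individuals
#' only, and oriented positive toward earlier flowering (the direction of
#' selection), so successful truncation gives `S_i > 0`.
#'
#' @param summary One row of a [generation_summaries()] table (or any list
#'   with `mean_fertile`, `mean_selected`, `n_selected`).
#' @return `S_i` in days.
#' @export
selection_differential <- function(summary) {
  if (is.na(summary$n_selected) || summary$n_selected < 1) {
    rlang::abort("no individuals were selected from this cohort",
      class = "ploidysel_error_empty_selection"
    )
  }
  summary$mean_fertile - summary$mean_selected
}

#' Control-corrected response series
#'
#' Divergence from the control, `D_t = control_mean_t - selected_mean_t`
#' (positive = selected line flowers earlier), and the per-generation
#' response `R_i = D_i - D_{i-1}`. Both series must start at generation 0,
#' where the lines share the base cohort and the divergence is 0. The
#' control correction removes the large between-generation environmental
#' blocks, which would otherwise dominate a base-referenced response.
#'
#' @param selected_means Mean flowering time of the selected line per
#'   generation, starting at generation 0.
#' @param control_means Control-line means, same length.
#' @return Tibble with `generation`, `divergence` (`D_t`) and `response`
#'   (`R_i`; `NA` for generation 0). `sum(response)` telescopes to the final
#'   divergence.
#' @export
response_series <- function(selected_means, control_means) {
  if (length(selected_means) != length(control_means)) {
    rlang::abort("selected and control series differ in length",
      class = "ploidysel_error_length_mismatch"
    )
  }
  d <- control_means - selected_means
  tibble::tibble(
    generation = seq_along(d) - 1L,
    divergence = d,
    response = c(NA_real_, diff(d))
  )
}

#' Realized heritability
#'
#' The ratio of cumulative control-corrected response to cumulative
#' selection differential, `b_T = R_c / S_c`, evaluated at the final
#' generation (`method = "ratio"`, the default) or as a through-origin
#' regression of the cumulative response on the cumulative differential
#' across generations (`method = "regression"`).
#'
#' @param S Per-generation selection differentials (days), or a list/row
#'   with elements `S` and `R`.
#' @param R Per-generation responses (days), same length as `S`.
#' @param method `"ratio"` or `"regression"`.
#' @return `b_T` (dimensionless). If the cumulative differential is zero
#'   (e.g. a control line) the result is `NA` with attribute
#'   `"reason" = "undefined: zero cumulative selection differential"`.
#' @export
realized_heritability <- function(S, R = NULL, method = c("ratio", "regression")) {
  method <- match.arg(method)
  if (is.null(R)) {
    R <- S$R
    S <- S$S
  }
  if (length(S) != length(R)) {
    rlang::abort("S and R series differ in length",
      class = "ploidysel_error_length_mismatch"
    )
  }
  s_c <- cumsum(S)
  r_c <- cumsum(R)
  if (s_c[length(s_c)] == 0 || (method == "regression" && all(s_c == 0))) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: zero cumulative selection differential"
    return(out)
  }
  if (method == "ratio") {
    r_c[length(r_c)] / s_c[length(s_c)]
  } else {
    sum(s_c * r_c) / sum(s_c^2)
  }
}

#' Sampling error and confidence limits for realized heritability
#'
#' A drift-free sampling approximation in the spirit of the classical
#' realized-heritability variance formulas:
#' \deqn{Var(b_T) = \sigma^2_P (1/M + 1/N) / S_c^2,}
#' with `N` the (harmonic-mean) number of plants grown per generation for
#' the line, `M` the number selected, and \eqn{\sigma^2_P} the base
#' population's phenotypic variance. Confidence limits use the t
#' distribution with `N - 1` degrees of freedom. The standard error is
#' strictly decreasing in `N`, `M` and `S_c`; it ignores genetic drift
#' between generations and should be checked against replicate simulations
#' for any given design.
#'
#' @param b_T Realized heritability point estimate.
#' @param N Plants grown per generation (harmonic mean across generations).
#' @param M Plants selected per generation.
#' @param sigma2_P Base-population phenotypic variance (days squared).
#' @param S_c Cumulative selection differential (days).
#' @param level Confidence level (default 0.95).
#' @return List with `se`, `lower_cl`, `upper_cl`.
#' @export
heritability_confidence <- function(b_T, N, M, sigma2_P, S_c, level = 0.95) {
  if (N <= M || M < 1) {
    rlang::abort("need N > M >= 1", class = "ploidysel_error_bad_argument")
  }
  if (sigma2_P <= 0 || S_c <= 0) {
    rlang::abort("need sigma2_P > 0 and S_c > 0",
      class = "ploidysel_error_bad_argument"
    )
  }
  se <- sqrt(sigma2_P * (1 / M + 1 / N)) / S_c
  tcrit <- stats::qt((1 + level) / 2, df = N - 1)
  list(se = se, lower_cl = b_T - tcrit * se, upper_cl = b_T + tcrit * se)
}

#' Estimate responses and realized heritability for every selected line
#'
#' Applies the full estimation chain to an experiment: per-generation and
#' cumulative selection differentials, control-corrected responses, and
#' `b_T` with its standard error and confidence limits, in the tidy layout
#' `line, generation, N, M, S_i, R_i, S_c, R_c, b_T, se, lcl, ucl`.
#'
#' @param x An `experiment_record`, a phenotype tibble, or a
#'   [generation_summaries()] table.
#' @param control Control line label. Defaults to the design's control line
#'   for an `experiment_record`; otherwise the line whose label ends in
#'   `"C"`.
#' @param method Passed to [realized_heritability()].
#' @param level Confidence level.
#' @return A tibble, one row per selected line and generation >= 1.
#' @export
estimate_response <- function(x, control = NULL,
                              method = c("ratio", "regression"), level = 0.95) {
  method <- match.arg(method)
  if (inherits(x, "experiment_record")) {
    if (is.null(control)) control <- x$design$control
    summ <- generation_summaries(x)
  } else if (all(c("mean_fertile", "mean_selected") %in% names(x))) {
    summ <- x
  } else {
    summ <- generation_summaries(x)
  }
  lines <- unique(summ$line)
  if (is.null(control)) control <- lines[grepl("C$", lines)][1]
  if (is.na(control) || !control %in% lines) {
    rlang::abort("control line not found", class = "ploidysel_error_missing_control")
  }
  ctrl <- summ[summ$line == control, ]
  ctrl <- ctrl[order(ctrl$generation), ]
  out <- list()
  for (ln in setdiff(lines, control)) {
    li <- summ[summ$line == ln, ]
    li <- li[order(li$generation), ]
    gens <- intersect(li$generation, ctrl$generation)
    li <- li[li$generation %in% gens, ]
    ci <- ctrl[ctrl$generation %in% gens, ]
    rs <- response_series(li$mean_fertile, ci$mean_fertile)
    sel_rows <- li$n_selected > 0 & !is.na(li$mean_selected)
    s_i <- ifelse(sel_rows, li$mean_fertile - li$mean_selected, NA_real_)
    # S of round i sits on the generation i-1 row; align to response rows
    s_aligned <- c(NA_real_, s_i[-length(s_i)])
    s_c <- cumsum(ifelse(is.na(s_aligned), 0, s_aligned))
    r_c <- cumsum(ifelse(is.na(rs$response), 0, rs$response))
    keep <- rs$generation >= 1L
    b_t <- realized_heritability(
      S = s_aligned[keep], R = rs$response[keep],
      method = method
    )
    n_line <- li$n_grown[li$generation >= 1L]
    n_harm <- if (length(n_line)) length(n_line) / sum(1 / n_line) else NA_real_
    m_bar <- mean(li$n_selected[sel_rows])
    sigma2_p <- li$sd_fertile[li$generation == 0L]^2
    conf <- if (!is.na(b_t) && s_c[length(s_c)] > 0 && length(sigma2_p) == 1 && !is.na(sigma2_p)) {
      heritability_confidence(b_t, n_harm, m_bar, sigma2_p, s_c[length(s_c)], level)
    } else {
      list(se = NA_real_, lower_cl = NA_real_, upper_cl = NA_real_)
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      line = ln,
      generation = rs$generation[keep],
      N = li$n_grown[keep],
      M = li$n_selected[keep],
      S_i = s_aligned[keep],
      R_i = rs$response[keep],
      S_c = s_c[keep],
      R_c = r_c[keep],
      b_T = as.numeric(b_t),
      se = conf$se, lcl = conf$lower_cl, ucl = conf$upper_cl
    )
  }
  dplyr::bind_rows(out)
}

#' Average realized heritability across replicate lines
#'
#' Arithmetic mean of per-line `b_T` values with an equal-weight pooled
#' confidence limit: the variance of the mean of `k` independent line
#' estimates is the mean of their variances divided by `k`.
#'
#' @param line_estimates Tibble from [estimate_response()] (or any table
#'   with one `b_T`, `se`, `N` per line).
#' @param level Confidence level.
#' @return List with `b_T`, `se`, `lower_cl`, `upper_cl`, `n_lines`.
#' @export
average_line_heritability <- function(line_estimates, level = 0.95) {
  per_line <- unique(line_estimates[c("line", "b_T", "se", "N")])
  per_line <- per_line[!duplicated(per_line$line), ]
  if (nrow(per_line) == 0) {
    rlang::abort("no line estimates supplied", class = "ploidysel_error_empty_selection")
  }
  k <- nrow(per_line)
  b <- mean(per_line$b_T)
  se <- sqrt(mean(per_line$se^2) / k)
  df <- mean(per_line$N) - 1
  tcrit <- stats::qt((1 + level) / 2, df = df)
  list(
    b_T = b, se = se,
    lower_cl = b - tcrit * se, upper_cl = b + tcrit * se,
    n_lines = k
  )
}

#' Divergence of selected lines from the control at one generation
#'
#' Control mean minus the average of the selected-line means, with a
#' standard error propagated from the per-line standard errors when the
#' summaries carry `sd_fertile` and `n_grown`.
#'
#' @param summaries A [generation_summaries()]-style table covering one
#'   ploidy (columns `line`, `generation`, `mean_fertile`, optionally
#'   `sd_fertile`, `n_grown`).
#' @param control Control line label.
#' @param generation Generation at which to evaluate.
#' @param selected Selected line labels; defaults to every non-control line
#'   present at that generation.
#' @return List with `divergence` (days), `se` (or `NA`), `control_mean`,
#'   `selected_means`.
#' @export
divergence_statistic <- function(summaries, control, generation, selected = NULL) {
  rows <- summaries[summaries$generation == generation, ]
  if (!control %in% rows$line) {
    rlang::abort("control line missing at this generation",
      class = "ploidysel_error_missing_control"
    )
  }
  if (is.null(selected)) selected <- setdiff(rows$line, c(control, "base"))
  if (length(selected) == 0) {
    rlang::abort("no selected lines at this generation",
      class = "ploidysel_error_empty_selection"
    )
  }
  crow <- rows[rows$line == control, ]
  srows <- rows[rows$line %in% selected, ]
  div <- crow$mean_fertile[1] - mean(srows$mean_fertile)
  se <- NA_real_
  if (all(c("sd_fertile", "n_grown") %in% names(rows)) &&
    !anyNA(c(crow$sd_fertile, srows$sd_fertile))) {
    v_line <- srows$sd_fertile^2 / srows$n_grown
    se <- sqrt(crow$sd_fertile[1]^2 / crow$n_grown[1] + sum(v_line) / length(v_line)^2)
  }
  list(
    divergence = div, se = se,
    control_mean = crow$mean_fertile[1],
    selected_means = stats::setNames(srows$mean_fertile, srows$line)
  )
}
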