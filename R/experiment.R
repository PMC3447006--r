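#' Selection-experiment design configurations
#'
#' A design config captures the line structure and counts of one ploidy's
#' four-generation divergence selection experiment: base maternal families
#' (two individuals each), two selected lines and one control line, `M`
#' parents selected per line and round, `k` partners per parent in the
#' reciprocal crossing design, four seedlings reared per seed family (two in
#' the final, common-garden generation, for which only a subset of families
#' is reared), and an independent seedling mortality rate.
#'
#' `design_diploid()`, `design_tetraploid()` and `design_neotetraploid()`
#' return the configurations of the fireweed experiment the package models:
#' 113, 105 and 29 base families respectively. The neotetraploid design has
#' a special first round: a single selected line of `M = 20` (and a control
#' of 20 sharing individuals with it), each parent crossed to `k = 4`
#' partners giving 40 pairs, of which 35 are sampled to found each of the
#' two selected lines (and likewise the control line).
#'
#' @param base_families Number of base maternal families.
#' @param base_per_family Individuals per base family (default 2).
#' @param M Parents selected per line and round.
#' @param k Crossing partners per parent.
#' @param generations Number of selection rounds (default 4).
#' @param n_offspring Seedlings per family in ordinary rounds.
#' @param final_n_offspring,final_families Seedlings per family and number of
#'   families reared in the final generation.
#' @param mortality Seedling mortality rate.
#' @param cytotype Cytotype of the design.
#' @param line_prefix Single-letter prefix for line labels (e.g. `"D"` gives
#'   lines D1, D2, DC).
#' @param neo_round1 Use the neotetraploid first-round special case.
#' @param round1_M,round1_k,round1_sampled First-round selected count,
#'   partners per parent, and families sampled from the created pairs (used
#'   only when `neo_round1` is `TRUE`).
#' @param neo_founders `"hwe"` or `"doubled"`: how ploidy-4 founder genotypes
#'   arise (see [found_base_population()]).
#' @return A `design_config` list.
#' @export
design_config <- function(base_families, base_per_family = 2, M = 24, k = 3,
                          generations = 4, n_offspring = 4,
                          final_n_offspring = 2, final_families = 15,
                          mortality = 0.1,
                          cytotype = c("diploid", "neotetraploid", "tetraploid"),
                          line_prefix = "D",
                          neo_round1 = FALSE, round1_M = 20, round1_k = 4,
                          round1_sampled = 35,
                          neo_founders = c("hwe", "doubled")) {
  cytotype <- match.arg(cytotype)
  neo_founders <- match.arg(neo_founders)
  if (M < 1 || k < 1) {
    rlang::abort("M and k must be >= 1", class = "ploidysel_error_bad_argument")
  }
  structure(
    list(
      base_families = as.integer(base_families),
      base_per_family = as.integer(base_per_family),
      M = as.integer(M), k = as.integer(k),
      generations = as.integer(generations),
      n_offspring = as.integer(n_offspring),
      final_n_offspring = as.integer(final_n_offspring),
      final_families = as.integer(final_families),
      mortality = mortality,
      cytotype = cytotype,
      ploidy = if (cytotype == "diploid") 2L else 4L,
      line_prefix = line_prefix,
      lines = paste0(line_prefix, c("1", "2")),
      control = paste0(line_prefix, "C"),
      neo_round1 = neo_round1,
      round1_M = as.integer(round1_M),
      round1_k = as.integer(round1_k),
      round1_sampled = as.integer(round1_sampled),
      neo_founders = neo_founders
    ),
    class = "design_config"
  )
}

#' @rdname design_config
#' @export
design_diploid <- function() {
  design_config(base_families = 113, cytotype = "diploid", line_prefix = "D")
}

#' @rdname design_config
#' @export
design_tetraploid <- function() {
  design_config(base_families = 105, cytotype = "tetraploid", line_prefix = "T")
}

#' @rdname design_config
#' @export
design_neotetraploid <- function(neo_founders = c("hwe", "doubled")) {
  design_config(
    base_families = 29, cytotype = "neotetraploid", line_prefix = "N",
    neo_round1 = TRUE, neo_founders = match.arg(neo_founders)
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config> ", x$cytotype, ": ", x$base_families, " base families, lines ",
    paste(c(x$lines, x$control), collapse = "/"),
    ", M=", x$M, " k=", x$k, ", ", x$generations, " generations\n",
    sep = ""
  )
  invisible(x)
}

# deterministic per-(line, round, stage) sub-seeds derived from the master seed
stream_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run one replicate of a selection experiment
#'
#' Simulates the full design: founding of the base population, four rounds of
#' within-line truncation selection (random, non-truncating draws for the
#' control line), reciprocal crossing among non-relatives, and rearing of the
#' next generation with mortality, including the neotetraploid first-round
#' special case. Each (line, round) stage runs on its own named random
#' stream derived from `seed`, so results are reproducible and robust to
#' config edits elsewhere in the design.
#'
#' @param design A [design_config()].
#' @param arch A [genetic_architecture()].
#' @param seed Integer seed.
#' @return An `experiment_record`: list with `cohorts` (per line, per
#'   generation [sim_cohort()]s; generation 0 is the shared base under line
#'   `"base"`), `selections` (tibble of per-line per-round selected-group
#'   means and sizes), `pedigree` (a [pedigree()] of every reared
#'   individual), `phenotypes` (tidy tibble), `design`, `arch` and `seed`.
#' @export
run_experiment <- function(design, arch, seed = 1L) {
  stopifnot(inherits(design, "design_config"), inherits(arch, "genetic_architecture"))
  all_lines <- c(design$lines, design$control)
  n_streams <- 2L + length(all_lines) * (design$generations + 1L)
  seeds <- stream_seeds(seed, n_streams)
  s_i <- 0L
  next_stream <- function() {
    s_i <<- s_i + 1L
    set.seed(seeds[s_i])
  }

  next_stream()
  base <- found_base_population(
    arch, design$base_families, design$base_per_family,
    ploidy = design$ploidy, cytotype = design$cytotype,
    line = "base", neo_founders = design$neo_founders,
    id_prefix = paste0(design$line_prefix, "B")
  )
  cohorts <- list(base = list(`0` = base))
  for (ln in all_lines) cohorts[[ln]] <- list()
  selections <- list()
  ped_rows <- list(base$info)

  record_selection <- function(line, round, sel) {
    selections[[length(selections) + 1L]] <<- tibble::tibble(
      line = line, round = round,
      n_selected = nrow(sel$info),
      mean_selected = mean(sel$info$phenotype),
      ids = list(sel$info$id)
    )
  }
  live_ped <- function() {
    pedigree(dplyr::bind_rows(ped_rows)[, c(
      "id", "dam", "sire", "maternal_family",
      "line", "generation", "ploidy", "fertile"
    )])
  }

  # --- round 1 (selection on the shared base) ---
  next_stream()
  ped0 <- live_ped()
  if (design$neo_round1) {
    selN <- truncation_select(base, design$round1_M)
    selC <- random_select(base, design$round1_M)
    pairsN <- crossing_design(selN, design$round1_k, ped0)
    pairsC <- crossing_design(selC, design$round1_k, ped0)
    for (ln in design$lines) record_selection(ln, 1L, selN)
    record_selection(design$control, 1L, selC)
    round1 <- stats::setNames(
      list(list(selN, pairsN), list(selN, pairsN), list(selC, pairsC)),
      c(design$lines, design$control)
    )
    round1_families <- design$round1_sampled
  } else {
    two <- split_base_two_lines(base, design$M)
    selC <- random_select(base, design$M)
    p1 <- crossing_design(two[[1]], design$k, ped0)
    p2 <- crossing_design(two[[2]], design$k, ped0)
    pC <- crossing_design(selC, design$k, ped0)
    record_selection(design$lines[1], 1L, two[[1]])
    record_selection(design$lines[2], 1L, two[[2]])
    record_selection(design$control, 1L, selC)
    round1 <- stats::setNames(
      list(list(two[[1]], p1), list(two[[2]], p2), list(selC, pC)),
      c(design$lines, design$control)
    )
    round1_families <- NULL
  }
  for (ln in c(design$lines, design$control)) {
    next_stream()
    stage <- round1[[ln]]
    cohort <- advance_generation(stage[[2]], stage[[1]], arch,
      generation = 1L, line = ln,
      n_offspring = design$n_offspring, mortality = design$mortality,
      n_families = round1_families
    )
    cohorts[[ln]][["1"]] <- cohort
    ped_rows[[length(ped_rows) + 1L]] <- cohort$info
  }

  # --- rounds 2..G ---
  for (round in seq(2L, design$generations)) {
    final <- round == design$generations
    ped_now <- live_ped()
    for (ln in c(design$lines, design$control)) {
      next_stream()
      cohort <- cohorts[[ln]][[as.character(round - 1L)]]
      sel <- if (ln == design$control) {
        random_select(cohort, design$M)
      } else {
        truncation_select(cohort, design$M)
      }
      record_selection(ln, round, sel)
      pairs <- crossing_design(sel, design$k, ped_now)
      nxt <- advance_generation(pairs, sel, arch,
        generation = round, line = ln,
        n_offspring = if (final) design$final_n_offspring else design$n_offspring,
        mortality = design$mortality,
        n_families = if (final) design$final_families else NULL
      )
      cohorts[[ln]][[as.character(round)]] <- nxt
      ped_rows[[length(ped_rows) + 1L]] <- nxt$info
    }
  }

  phen_cols <- c(
    "id", "dam", "sire", "maternal_family", "line", "generation",
    "ploidy", "cytotype", "fertile", "phenotype", "breeding_value"
  )
  phenotypes <- dplyr::bind_rows(ped_rows)[phen_cols]
  names(phenotypes)[names(phenotypes) == "phenotype"] <- "phenotype_days"
  structure(
    list(
      cohorts = cohorts,
      selections = dplyr::bind_rows(selections),
      pedigree = live_ped(),
      phenotypes = phenotypes,
      design = design, arch = arch, seed = seed
    ),
    class = "experiment_record"
  )
}

#' @export
print.experiment_record <- function(x, ...) {
  cat("<experiment_record> ", x$design$cytotype, " design, seed ", x$seed,
    ": ", nrow(x$phenotypes), " individuals across ",
    x$design$generations + 1L, " generations\n",
    sep = ""
  )
  invisible(x)
}

# Base-round assignment: the earliest 2M fertile plants are walked in rank
# order and dealt to the two selected lines, maternal siblings to different
# lines, at most one member of a family per line.
split_base_two_lines <- function(base, M) {
  info <- base$info
  eligible <- which(info$fertile)
  ord <- eligible[order(info$phenotype[eligible], stats::runif(length(eligible)))]
  lines <- list(integer(0), integer(0))
  fams <- list(character(0), character(0))
  for (i in ord) {
    f <- info$maternal_family[i]
    open <- which(vapply(
      seq_len(2),
      function(l) length(lines[[l]]) < M && !f %in% fams[[l]], logical(1)
    ))
    if (length(open) == 0) next
    pick <- if (length(open) == 2) {
      sizes <- lengths(lines)[open]
      if (sizes[1] == sizes[2]) sample(open, 1) else open[which.min(sizes)]
    } else {
      open
    }
    lines[[pick]] <- c(lines[[pick]], i)
    fams[[pick]] <- c(fams[[pick]], f)
    if (all(lengths(lines) == M)) break
  }
  if (!all(lengths(lines) == M)) {
    rlang::abort("not enough fertile base individuals to found two selected lines",
      class = "ploidysel_error_insufficient"
    )
  }
  lapply(lines, function(idx) {
    out <- cohort_subset(base, idx)
    attr(out, "indices") <- idx
    out
  })
}

#' Per-line per-generation phenotype summaries
#'
#' Builds the generation-summary table the estimators consume: for every line
#' and generation, the number of plants grown, fertile-only mean and SD of
#' flowering time, and the size and mean of the selected group whose
#' selection acted on that cohort. Generation-0 rows are duplicated per line
#' (the base cohort is shared) so each line's round-1 selection has a home.
#'
#' @param record An `experiment_record`, or a phenotype tibble in the format
#'   of `record$phenotypes` (in which case selected groups are recovered
#'   from parentage: the parents of generation `g + 1` offspring of a line
#'   are its round-`g + 1` selected group).
#' @return A tibble with columns `line`, `generation`, `n_grown`,
#'   `n_selected`, `mean_fertile`, `sd_fertile`, `mean_selected`.
#' @export
generation_summaries <- function(record) {
  if (inherits(record, "experiment_record")) {
    phen <- record$phenotypes
    sel <- record$selections
  } else {
    phen <- tibble::as_tibble(record)
    sel <- selections_from_parentage(phen)
  }
  lines <- setdiff(unique(phen$line), "base")
  base_rows <- phen[phen$line == "base" & phen$generation == 0L, ]
  out <- list()
  for (ln in lines) {
    gens <- sort(unique(phen$generation[phen$line == ln]))
    gen0 <- if (nrow(base_rows) > 0) 0L else integer(0)
    for (g in union(gen0, gens)) {
      rows <- if (g == 0L && nrow(base_rows) > 0) base_rows else phen[phen$line == ln & phen$generation == g, ]
      fert <- rows$phenotype_days[rows$fertile]
      selrow <- sel[sel$line == ln & sel$round == g + 1L, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        line = ln, generation = as.integer(g),
        n_grown = nrow(rows),
        n_selected = if (nrow(selrow)) selrow$n_selected[1] else 0L,
        mean_fertile = mean(fert),
        sd_fertile = stats::sd(fert),
        mean_selected = if (nrow(selrow)) selrow$mean_selected[1] else NA_real_
      )
    }
  }
  dplyr::bind_rows(out)
}

# selected group of round r = unique parents of a line's generation-r offspring
selections_from_parentage <- function(phen) {
  out <- list()
  for (ln in setdiff(unique(phen$line), "base")) {
    for (g in sort(unique(phen$generation[phen$line == ln]))) {
      off <- phen[phen$line == ln & phen$generation == g, ]
      parents <- unique(c(off$dam, off$sire))
      parents <- setdiff(parents, UNKNOWN_PARENT)
      if (length(parents) == 0) next
      pr <- phen[match(parents, phen$id), ]
      out[[length(out) + 1L]] <- tibble::tibble(
        line = ln, round = as.integer(g),
        n_selected = length(parents),
        mean_selected = mean(pr$phenotype_days),
        ids = list(parents)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Write simulated phenotype records to CSV
#'
#' Emits the pedigree columns plus `phenotype_days` and `breeding_value`,
#' one row per reared individual, in a stable order.
#'
#' @param record An `experiment_record` (or its `phenotypes` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(record, path) {
  phen <- if (inherits(record, "experiment_record")) record$phenotypes else record
  phen <- as.data.frame(phen)
  phen$phenotype_days <- formatC(phen$phenotype_days, format = "g", digits = 15)
  phen$breeding_value <- formatC(phen$breeding_value, format = "g", digits = 15)
  utils::write.csv(phen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenotype records written by [write_phenotypes()]
#'
#' @param path CSV path.
#' @return A tibble in the `phenotypes` format of an `experiment_record`.
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  tibble::tibble(
    id = raw$id, dam = normalize_parent(raw$dam), sire = normalize_parent(raw$sire),
    maternal_family = raw$maternal_family, line = raw$line,
    generation = as.integer(raw$generation), ploidy = as.integer(raw$ploidy),
    cytotype = if ("cytotype" %in% names(raw)) raw$cytotype else NA_character_,
    fertile = raw$fertile %in% c("TRUE", "true", "T", "1"),
    phenotype_days = as.numeric(raw$phenotype_days),
    breeding_value = if ("breeding_value" %in% names(raw)) as.numeric(raw$breeding_value) else NA_real_
  )
}
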