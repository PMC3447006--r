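#' Published per-line mean flowering times
#'
#' The per-line, per-generation mean flowering times (days) of the fireweed
#' divergence selection experiment the package models, shipped as a packaged
#' fixture so the end-of-experiment divergence statistics can be recomputed
#' without raw data or simulation.
#'
#' @return Tibble with `cytotype`, `line`, `generation`, `mean_fertile`
#'   (days). Generation-0 rows carry line `"base"`.
#' @export
flowering_means_reference <- function() {
  path <- system.file("extdata", "flowering_time_line_means.csv",
    package = "ploidysel", mustWork = TRUE
  )
  raw <- utils::read.csv(path)
  tibble::tibble(
    cytotype = raw$cytotype, line = raw$line,
    generation = as.integer(raw$generation),
    mean_fertile = as.numeric(raw$mean_days)
  )
}

#' Divergence statistics from the published line means
#'
#' Recomputes, for each cytotype, the final-generation divergence of the
#' selected lines from the control using [divergence_statistic()] on the
#' packaged reference means.
#'
#' @param generation Generation at which to evaluate (default 4).
#' @return Tibble with `cytotype`, `generation`, `divergence`.
#' @export
reference_divergences <- function(generation = 4) {
  ref <- flowering_means_reference()
  out <- lapply(unique(ref$cytotype), function(cc) {
    rows <- ref[ref$cytotype == cc, ]
    control <- rows$line[grepl("C$", rows$line)][1]
    d <- divergence_statistic(rows, control = control, generation = generation)
    tibble::tibble(cytotype = cc, generation = generation, divergence = d$divergence)
  })
  dplyr::bind_rows(out)
}

#' Run replicated selection experiments
#'
#' Simulates `n_reps` independent replicates of one design, with
#' per-replicate seeds derived deterministically from `master_seed`, and
#' applies the whole estimation chain to each: realized heritability per
#' selected line, divergence trajectories, per-line CVs, and mean
#' inbreeding coefficients in the final generation.
#'
#' @param design A [design_config()].
#' @param arch A [genetic_architecture()].
#' @param n_reps Number of replicates (>= 1).
#' @param master_seed Integer master seed.
#' @param cv_intervals Compute noncentral-t CIs in the CV tables (slower;
#'   default `TRUE`).
#' @param inbreeding Compute final-generation mean F per line (default
#'   `TRUE`).
#' @return A `replicate_summary`: list of tibbles `estimates` (replicate,
#'   line, b_T, se, S_c, R_c), `divergence` (replicate, line, generation,
#'   divergence), `cv` (per replicate [cv_table()]), `inbreeding`
#'   (replicate, line, mean_F), plus a `manifest`.
#' @export
run_replicates <- function(design, arch, n_reps, master_seed = 1L,
                           cv_intervals = TRUE, inbreeding = TRUE) {
  if (n_reps < 1) {
    rlang::abort("n_reps must be >= 1", class = "ploidysel_error_bad_argument")
  }
  rep_seeds <- stream_seeds(master_seed, n_reps)
  est_l <- vector("list", n_reps)
  div_l <- vector("list", n_reps)
  cv_l <- vector("list", n_reps)
  f_l <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rec <- run_experiment(design, arch, seed = rep_seeds[r])
    est <- estimate_response(rec)
    per_line <- unique(est[c("line", "b_T", "se", "lcl", "ucl")])
    last <- est[est$generation == max(est$generation), c("line", "S_c", "R_c")]
    est_l[[r]] <- dplyr::bind_cols(replicate = r, dplyr::left_join(per_line, last, by = "line"))
    summ <- generation_summaries(rec)
    div_rows <- list()
    for (ln in design$lines) {
      li <- summ[summ$line == ln, ]
      ci <- summ[summ$line == design$control, ]
      gens <- intersect(li$generation, ci$generation)
      rs <- response_series(
        li$mean_fertile[match(gens, li$generation)],
        ci$mean_fertile[match(gens, ci$generation)]
      )
      div_rows[[ln]] <- tibble::tibble(
        replicate = r, line = ln,
        generation = rs$generation, divergence = rs$divergence
      )
    }
    div_l[[r]] <- dplyr::bind_rows(div_rows)
    if (cv_intervals) {
      cv_l[[r]] <- dplyr::bind_cols(replicate = r, cv_table(rec$phenotypes))
    }
    if (inbreeding) {
      f_l[[r]] <- dplyr::bind_rows(lapply(
        c(design$lines, design$control),
        function(ln) {
          tibble::tibble(
            replicate = r, line = ln,
            mean_F = mean_line_inbreeding(rec$pedigree, ln, design$generations)
          )
        }
      ))
    }
  }
  structure(
    list(
      estimates = dplyr::bind_rows(est_l),
      divergence = dplyr::bind_rows(div_l),
      cv = dplyr::bind_rows(cv_l),
      inbreeding = dplyr::bind_rows(f_l),
      manifest = run_manifest(design, arch, n_reps, master_seed, rep_seeds)
    ),
    class = "replicate_summary"
  )
}

run_manifest <- function(design, arch, n_reps, master_seed, rep_seeds) {
  list(
    package_version = as.character(utils::packageVersion("ploidysel")),
    design_digest = rlang::hash(unclass(design)),
    architecture_digest = rlang::hash(unclass(arch)),
    master_seed = master_seed,
    n_reps = n_reps,
    replicate_seeds = rep_seeds,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary> ", x$manifest$n_reps, " replicates; mean b_T = ",
    format(mean(x$estimates$b_T), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write the report tables of a run
#'
#' Emits CSV analogues of the experiment's report tables, with a stable
#' column order, plus a JSON run manifest:
#' `counts.csv` (per line and round: families, individuals grown, fertile,
#' selected, seed-family pairs created), `flowering_means.csv`,
#' `cv.csv`, `inbreeding.csv`, `results.csv` (the tidy
#' [estimate_response()] output). Re-running on the same record writes
#' byte-identical files.
#'
#' @param x An `experiment_record` or `replicate_summary`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
emit_tables <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(col) {
      ifelse(is.na(col), "", formatC(col, format = "g", digits = 10))
    })
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (inherits(x, "experiment_record")) {
    summ <- generation_summaries(x)
    wr(experiment_counts(x), "counts.csv")
    wr(
      summ[c("line", "generation", "n_grown", "mean_fertile", "sd_fertile")],
      "flowering_means.csv"
    )
    wr(cv_table(x$phenotypes), "cv.csv")
    fin <- x$design$generations
    lines <- c(x$design$lines, x$design$control)
    wr(tibble::tibble(
      line = lines,
      generation = fin,
      mean_F = vapply(lines, function(ln) {
        mean_line_inbreeding(x$pedigree, ln, fin)
      }, numeric(1))
    ), "inbreeding.csv")
    wr(estimate_response(x), "results.csv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("ploidysel")),
      design_digest = rlang::hash(unclass(x$design)),
      architecture_digest = rlang::hash(unclass(x$arch)),
      seed = x$seed
    )
  } else if (inherits(x, "replicate_summary")) {
    wr(x$estimates, "results.csv")
    wr(x$divergence, "divergence.csv")
    if (nrow(x$cv)) wr(x$cv, "cv.csv")
    if (nrow(x$inbreeding)) wr(x$inbreeding, "inbreeding.csv")
    manifest <- x$manifest
  } else {
    rlang::abort("emit_tables expects an experiment_record or replicate_summary",
      class = "ploidysel_error_bad_argument"
    )
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

# per-line stage counts for one replicate; round-1 selection acts on
# the shared base cohort and is reported on each line's generation-0 row
experiment_counts <- function(record) {
  design <- record$design
  phen <- record$phenotypes
  sel <- record$selections
  base_rows <- phen[phen$line == "base", ]
  out <- list()
  for (ln in c(design$lines, design$control)) {
    gens <- sort(unique(phen$generation[phen$line == ln]))
    for (g in union(0L, gens)) {
      rows <- if (g == 0L) base_rows else phen[phen$line == ln & phen$generation == g, ]
      selrow <- sel[sel$line == ln & sel$round == g + 1L, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        line = ln, generation = g,
        maternal_families = length(unique(rows$maternal_family)),
        individuals = nrow(rows),
        fertile = sum(rows$fertile),
        selected = if (nrow(selrow)) selrow$n_selected[1] else NA_integer_,
        pairs_created = if (nrow(selrow)) {
          m <- selrow$n_selected[1]
          k <- if (design$neo_round1 && g == 0L) design$round1_k else design$k
          as.integer(m * k / 2)
        } else {
          NA_integer_
        }
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Read a design + architecture config file
#'
#' A flat YAML mapping with sections `design`, `architecture` and optional
#' `run`. `design` keys mirror [design_config()] arguments (plus `kind:
#' diploid|tetraploid|neotetraploid` to start from a packaged design);
#' `architecture` keys either give `h2` (and optionally `mean_days`,
#' `cv_percent`) for [calibrate_architecture()], or explicit
#' [genetic_architecture()] arguments. `run` may carry `reps` and `seed`.
#'
#' @param path YAML file path.
#' @return List with `design`, `arch`, `reps`, `seed`.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dsec <- cfg$design %||% list()
  kind <- dsec$kind %||% "diploid"
  base <- switch(kind,
    diploid = design_diploid(),
    tetraploid = design_tetraploid(),
    neotetraploid = design_neotetraploid(),
    rlang::abort(paste0("unknown design kind: ", kind),
      class = "ploidysel_error_bad_config"
    )
  )
  overridable <- c(
    "base_families", "base_per_family", "M", "k", "generations",
    "n_offspring", "final_n_offspring", "final_families", "mortality",
    "neo_founders"
  )
  bad <- setdiff(names(dsec), c("kind", overridable))
  if (length(bad)) {
    rlang::abort(paste0("unknown design key(s): ", paste(bad, collapse = ", ")),
      class = "ploidysel_error_bad_config"
    )
  }
  for (key in intersect(names(dsec), overridable)) base[[key]] <- dsec[[key]]
  asec <- cfg$architecture %||% list()
  arch <- if (!is.null(asec$h2)) {
    calib_args <- asec[intersect(names(asec), c(
      "h2", "mean_days", "cv_percent",
      "founders", "n_loci", "founder_allele_freq"
    ))]
    calib_args$cytotype <- base$cytotype
    do.call(calibrate_architecture, calib_args)
  } else {
    do.call(genetic_architecture, asec)
  }
  list(
    design = base, arch = arch,
    reps = cfg$run$reps %||% 1L,
    seed = cfg$run$seed %||% 1L
  )
}
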