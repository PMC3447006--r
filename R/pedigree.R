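#' Construct a pedigree
#'
#' A pedigree is a validated table of individuals, their parents, maternal
#' family, experimental line, generation, ploidy and fertility. Unknown
#' parents are coded with the sentinel `"0"` (the empty string is accepted on
#' input and normalised to `"0"`). Founders (generation 0 individuals with no
#' recorded parents) must have both parents unknown; non-founders may have one
#' known and one unknown parent.
#'
#' @param records A data frame with columns `id`, `dam`, `sire`,
#'   `maternal_family`, `line`, `generation`, `ploidy`, `fertile`.
#'
#' @details Validation enforces: unique ids
#'   (`ploidysel_error_duplicate_id`), all referenced parents present
#'   (`ploidysel_error_dangling_parent`), known parents belonging to a
#'   strictly earlier generation, and acyclicity
#'   (`ploidysel_error_cycle`). Each violation signals a condition of the
#'   named class so callers can distinguish them.
#'
#' @return An object of class `pedigree`: a tibble of the validated records.
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("f1", "f2", "x"), dam = c("0", "0", "f1"), sire = c("0", "0", "f2"),
#'   maternal_family = c("A", "B", "A"), line = "D1",
#'   generation = c(0L, 0L, 1L), ploidy = 2L,
#'   fertile = TRUE
#' ))
#' inbreeding_coefficient(ped, "x")
pedigree <- function(records) {
  required <- c(
    "id", "dam", "sire", "maternal_family", "line",
    "generation", "ploidy", "fertile"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("pedigree records lack columns: ", paste(missing_cols, collapse = ", ")),
      class = "ploidysel_error_bad_columns"
    )
  }
  rec <- tibble::as_tibble(records)[required]
  rec$id <- as.character(rec$id)
  rec$dam <- normalize_parent(rec$dam)
  rec$sire <- normalize_parent(rec$sire)
  rec$maternal_family <- as.character(rec$maternal_family)
  rec$line <- as.character(rec$line)
  rec$generation <- as.integer(rec$generation)
  rec$ploidy <- as.integer(rec$ploidy)
  rec$fertile <- as.logical(rec$fertile)

  dup <- rec$id[duplicated(rec$id)]
  if (length(dup) > 0) {
    rlang::abort(
      paste0("duplicate pedigree id(s): ", paste(unique(dup), collapse = ", ")),
      class = "ploidysel_error_duplicate_id"
    )
  }
  parents <- c(rec$dam, rec$sire)
  known <- setdiff(unique(parents), UNKNOWN_PARENT)
  dangling <- setdiff(known, rec$id)
  if (length(dangling) > 0) {
    rlang::abort(
      paste0("parent id(s) not present in pedigree: ", paste(dangling, collapse = ", ")),
      class = "ploidysel_error_dangling_parent"
    )
  }
  if (any(rec$dam == rec$id) || any(rec$sire == rec$id)) {
    rlang::abort("individual listed as its own parent",
      class = "ploidysel_error_cycle"
    )
  }
  gen <- stats::setNames(rec$generation, rec$id)
  for (side in c("dam", "sire")) {
    p <- rec[[side]]
    has <- p != UNKNOWN_PARENT
    bad <- has & !(gen[p] < rec$generation)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      rlang::abort(
        paste0(
          "parent generation not earlier than offspring for id(s): ",
          paste(rec$id[bad], collapse = ", ")
        ),
        class = "ploidysel_error_cycle"
      )
    }
  }
  # generations strictly decrease along parent links, so the graph is acyclic;
  # a full traversal check would be redundant here.
  structure(rec, class = c("pedigree", class(rec)))
}

UNKNOWN_PARENT <- "0"

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- UNKNOWN_PARENT
  x
}

#' Read a pedigree from CSV
#'
#' Expects a header `id,dam,sire,maternal_family,line,generation,ploidy,fertile`.
#' Unknown parents may be coded `"0"` or left empty. Row order is irrelevant.
#'
#' @param path Path to a comma-delimited UTF-8 file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.csv(path,
    colClasses = "character",
    fileEncoding = "UTF-8", check.names = TRUE
  )
  if (!"fertile" %in% names(raw)) {
    rlang::abort("pedigree file lacks a 'fertile' column",
      class = "ploidysel_error_bad_columns"
    )
  }
  raw$fertile <- raw$fertile %in% c("TRUE", "true", "T", "1")
  pedigree(raw)
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()]; unknown parents are written as `"0"`.
#'
#' @param ped A [pedigree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(
    "<pedigree> ", nrow(x), " individuals, ",
    length(unique(x$line)), " line(s), generations ",
    min(x$generation), "-", max(x$generation), "\n",
    sep = ""
  )
  NextMethod()
}

ped_index <- function(ped) {
  stats::setNames(seq_len(nrow(ped)), ped$id)
}

assert_ped_id <- function(ped, id) {
  missing <- setdiff(id, ped$id)
  if (length(missing) > 0) {
    rlang::abort(
      paste0("unknown pedigree id(s): ", paste(missing, collapse = ", ")),
      class = "ploidysel_error_unknown_id"
    )
  }
}
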